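#' Configuration for a synthetic proteomic cohort
#'
#' Describes the statistical world the generator draws from: a cohort of
#' pre-treatment tumor biopsies with quantified log2 protein intensities, a
#' planted co-expressed module (the adherens-junction stand-in) whose mean is
#' depressed in a latent "AJ-low" patient subgroup, and clinical covariates
#' (therapy, response, histology, inflammation grades) whose conditional
#' distributions mirror the frequencies observed in the motivating cohort of
#' 157 esophageal adenocarcinoma patients.
#'
#' Expression model, for sample \eqn{s} and protein \eqn{g}:
#' \deqn{X_{gs} = \mu_g + \lambda f_s - \delta\,[s\ \mathrm{AJ\!-\!low}] + \epsilon_{gs}}
#' for module proteins, where \eqn{f_s \sim N(0,1)} is a per-sample latent
#' factor, \eqn{\lambda} = `module_loading` and \eqn{\delta} = `module_shift`
#' (log2 units); decoy modules share their own factors; background proteins
#' are \eqn{\mu_g + \epsilon_{gs}} with \eqn{\mu_g \sim N(20, 2)} and
#' \eqn{\epsilon \sim N(0, \mathrm{noise\_sd}^2)}. Entries are masked missing
#' completely at random at rate `missing_rate`.
#'
#' @param n_samples Number of patients (default 157).
#' @param n_proteins Number of quantified proteins (default 1200; scale up to
#'   match a full proteome, the model is unchanged).
#' @param module_size Size of the planted module (default 10).
#' @param module_loading Latent-factor loading \eqn{\lambda \ge 0} of module
#'   and decoy-module proteins (default 1.5). With `noise_sd` 1 the implied
#'   pairwise within-module correlation is
#'   \eqn{\lambda^2 / (\lambda^2 + \sigma^2) \approx 0.69}.
#' @param module_shift Mean depression \eqn{\delta \ge 0} (log2 units) of
#'   module proteins in AJ-low samples (default 2).
#' @param frac_aj_low_by_histology Named probabilities of the AJ-low label
#'   given histology (defaults tubular 0.27, mixed 0.40, diffuse 0.50,
#'   other 0.33).
#' @param histology_mix Named probabilities over
#'   `c("tubular","diffuse","mixed","other")` (defaults 0.55/0.18/0.22/0.05).
#' @param therapy_mix Probability of FLOT (vs CROSS) therapy (default 0.459).
#' @param p_major Named probabilities of major response given therapy and
#'   AJ group, names `FLOT_high`, `FLOT_low`, `CROSS_high`, `CROSS_low`
#'   (defaults 0.35 / 0.06 / 0.26 / 0.26).
#' @param ulceration_probs,inflammation_probs Lists with elements `high` and
#'   `low`, each a probability 3-vector over `c("none","few","abundant")`.
#' @param noise_sd Residual standard deviation (default 1).
#' @param missing_rate Probability an entry is masked missing (default 0.05).
#' @param n_decoy_modules Number of decoy correlated modules (default 5).
#' @param n_matrisome Number of proteins tagged as matrisome/ECM (default 200).
#' @param n_ecm_up Number of matrisome-tagged proteins whose mean is raised by
#'   `module_shift` in AJ-low samples, emulating ECM remodeling (default 5).
#' @param n_random_sets Number of random decoy gene sets in the generated
#'   collection (default 20).
#'
#' @return A list of class `cohort_config`.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_samples = 157,
                          n_proteins = 1200,
                          module_size = 10,
                          module_loading = 1.5,
                          module_shift = 2,
                          frac_aj_low_by_histology = c(tubular = 0.27, mixed = 0.40,
                                                       diffuse = 0.50, other = 0.33),
                          histology_mix = c(tubular = 0.55, diffuse = 0.18,
                                            mixed = 0.22, other = 0.05),
                          therapy_mix = 0.459,
                          p_major = c(FLOT_high = 0.35, FLOT_low = 0.06,
                                      CROSS_high = 0.26, CROSS_low = 0.26),
                          ulceration_probs = list(high = c(0.63, 0.30, 0.07),
                                                  low = c(0.33, 0.38, 0.29)),
                          inflammation_probs = list(high = c(0.63, 0.28, 0.09),
                                                    low = c(0.12, 0.63, 0.25)),
                          noise_sd = 1,
                          missing_rate = 0.05,
                          n_decoy_modules = 5,
                          n_matrisome = 200,
                          n_ecm_up = 5,
                          n_random_sets = 20) {
  cfg <- list(
    n_samples = n_samples, n_proteins = n_proteins, module_size = module_size,
    module_loading = module_loading, module_shift = module_shift,
    frac_aj_low_by_histology = frac_aj_low_by_histology,
    histology_mix = histology_mix, therapy_mix = therapy_mix,
    p_major = p_major, ulceration_probs = ulceration_probs,
    inflammation_probs = inflammation_probs, noise_sd = noise_sd,
    missing_rate = missing_rate, n_decoy_modules = n_decoy_modules,
    n_matrisome = n_matrisome, n_ecm_up = n_ecm_up,
    n_random_sets = n_random_sets
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$module_size > cfg$n_proteins) {
    abort("`module_size` must not exceed `n_proteins`.", class = "ajnet_config_error")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    abort("`missing_rate` must lie in [0, 1).", class = "ajnet_config_error")
  }
  check_simplex <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      abort(paste0("`", what, "` must be a probability vector summing to 1."),
            class = "ajnet_config_error")
    }
  }
  check_simplex(cfg$histology_mix, "histology_mix")
  check_simplex(cfg$ulceration_probs$high, "ulceration_probs$high")
  check_simplex(cfg$ulceration_probs$low, "ulceration_probs$low")
  check_simplex(cfg$inflammation_probs$high, "inflammation_probs$high")
  check_simplex(cfg$inflammation_probs$low, "inflammation_probs$low")
  probs <- c(cfg$frac_aj_low_by_histology, cfg$therapy_mix, cfg$p_major,
             cfg$missing_rate)
  if (any(probs < 0 | probs > 1)) {
    abort("All probabilities must lie in [0, 1].", class = "ajnet_config_error")
  }
  needed <- c("tubular", "diffuse", "mixed", "other")
  if (!all(needed %in% names(cfg$histology_mix)) ||
      !all(needed %in% names(cfg$frac_aj_low_by_histology))) {
    abort("histology maps must name tubular, diffuse, mixed and other.",
          class = "ajnet_config_error")
  }
  invisible(cfg)
}

# Clinical nuisance distributions conditional on response, pooled over both
# therapy arms of the motivating cohort (39 major, 118 minor responders).
.clinical_priors <- list(
  gender_male = 0.86,
  age_lt65 = 0.637,
  ypT = list(major = c(13, 12, 7, 7, 0) / 39, minor = c(0, 14, 20, 80, 4) / 118),
  ypN = list(major = c(27, 11, 1, 0) / 39,    minor = c(41, 31, 19, 27) / 118),
  L1  = list(major = 4 / 39,  minor = 58 / 118),
  V1  = list(major = 0,       minor = 29 / 118),
  Pn  = list(major = c(34, 0, 5) / 39, minor = c(54, 42, 22) / 118)
)

#' Simulate a synthetic proteomic cohort with ground truth
#'
#' Draws an expression matrix, clinical annotation, gene-set collection,
#' synthetic matrisome annotation and the generating ground truth from the
#' world described by a [cohort_config()]. Identical `config` + `seed` give
#' bit-identical output.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; all randomness derives from it.
#'
#' @return A list of class `aj_cohort` with elements
#' \describe{
#'   \item{expression}{numeric matrix, proteins in rows, samples in columns,
#'     log2 intensities with `NA` for missing.}
#'   \item{clinical}{tibble, one row per sample: therapy, response, histology,
#'     ypT, ypN, L, V, Pn, ulceration, inflammation, gender, age_class.}
#'   \item{gene_sets}{named list of protein-id character vectors; contains an
#'     `ADHERENS_JUNCTION` set covering the planted module, one set per decoy
#'     module, and random decoy sets.}
#'   \item{matrisome}{tibble (protein_id, category) of ECM-tagged proteins.}
#'   \item{truth}{list: module_proteins, aj_label_true (named "high"/"low"
#'     vector over samples), decoy_modules, ecm_up_proteins.}
#' }
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_samples = 40, n_proteins = 100), seed = 1)
#' dim(cohort$expression)
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  validate_cohort_config(config)
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(as.integer(seed))
  n <- config$n_samples
  p <- config$n_proteins

  protein_ids <- sprintf("P%05d", seq_len(p))
  sample_ids <- sprintf("S%04d", seq_len(n))

  ## planted structure: module, decoy modules, ECM-up proteins all disjoint
  n_special <- config$module_size * (1 + config$n_decoy_modules) + config$n_ecm_up
  if (n_special > p) {
    abort("n_proteins too small for the requested module structure.",
          class = "ajnet_config_error")
  }
  special <- sample(protein_ids, n_special)
  module_proteins <- special[seq_len(config$module_size)]
  decoy_modules <- list()
  off <- config$module_size
  for (d in seq_len(config$n_decoy_modules)) {
    decoy_modules[[d]] <- special[off + seq_len(config$module_size)]
    off <- off + config$module_size
  }
  ecm_up <- if (config$n_ecm_up > 0) special[off + seq_len(config$n_ecm_up)] else character()

  ## clinical draws
  histology <- sample(names(config$histology_mix), n, replace = TRUE,
                      prob = config$histology_mix)
  aj_low <- stats::rbinom(n, 1, config$frac_aj_low_by_histology[histology]) == 1
  aj_true <- ifelse(aj_low, "low", "high")
  therapy <- ifelse(stats::rbinom(n, 1, config$therapy_mix) == 1, "FLOT", "CROSS")
  p_major <- config$p_major[paste(therapy, aj_true, sep = "_")]
  response <- ifelse(stats::rbinom(n, 1, p_major) == 1, "major", "minor")
  grades <- c("none", "few", "abundant")
  draw_grade <- function(probs) {
    vapply(aj_true, function(g) sample(grades, 1, prob = probs[[g]]), character(1))
  }
  ulceration <- draw_grade(config$ulceration_probs)
  inflammation <- draw_grade(config$inflammation_probs)
  pri <- .clinical_priors
  gender <- ifelse(stats::rbinom(n, 1, pri$gender_male) == 1, "male", "female")
  age_class <- ifelse(stats::rbinom(n, 1, pri$age_lt65) == 1, "lt65", "ge65")
  draw_by_response <- function(levels, prior) {
    vapply(response, function(r) sample(levels, 1, prob = prior[[r]]), character(1))
  }
  ypT <- draw_by_response(as.character(0:4), pri$ypT)
  ypN <- draw_by_response(as.character(0:3), pri$ypN)
  L <- ifelse(stats::rbinom(n, 1, ifelse(response == "major", pri$L1$major, pri$L1$minor)) == 1, "1", "0")
  V <- ifelse(stats::rbinom(n, 1, ifelse(response == "major", pri$V1$major, pri$V1$minor)) == 1, "1", "0")
  Pn <- draw_by_response(c("0", "1", "unknown"), pri$Pn)

  clinical <- tibble(
    sample_id = sample_ids, therapy = therapy, response = unname(response),
    histology = histology, ypT = unname(ypT), ypN = unname(ypN),
    L = unname(L), V = unname(V), Pn = unname(Pn),
    ulceration = unname(ulceration), inflammation = unname(inflammation),
    gender = gender, age_class = age_class
  )

  ## expression
  mu <- stats::rnorm(p, mean = 20, sd = 2)
  names(mu) <- protein_ids
  X <- matrix(stats::rnorm(p * n, sd = config$noise_sd), nrow = p,
              dimnames = list(protein_ids, sample_ids))
  X <- X + mu
  f_module <- stats::rnorm(n)
  X[module_proteins, ] <- X[module_proteins, ] +
    rep(config$module_loading * f_module, each = config$module_size)
  X[module_proteins, aj_low] <- X[module_proteins, aj_low] - config$module_shift
  for (dm in decoy_modules) {
    f_d <- stats::rnorm(n)
    X[dm, ] <- X[dm, ] + rep(config$module_loading * f_d, each = length(dm))
  }
  if (length(ecm_up) > 0) {
    X[ecm_up, aj_low] <- X[ecm_up, aj_low] + config$module_shift
  }

  ## missingness, MCAR; keep at least one observed value per protein
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(p * n) < config$missing_rate, nrow = p)
    dead <- rowSums(!mask) == 0
    if (any(dead)) {
      keep <- sample.int(n, sum(dead), replace = TRUE)
      mask[cbind(which(dead), keep)] <- FALSE
    }
    X[mask] <- NA_real_
  }

  ## gene sets: AJ set = module plus a few unrelated proteins, decoy-module
  ## sets, and random decoys
  background <- setdiff(protein_ids, special)
  gene_sets <- list()
  gene_sets[["ADHERENS_JUNCTION"]] <- c(module_proteins,
    sample(background, min(5, length(background))))
  for (d in seq_along(decoy_modules)) {
    gene_sets[[sprintf("DECOY_MODULE_%02d", d)]] <-
      c(decoy_modules[[d]], sample(background, min(5, length(background))))
  }
  for (i in seq_len(config$n_random_sets)) {
    gene_sets[[sprintf("RANDOM_SET_%02d", i)]] <-
      sample(protein_ids, min(sample(10:40, 1), p))
  }

  n_extra <- min(max(0, config$n_matrisome - length(ecm_up)), length(background))
  matrisome_pool <- unique(c(ecm_up, sample(background, n_extra)))
  matrisome <- tibble(
    protein_id = matrisome_pool,
    category = ifelse(matrisome_pool %in% ecm_up, "ECM Regulators", "Core matrisome")
  )

  structure(list(
    expression = X,
    clinical = clinical,
    gene_sets = gene_sets,
    matrisome = matrisome,
    truth = list(module_proteins = module_proteins,
                 aj_label_true = setNames(aj_true, sample_ids),
                 decoy_modules = decoy_modules,
                 ecm_up_proteins = ecm_up),
    config = config,
    seed = as.integer(seed)
  ), class = "aj_cohort")
}

#' @export
print.aj_cohort <- function(x, ...) {
  cat(sprintf("<aj_cohort> %d proteins x %d samples (seed %d)\n",
              nrow(x$expression), ncol(x$expression), x$seed))
  cat(sprintf("  planted module: %d proteins; %d decoy modules; %d gene sets\n",
              length(x$truth$module_proteins), length(x$truth$decoy_modules),
              length(x$gene_sets)))
  cat(sprintf("  AJ-low (true): %d / %d samples\n",
              sum(x$truth$aj_label_true == "low"), ncol(x$expression)))
  invisible(x)
}
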