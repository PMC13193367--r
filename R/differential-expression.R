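# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); y <= 0 is the caller's signal for an infinite-df prior.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

# Empirical-Bayes fit of the scaled inverse-chi-square variance prior
# (d0, s0^2) by moment matching on z_g = log s_g^2, as in the standard
# moderated-t: E[z] and Var[z] are digamma/trigamma functions of the
# residual df, so the excess variance of z identifies d0.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  s2 <- s2[ok]; df <- df[ok]
  if (length(s2) < 2) abort("Need >= 2 positive sample variances to fit the prior.",
                            class = "ajnet_input_error")
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  n <- length(e)
  target <- mean((e - ebar)^2 * n / (n - 1) - trigamma(df / 2))
  if (target <= 0) {
    ## no excess dispersion: variances are exchangeable, prior df infinite
    inform("No excess variance dispersion; prior degrees of freedom set to Inf.")
    return(list(d0 = Inf, s0_sq = exp(ebar)))
  }
  d0 <- 2 * trigamma_inverse(target)
  s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated-t differential expression between two sample groups
#'
#' Two-group empirical-Bayes moderated t-test, the standard shrinkage
#' estimator for small-sample expression studies: per-protein pooled
#' variances are shrunk toward a prior \eqn{(d_0, s_0^2)} fitted by moment
#' matching on the log variances, the posterior variance is
#' \eqn{\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)}, and
#' \eqn{t = \mathrm{log2fc} / (\tilde{s}_g \sqrt{1/n_1 + 1/n_2})} is referred
#' to a t distribution on \eqn{d_0 + d_g} degrees of freedom. The fold-change
#' sign convention is low-minus-high: negative log2fc means lower expression
#' in the "low" group. A protein is flagged significant under the dual rule
#' `p < de_p` and BH-adjusted `p < de_adj_p`.
#'
#' @param expr Numeric matrix, proteins in rows, samples in columns.
#' @param labels Named character vector or tibble (sample_id, aj_label)
#'   assigning samples to `"high"` / `"low"`; samples with other/missing
#'   labels are ignored.
#' @param de_p Raw p-value threshold of the dual rule (default 0.05).
#' @param de_adj_p Adjusted p-value threshold of the dual rule (default 0.2).
#' @param min_per_group Proteins observed in fewer samples than this in
#'   either group are excluded (default 3).
#' @param d0_override `NULL` (fit the prior), `0` (no moderation: ordinary
#'   equal-variance t), or `Inf` (full shrinkage to the prior variance).
#' @return Object of class `moderated_t_fit`: list with `results` tibble
#'   (protein_id, n_low, n_high, mean_low, mean_high, log2fc, s2, s2_post,
#'   t_mod, df_total, p, adj_p, significant), `prior` (d0, s0_sq), and the
#'   thresholds used. `tidy()` returns the results; `glance()` the prior and
#'   counts.
#' @export
fit_moderated_t <- function(expr, labels, de_p = 0.05, de_adj_p = 0.2,
                            min_per_group = 3, d0_override = NULL) {
  stopifnot(is.matrix(expr))
  if (is.data.frame(labels)) {
    labels <- setNames(labels$aj_label, labels$sample_id)
  }
  labels <- labels[!is.na(labels)]
  low_ids <- intersect(names(labels)[labels == "low"], colnames(expr))
  high_ids <- intersect(names(labels)[labels == "high"], colnames(expr))
  if (length(low_ids) == 0 || length(high_ids) == 0) {
    abort("Both groups need at least one labeled sample present in the matrix.",
          class = "ajnet_input_error")
  }
  xl <- expr[, low_ids, drop = FALSE]
  xh <- expr[, high_ids, drop = FALSE]
  n1 <- rowSums(!is.na(xl))
  n2 <- rowSums(!is.na(xh))
  usable <- n1 >= min_per_group & n2 >= min_per_group
  if (sum(!usable) > 0) {
    inform(sprintf("%d protein(s) excluded with < %d observations in a group.",
                   sum(!usable), min_per_group))
  }
  if (!any(usable)) abort("No protein has enough observations in both groups.",
                          class = "ajnet_input_error")
  xl <- xl[usable, , drop = FALSE]; xh <- xh[usable, , drop = FALSE]
  n1 <- n1[usable]; n2 <- n2[usable]
  m1 <- rowMeans(xl, na.rm = TRUE)
  m2 <- rowMeans(xh, na.rm = TRUE)
  v1 <- apply(xl, 1, stats::var, na.rm = TRUE)
  v2 <- apply(xh, 1, stats::var, na.rm = TRUE)
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  log2fc <- m1 - m2

  if (is.null(d0_override)) {
    prior <- fit_variance_prior(s2, df)
  } else if (d0_override == 0) {
    prior <- list(d0 = 0, s0_sq = NA_real_)
  } else if (is.infinite(d0_override)) {
    prior <- fit_variance_prior(s2, df)
    prior$d0 <- Inf
  } else {
    prior <- list(d0 = d0_override, s0_sq = fit_variance_prior(s2, df)$s0_sq)
  }
  d0 <- prior$d0; s0_sq <- prior$s0_sq
  s2_post <- if (d0 == 0) s2
             else if (is.infinite(d0)) rep(s0_sq, length(s2))
             else (d0 * s0_sq + df * s2) / (d0 + df)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- log2fc / se
  df_total <- d0 + df
  p <- 2 * pt(-abs(t_mod), df = df_total)
  adj_p <- bh_adjust(p)
  results <- tibble(
    protein_id = rownames(xl),
    n_low = as.integer(unname(n1)), n_high = as.integer(unname(n2)),
    mean_low = unname(m1), mean_high = unname(m2), log2fc = unname(log2fc),
    s2 = unname(s2), s2_post = unname(s2_post), t_mod = unname(t_mod),
    df_total = unname(df_total), p = unname(p), adj_p = unname(adj_p),
    significant = unname(p < de_p & adj_p < de_adj_p)
  )
  structure(list(results = results, prior = prior,
                 de_p = de_p, de_adj_p = de_adj_p,
                 n_excluded = sum(!usable)),
            class = "moderated_t_fit")
}

#' @export
print.moderated_t_fit <- function(x, ...) {
  cat(sprintf("<moderated_t_fit> %d proteins tested, %d significant (p < %g & adj p < %g)\n",
              nrow(x$results), sum(x$results$significant), x$de_p, x$de_adj_p))
  cat(sprintf("  prior: d0 = %.3g, s0^2 = %.3g\n", x$prior$d0, x$prior$s0_sq))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.moderated_t_fit <- function(x, ...) {
  x$results
}

#' @exportS3Method generics::glance
glance.moderated_t_fit <- function(x, ...) {
  tibble(
    n_tested = nrow(x$results),
    n_significant = sum(x$results$significant),
    n_excluded = x$n_excluded,
    d0 = x$prior$d0,
    s0_sq = x$prior$s0_sq
  )
}

#' Partition matrisome proteins by differential-expression direction
#'
#' Restricts a moderated-t result table to proteins in a matrisome
#' (extracellular-matrix) annotation and counts the significantly
#' differential ones in each direction, under the low-minus-high sign
#' convention: `log2fc > 0` means higher expression in the low group.
#'
#' @param fit A `moderated_t_fit` (or its `tidy()` tibble).
#' @param matrisome Character vector of matrisome protein ids, or a tibble
#'   with a protein_id column.
#' @return List: `n_up_in_low`, `n_up_in_high`, and `table` (tibble of
#'   significant matrisome proteins with a direction column).
#' @export
matrisome_partition <- function(fit, matrisome) {
  results <- if (inherits(fit, "moderated_t_fit")) fit$results else as_tibble(fit)
  ids <- if (is.data.frame(matrisome)) matrisome$protein_id else matrisome
  sub <- dplyr::filter(results, .data$protein_id %in% ids, .data$significant)
  tab <- sub |>
    dplyr::mutate(direction = ifelse(.data$log2fc > 0, "up_in_low", "up_in_high")) |>
    dplyr::select("protein_id", "log2fc", "p", "adj_p", "direction") |>
    dplyr::arrange(.data$adj_p)
  list(
    n_up_in_low = sum(tab$direction == "up_in_low"),
    n_up_in_high = sum(tab$direction == "up_in_high"),
    table = tab
  )
}

#' Write differential-expression results to TSV
#' @param fit A `moderated_t_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de <- function(fit, path) {
  readr::write_tsv(fit$results, path)
  invisible(path)
}

#' Volcano plot of a moderated-t fit
#' @param object A `moderated_t_fit`.
#' @param highlight Optional protein ids drawn in a distinct color.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.moderated_t_fit <- function(object, highlight = NULL, ...) {
  df <- object$results |>
    dplyr::mutate(
      status = dplyr::case_when(
        .data$protein_id %in% (highlight %||% character()) ~ "highlighted",
        .data$significant ~ "significant",
        TRUE ~ "ns"
      )
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = -log10(.data$p),
                                   color = .data$status)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_color_manual(values = c(ns = "grey70", significant = "steelblue",
                                           highlighted = "firebrick")) +
    ggplot2::labs(x = expression(log[2]~fold~change~(low - high)),
                  y = expression(-log[10]~italic(p)), color = NULL) +
    ggplot2::theme_minimal()
}
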