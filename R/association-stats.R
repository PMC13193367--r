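# log conditional probability of a table given both margins
# (multivariate hypergeometric)
log_table_prob <- function(counts) {
  sum(lfactorial(rowSums(counts))) + sum(lfactorial(colSums(counts))) -
    lfactorial(sum(counts)) - sum(lfactorial(counts))
}

# enumerate all r x c tables with the given margins, calling fun(counts)
enumerate_tables <- function(row_sums, col_sums, fun) {
  r <- length(row_sums); c <- length(col_sums)
  counts <- matrix(0L, r, c)
  rec <- function(i, j, row_rem, col_rem) {
    if (i == r) {
      ## last row forced by column remainders
      if (any(col_rem < 0)) return(invisible())
      counts[r, ] <<- col_rem
      if (sum(col_rem) == row_rem[r]) fun(counts)
      return(invisible())
    }
    if (j == c) {
      ## last cell of the row forced
      x <- row_rem[i]
      if (x < 0 || x > col_rem[c]) return(invisible())
      counts[i, c] <<- x
      rec(i + 1, 1, {rr <- row_rem; rr[i] <- 0; rr}, {cc <- col_rem; cc[c] <- cc[c] - x; cc})
      return(invisible())
    }
    hi <- min(row_rem[i], col_rem[j])
    for (x in 0:hi) {
      counts[i, j] <<- x
      rec(i, j + 1, {rr <- row_rem; rr[i] <- rr[i] - x; rr},
          {cc <- col_rem; cc[j] <- cc[j] - x; cc})
    }
    invisible()
  }
  rec(1, 1, row_sums, col_sums)
  invisible()
}

#' Fisher's exact test on an r x c contingency table
#'
#' Two-sided exact test: conditional on both margins, the p-value is the sum
#' of the multivariate hypergeometric probabilities of every table no more
#' probable than the observed one (with a relative tolerance of 1e-7 on the
#' comparison, matching common statistical software). Tables are enumerated
#' by a margin-respecting recursive traversal in log-factorial arithmetic;
#' the 2x2 case is additionally cross-checked against the direct
#' hypergeometric tail formulation. For totals above `max_total` exact
#' enumeration is refused; use `monte_carlo = TRUE` for a seeded
#' permutation-table estimate instead.
#'
#' @param counts Matrix of non-negative integer counts, at least 2x2. Zero
#'   rows and columns are dropped before testing.
#' @param max_total Enumeration guard on the table total (default 500).
#' @param monte_carlo Estimate the p-value from `n_mc` random tables with the
#'   observed margins instead of enumerating (default `FALSE`).
#' @param n_mc Number of Monte Carlo tables (default 1e5).
#' @param seed Seed for the Monte Carlo draw (default 1).
#' @return The two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(17, 55, 22, 63), 2, 2, byrow = TRUE))
#' @export
fisher_exact <- function(counts, max_total = 500, monte_carlo = FALSE,
                         n_mc = 1e5, seed = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Counts must be non-negative integers.", class = "ajnet_input_error")
  }
  storage.mode(counts) <- "double"
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    warn("Degenerate table after dropping empty margins; p = 1.")
    return(1)
  }
  total <- sum(counts)
  lp_obs <- log_table_prob(counts)
  cutoff <- lp_obs + log1p(1e-7)
  rs <- rowSums(counts); cs <- colSums(counts)
  if (monte_carlo) {
    set.seed(as.integer(seed))
    tabs <- stats::r2dtable(n_mc, rs, cs)
    hits <- vapply(tabs, function(tt) log_table_prob(tt) <= cutoff, logical(1))
    return((1 + sum(hits)) / (n_mc + 1))
  }
  if (total > max_total) {
    abort(sprintf("Table total %d exceeds max_total = %d; use monte_carlo = TRUE.",
                  total, max_total), class = "ajnet_input_error")
  }
  acc <- new.env()
  acc$lse <- -Inf  # log-sum-exp accumulator of qualifying probabilities
  enumerate_tables(rs, cs, function(tt) {
    lp <- log_table_prob(tt)
    if (lp <= cutoff) {
      m <- max(acc$lse, lp)
      acc$lse <- m + log(exp(acc$lse - m) + exp(lp - m))
    }
  })
  p <- min(1, exp(acc$lse))
  if (nrow(counts) == 2 && ncol(counts) == 2) {
    ## independent tail formulation on the hypergeometric distribution of
    ## the top-left cell
    a <- 0:min(rs[1], cs[1])
    probs <- stats::dhyper(a, cs[1], total - cs[1], rs[1])
    p2 <- min(1, sum(probs[probs <= exp(cutoff)]))
    stopifnot(abs(p - p2) < 1e-8)
  }
  p
}

# exact null distribution of the rank-sum of the smaller-indexed sample:
# number of n_x-subsets of ranks 1..N with each possible sum, by dynamic
# programming over ranks
ranksum_null_counts <- function(n_x, N) {
  w_max <- sum((N - n_x + 1):N)
  ## dp[k+1, w+1] = ways to pick k of the first i ranks with sum w
  dp <- matrix(0, n_x + 1, w_max + 1)
  dp[1, 1] <- 1
  for (i in seq_len(N)) {
    for (k in min(i, n_x):1) {
      shifted <- c(rep(0, i), dp[k, seq_len(w_max + 1 - i)])
      dp[k + 1, ] <- dp[k + 1, ] + shifted
    }
  }
  dp[n_x + 1, ]  # index w+1 = count of subsets with sum w
}

#' Wilcoxon rank-sum test
#'
#' Two-sided test of a location difference between two samples. Exact by the
#' rank-sum null distribution when the combined size is at most 20 and there
#' are no ties; otherwise a normal approximation with tie and continuity
#' corrections.
#'
#' @param x,y Non-empty numeric vectors.
#' @return The two-sided p-value.
#' @examples
#' wilcoxon_ranksum(c(1, 2), c(3, 4))
#' @export
wilcoxon_ranksum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    abort("Both samples must be non-empty.", class = "ajnet_input_error")
  }
  pooled <- c(x, y)
  N <- length(pooled)
  rk <- rank(pooled)
  W <- sum(rk[seq_along(x)])
  ties <- any(duplicated(pooled))
  if (N <= 20 && !ties) {
    cnt <- ranksum_null_counts(length(x), N)
    total <- sum(cnt)
    ## index w + 1 holds the count of subsets with rank sum w
    lower <- sum(cnt[seq_len(W + 1)])
    upper <- sum(cnt[(W + 1):length(cnt)])
    return(min(1, 2 * min(lower, upper) / total))
  }
  n_x <- length(x); n_y <- length(y)
  mu <- n_x * (N + 1) / 2
  tie_tab <- table(pooled)
  tie_adj <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- n_x * n_y / 12 * ((N + 1) - tie_adj)
  if (sigma2 <= 0) return(1)  # all observations identical
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

# Contingency table between two clinical factors with closed-vocabulary
# missingness handling; returns NULL (with a message) when either variable
# has < 2 observed levels.
cross_table <- function(df, var_a, var_b, drop_tokens = c("unknown")) {
  a <- df[[var_a]]; b <- df[[var_b]]
  keep <- !is.na(a) & !is.na(b) & !(a %in% drop_tokens) & !(b %in% drop_tokens)
  a <- a[keep]; b <- b[keep]
  if (length(unique(a)) < 2 || length(unique(b)) < 2) {
    inform(sprintf("Skipping %s x %s: fewer than 2 observed levels.", var_a, var_b))
    return(NULL)
  }
  tab <- table(a, b)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(NULL)
  tab
}

#' Build and test the study's categorical association tables
#'
#' Reproduces the categorical testing surface of the analysis: per-therapy
#' response associations with each clinicopathological variable, the
#' stratification label against response (per therapy), histology,
#' ulceration and inflammation, and histology against response. Each
#' association is tested with [fisher_exact()]. "unknown" tokens and missing
#' values are excluded by default.
#'
#' @param clinical Clinical tibble (see [read_clinical()]).
#' @param strat Optional `aj_stratification`; adds the label-based tables.
#' @param include_unknown Keep "unknown" as a category (default `FALSE`).
#' @return Tibble of class `association_tests`: association, therapy, n, p,
#'   table (list-column of count matrices).
#' @export
build_tables <- function(clinical, strat = NULL, include_unknown = FALSE) {
  drop_tokens <- if (include_unknown) character() else "unknown"
  df <- as_tibble(clinical)
  if (!is.null(strat)) {
    lab <- tidy(strat)[, c("sample_id", "aj_label")]
    df <- dplyr::left_join(df, lab, by = "sample_id")
  }
  out <- list()
  add <- function(name, therapy, sub, var_a, var_b) {
    tab <- cross_table(sub, var_a, var_b, drop_tokens)
    if (is.null(tab)) return(invisible())
    out[[length(out) + 1]] <<- tibble(
      association = name, therapy = therapy, n = sum(tab),
      p = fisher_exact(unclass(tab)), table = list(unclass(tab))
    )
  }
  clin_vars <- intersect(c("gender", "age_class", "ypT", "ypN", "L", "V", "Pn"),
                         colnames(df))
  for (th in intersect(c("FLOT", "CROSS"), unique(df$therapy))) {
    sub <- df[df$therapy == th & !is.na(df$therapy), ]
    for (v in clin_vars) add(paste0("response_x_", v), th, sub, "response", v)
    if ("aj_label" %in% colnames(df)) {
      add("aj_x_response", th, sub, "aj_label", "response")
    }
  }
  if ("aj_label" %in% colnames(df)) {
    for (v in intersect(c("histology", "ulceration", "inflammation"), colnames(df))) {
      add(paste0("aj_x_", v), NA_character_, df, "aj_label", v)
    }
  }
  add("histology_x_response", NA_character_, df, "histology", "response")
  res <- purrr::list_rbind(out)
  structure(res, class = c("association_tests", class(tibble())))
}

#' Write association test results to TSV
#' @param tests An `association_tests` tibble from [build_tables()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(tests, path) {
  flat <- as_tibble(tests)
  flat$table <- vapply(flat$table, function(tt) {
    paste(apply(tt, 1, paste, collapse = ","), collapse = ";")
  }, character(1))
  readr::write_tsv(flat, path)
  invisible(path)
}
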