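#' Benjamini–Hochberg adjustment
#'
#' Step-up FDR adjustment: on the ascending order statistics
#' \eqn{p_{(1)} \le \dots \le p_{(m)}}, the adjusted value is
#' \eqn{\min_{j \ge i} m\, p_{(j)} / j}, capped at 1 and mapped back to the
#' input order. Monotone nondecreasing in p and invariant to input
#' permutation.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1].", class = "ajnet_input_error")
  }
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  pmin(1, adj_sorted)[order(o)]
}

#' Hypergeometric overrepresentation analysis
#'
#' Tests a query protein set against every set in a collection with the
#' upper-tail hypergeometric test: with a universe of \eqn{N} proteins of
#' which \eqn{K} belong to the gene set, and a query of \eqn{n}, the p-value
#' is \eqn{P(X \ge k)} for the observed overlap \eqn{k}. P-values are
#' BH-adjusted across the sets tested in this call. Sets overlapping the
#' query by fewer than `min_overlap` proteins are reported with p = 1 and
#' excluded from the adjustment.
#'
#' @param query Character vector of protein ids (members outside the universe
#'   are dropped with a message).
#' @param sets Named list of protein-id character vectors (see [read_gmt()]).
#' @param universe Character vector: all quantified proteins.
#' @param min_overlap Minimum overlap for a set to enter the adjustment
#'   (default 2).
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @return Tibble of class `ora_result`, sorted by adj_p then set_name:
#'   set_name, universe_N, set_K, query_n, overlap_k, p, adj_p, tested,
#'   overlap_ids (list-column).
#' @examples
#' universe <- sprintf("P%02d", 1:20)
#' ora(universe[1:5], list(HIT = universe[1:5]), universe)
#' @export
ora <- function(query, sets, universe, min_overlap = 2,
                adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (length(universe) == 0) abort("Empty universe.", class = "ajnet_input_error")
  if (length(query) == 0) abort("Empty query.", class = "ajnet_input_error")
  universe <- unique(universe)
  query0 <- unique(query)
  query <- intersect(query0, universe)
  if (length(query) < length(query0)) {
    inform(sprintf("Dropped %d query protein(s) outside the universe.",
                   length(query0) - length(query)))
  }
  if (length(query) == 0) abort("Query has no proteins in the universe.",
                                class = "ajnet_input_error")
  N <- length(universe)
  n <- length(query)
  res <- purrr::map(names(sets), function(nm) {
    members <- intersect(unique(sets[[nm]]), universe)
    K <- length(members)
    overlap <- intersect(members, query)
    k <- length(overlap)
    ## upper tail P(X >= k)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(set_name = nm, universe_N = N, set_K = K, query_n = n,
           overlap_k = k, p = p, tested = k >= min_overlap,
           overlap_ids = list(sort(overlap)))
  }) |> purrr::list_rbind()
  res$p[!res$tested] <- 1
  res$adj_p <- NA_real_
  if (any(res$tested)) {
    res$adj_p[res$tested] <- switch(adjust,
      BH = bh_adjust(res$p[res$tested]),
      bonferroni = pmin(1, res$p[res$tested] * sum(res$tested))
    )
  }
  if (any(!res$tested)) {
    inform(sprintf("%d set(s) below min_overlap excluded from adjustment.",
                   sum(!res$tested)))
  }
  res <- dplyr::arrange(res, !.data$tested, .data$adj_p, .data$set_name)
  res <- res[, c("set_name", "universe_N", "set_K", "query_n", "overlap_k",
                 "p", "adj_p", "tested", "overlap_ids")]
  structure(res, adjust = adjust, class = c("ora_result", class(tibble())))
}

#' Write enrichment results to TSV
#' @param result An `ora_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(result, path) {
  flat <- as_tibble(result)
  flat$overlap_ids <- vapply(flat$overlap_ids, paste, character(1), collapse = ";")
  readr::write_tsv(flat, path)
  invisible(path)
}

#' Barplot of top enriched sets
#' @param object An `ora_result`.
#' @param n_top Number of sets shown (default 8).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ora_result <- function(object, n_top = 8, ...) {
  top <- as_tibble(object) |>
    dplyr::filter(.data$tested) |>
    dplyr::slice_min(.data$adj_p, n = n_top, with_ties = FALSE)
  ggplot2::ggplot(top, ggplot2::aes(x = -log10(.data$adj_p),
                                    y = stats::reorder(.data$set_name, -.data$adj_p))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = expression(-log[10]~adjusted~italic(p)), y = NULL) +
    ggplot2::theme_minimal()
}
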