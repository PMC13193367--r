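#' Euclidean distance summaries between sample groups
#'
#' For each requested pair of groups, computes Euclidean distances between
#' the (unscaled log2) expression vectors of all cross-group sample pairs —
#' or all within-group pairs when the two labels coincide — restricted to
#' proteins observed in every involved sample (complete case per
#' comparison).
#'
#' @param expr Numeric matrix, proteins in rows, samples in columns.
#' @param groups Named character vector (or tibble sample_id/group) mapping
#'   samples to group labels; unlabeled samples are ignored.
#' @param subset Protein ids to restrict to, or `NULL` for the full proteome.
#' @param pairs List of length-2 character vectors `(label_a, label_b)`;
#'   `label_a == label_b` requests within-group (internal) distances.
#' @return Tibble of class `distance_summary`: group_a, group_b, subset_name,
#'   n_proteins, n_pairs, median, distances (list-column).
#' @examples
#' x <- matrix(c(1, 2, 4, 6), nrow = 2, dimnames = list(c("p1", "p2"), c("a", "b")))
#' group_distances(x, c(a = "g1", b = "g2"), pairs = list(c("g1", "g2")))
#' @export
group_distances <- function(expr, groups, subset = NULL, pairs) {
  stopifnot(is.matrix(expr))
  if (is.data.frame(groups)) groups <- setNames(groups$group, groups$sample_id)
  groups <- groups[!is.na(groups)]
  subset_name <- if (is.null(subset)) "full_proteome" else "subset"
  if (!is.null(subset)) {
    subset <- intersect(subset, rownames(expr))
    if (length(subset) == 0) abort("No subset protein present in the matrix.",
                                   class = "ajnet_input_error")
    expr <- expr[subset, , drop = FALSE]
  }
  purrr::map(pairs, function(pr) {
    a <- names(groups)[groups == pr[1]]
    b <- names(groups)[groups == pr[2]]
    a <- intersect(a, colnames(expr)); b <- intersect(b, colnames(expr))
    internal <- pr[1] == pr[2]
    if (length(a) == 0 || length(b) == 0 ||
        (internal && length(a) < 2)) {
      abort(sprintf("Group '%s' or '%s' too small for distances.", pr[1], pr[2]),
            class = "ajnet_input_error")
    }
    involved <- union(a, b)
    complete <- rowSums(is.na(expr[, involved, drop = FALSE])) == 0
    if (!any(complete)) abort("No protein observed in every involved sample.",
                              class = "ajnet_input_error")
    sub <- expr[complete, , drop = FALSE]
    d <- if (internal) {
      dm <- as.matrix(stats::dist(t(sub[, a, drop = FALSE])))
      dm[upper.tri(dm)]
    } else {
      sq <- outer(colSums(sub[, a, drop = FALSE]^2), colSums(sub[, b, drop = FALSE]^2), "+") -
        2 * crossprod(sub[, a, drop = FALSE], sub[, b, drop = FALSE])
      dm <- sqrt(pmax(sq, 0))
      as.vector(dm)
    }
    tibble(group_a = pr[1], group_b = pr[2], subset_name = subset_name,
           n_proteins = sum(complete), n_pairs = length(d),
           median = median(d), distances = list(unname(d)))
  }) |> purrr::list_rbind() |>
    structure(class = c("distance_summary", class(tibble())))
}

#' Compare two distance distributions
#'
#' Wilcoxon rank-sum comparison of the pair-distance distributions of two
#' rows of a [group_distances()] result.
#'
#' @param summary A `distance_summary` tibble.
#' @param i,j Row indices of the two distributions to compare.
#' @return The two-sided Wilcoxon p-value.
#' @export
compare_distances <- function(summary, i, j) {
  wilcoxon_ranksum(summary$distances[[i]], summary$distances[[j]])
}

#' Write distance summaries to TSV
#' @param summary A `distance_summary` tibble.
#' @param path Output path.
#' @param full_pairs Also write every pair distance (default `FALSE`:
#'   medians only).
#' @return `path`, invisibly.
#' @export
write_distances <- function(summary, path, full_pairs = FALSE) {
  flat <- as_tibble(summary)
  if (full_pairs) {
    flat$distances <- vapply(flat$distances, function(d)
      paste(sprintf("%.6f", d), collapse = ";"), character(1))
  } else {
    flat$distances <- NULL
  }
  readr::write_tsv(flat, path)
  invisible(path)
}

#' Boxplot of group-distance distributions
#' @param object A `distance_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.distance_summary <- function(object, ...) {
  long <- as_tibble(object) |>
    dplyr::mutate(comparison = paste(.data$group_a, "vs", .data$group_b)) |>
    dplyr::select("comparison", "distances") |>
    tidyr::unnest_longer("distances", values_to = "distance")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$comparison, y = .data$distance)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Euclidean distance") +
    ggplot2::theme_minimal()
}
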