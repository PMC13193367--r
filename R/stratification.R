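# Per-protein z-scoring over observed values; missing entries become 0
# (the protein mean). Rows with zero variance are centered only.
zscore_rows <- function(x) {
  mu <- rowMeans(x, na.rm = TRUE)
  s <- apply(x, 1, sd, na.rm = TRUE)
  s[is.na(s) | s == 0] <- 1
  z <- (x - mu) / s
  z[is.na(z)] <- 0
  z
}

#' Order samples by Ward hierarchical clustering
#'
#' Agglomerative clustering of samples with the "ward.D2" criterion on
#' Euclidean distances over per-protein z-scored expression, as used for
#' expression-heatmap column ordering. Returns the dendrogram leaf order.
#'
#' @param expr_subset Numeric matrix, proteins in rows, samples in columns
#'   (typically the module subset); missing values are mean-imputed after
#'   z-scoring.
#' @return Character vector: sample ids in leaf order.
#' @export
ward_order <- function(expr_subset) {
  stopifnot(is.matrix(expr_subset))
  if (ncol(expr_subset) < 2) return(colnames(expr_subset))
  z <- zscore_rows(expr_subset)
  hc <- stats::hclust(stats::dist(t(z)), method = "ward.D2")
  colnames(expr_subset)[hc$order]
}

#' Split samples into high/low expressors by K-means
#'
#' Per-protein z-scoring, exclusion of samples missing more than half of the
#' subset, mean imputation of remaining gaps (z = 0), then Lloyd's K-means
#' with `k = 2` and the best of `n_restarts` random starts (restart seeds
#' derived from `seed`). The cluster whose centroid has the larger mean over
#' the subset is labeled `"high"`, so the labeling is invariant to cluster
#' index permutation.
#'
#' @param expr_subset Numeric matrix, proteins in rows (the module subset),
#'   samples in columns.
#' @param k Number of groups (default 2).
#' @param n_restarts Random restarts (default 50).
#' @param seed Integer seed controlling all restarts.
#' @param max_missing_frac Samples missing more than this fraction of the
#'   subset are excluded (default 0.5).
#' @return Object of class `aj_stratification`: list with `labels` (tibble:
#'   sample_id, aj_label, dist_high, dist_low, excluded), `protein_subset`,
#'   `centroids` (k x proteins, z-score units), `sample_order` (Ward leaf
#'   order of included samples), `n_excluded`, `tot_withinss`, `degenerate`.
#' @export
kmeans_split <- function(expr_subset, k = 2, n_restarts = 50, seed = 1,
                         max_missing_frac = 0.5) {
  stopifnot(is.matrix(expr_subset), k >= 2)
  miss_frac <- colMeans(is.na(expr_subset))
  excluded <- colnames(expr_subset)[miss_frac > max_missing_frac]
  kept <- setdiff(colnames(expr_subset), excluded)
  if (length(kept) < k) {
    abort(sprintf("Only %d usable sample(s) for k = %d.", length(kept), k),
          class = "ajnet_input_error")
  }
  z <- zscore_rows(expr_subset[, kept, drop = FALSE])
  pts <- t(z)  # samples x proteins
  degenerate <- nrow(unique(pts)) < k
  if (degenerate) {
    warn("Fewer distinct sample profiles than clusters; all samples in one group.")
    labels <- tibble(sample_id = kept, aj_label = "high",
                     dist_high = 0, dist_low = NA_real_, excluded = FALSE)
    centroids <- matrix(colMeans(pts), nrow = 1,
                        dimnames = list("high", rownames(expr_subset)))
    fitbest <- list(tot.withinss = 0)
  } else {
    set.seed(as.integer(seed))
    restart_seeds <- sample.int(.Machine$integer.max - 1L, n_restarts)
    fitbest <- NULL
    for (s in restart_seeds) {
      set.seed(s)
      ## Lloyd can warn at its iteration cap or error on an empty cluster;
      ## a failed restart is simply skipped
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(pts, centers = k, algorithm = "Lloyd",
                                       iter.max = 100)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(fitbest) || fit$tot.withinss < fitbest$tot.withinss) fitbest <- fit
    }
    if (is.null(fitbest)) {
      abort("K-means failed on every restart.", class = "ajnet_input_error")
    }
    ## orientation: larger centroid mean = "high"
    cent_mean <- rowMeans(fitbest$centers)
    ord <- order(-cent_mean)
    lab_names <- if (k == 2) c("high", "low") else paste0("group", seq_len(k))
    lab_of_cluster <- character(k)
    lab_of_cluster[ord] <- lab_names
    d <- as.matrix(stats::dist(rbind(fitbest$centers, pts)))[-(1:k), 1:k, drop = FALSE]
    labels <- tibble(
      sample_id = kept,
      aj_label = lab_of_cluster[fitbest$cluster],
      dist_high = d[, ord[1]],
      dist_low = d[, ord[k]],
      excluded = FALSE
    )
    centroids <- fitbest$centers[ord, , drop = FALSE]
    rownames(centroids) <- lab_names
    colnames(centroids) <- rownames(expr_subset)
  }
  if (length(excluded) > 0) {
    labels <- dplyr::bind_rows(labels, tibble(
      sample_id = excluded, aj_label = NA_character_,
      dist_high = NA_real_, dist_low = NA_real_, excluded = TRUE
    ))
  }
  structure(list(
    labels = labels,
    protein_subset = rownames(expr_subset),
    centroids = centroids,
    sample_order = ward_order(expr_subset[, kept, drop = FALSE]),
    n_excluded = length(excluded),
    tot_withinss = fitbest$tot.withinss,
    degenerate = degenerate,
    seed = as.integer(seed)
  ), class = "aj_stratification")
}

#' @export
print.aj_stratification <- function(x, ...) {
  tab <- table(x$labels$aj_label, useNA = "no")
  cat(sprintf("<aj_stratification> %s over %d proteins; %d excluded%s\n",
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              length(x$protein_subset), x$n_excluded,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.aj_stratification <- function(x, ...) {
  x$labels
}

#' @exportS3Method generics::glance
glance.aj_stratification <- function(x, ...) {
  tibble(
    n_high = sum(x$labels$aj_label == "high", na.rm = TRUE),
    n_low = sum(x$labels$aj_label == "low", na.rm = TRUE),
    n_excluded = x$n_excluded,
    n_proteins = length(x$protein_subset),
    tot_withinss = x$tot_withinss,
    degenerate = x$degenerate
  )
}

#' Write stratification labels to TSV
#' @param strat An `aj_stratification`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stratification <- function(strat, path) {
  readr::write_tsv(strat$labels, path)
  invisible(path)
}

#' Heatmap of module expression with stratification labels
#'
#' Samples in Ward leaf order on the x axis, module proteins on the y axis,
#' per-protein z-scores as fill, with a label strip underneath — the standard
#' module-expression heatmap view.
#'
#' @param object An `aj_stratification`.
#' @param expr Full expression matrix the stratification was computed from.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.aj_stratification <- function(object, expr, ...) {
  sub <- expr[object$protein_subset, object$sample_order, drop = FALSE]
  z <- zscore_rows(sub)
  long <- as_tibble(z, rownames = "protein_id") |>
    tidyr::pivot_longer(-"protein_id", names_to = "sample_id", values_to = "z") |>
    dplyr::mutate(sample_id = factor(.data$sample_id, levels = object$sample_order)) |>
    dplyr::left_join(object$labels[, c("sample_id", "aj_label")], by = "sample_id")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$protein_id,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$aj_label), scales = "free_x",
                        space = "free_x") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = NULL, fill = "z")
}
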