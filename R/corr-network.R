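#' Pairwise-complete Pearson correlation over proteins
#'
#' Computes the protein-by-protein Pearson correlation matrix over
#' pairwise-complete observations, together with the per-pair support count
#' (samples observed for both proteins). Pairs supported by fewer than
#' `min_pairs` samples, and pairs involving a zero-variance protein, are set
#' to `NA` and carry no edge downstream.
#'
#' @param expr Numeric matrix, proteins in rows, samples in columns; `NA`
#'   marks missing values.
#' @param min_pairs Minimum number of complete pairs required for a
#'   correlation to be defined (default 10).
#' @return A list of class `protein_correlation` with elements `r` (symmetric
#'   correlation matrix, unit diagonal where defined) and `n_pairs` (integer
#'   support matrix).
#' @export
correlate_proteins <- function(expr, min_pairs = 10) {
  stopifnot(is.matrix(expr), ncol(expr) >= 2)
  obs <- !is.na(expr)
  n_pairs <- obs %*% t(obs)
  r <- suppressWarnings(cor(t(expr), use = "pairwise.complete.obs"))
  r[n_pairs < min_pairs] <- NA_real_
  undef <- sum(is.na(r[upper.tri(r)]))
  if (undef > 0) {
    inform(sprintf("%d protein pairs have undefined correlation (low support or zero variance).",
                   undef))
  }
  diag(r)[!is.na(diag(r))] <- 1
  structure(list(r = r, n_pairs = n_pairs), class = "protein_correlation")
}

#' Sparsify a correlation matrix into a co-expression network
#'
#' Two-step filter: (1) drop every pair with `|r|` below `min_abs`; (2) for
#' each protein, rank its surviving incident edges by `|r|` (ties broken by
#' lexicographic partner id) and mark its `top_k` strongest. Under the
#' default `"union"` rule an edge is retained when at least one endpoint
#' marked it, so hub degree can exceed `top_k`; under `"mutual"` both
#' endpoints must mark it. Proteins losing all edges remain in the network as
#' isolated nodes.
#'
#' @param correlation A `protein_correlation` from [correlate_proteins()], or
#'   a plain symmetric correlation matrix.
#' @param min_abs Absolute-correlation floor (default 0.4).
#' @param top_k Number of strongest correlations marked per node (default 3).
#' @param rule `"union"` (default) or `"mutual"` top-k retention.
#' @return Tibble of class `coexpression_network` with columns protein_a,
#'   protein_b (a < b lexicographically), r, abs_r, n_pairs; attributes
#'   `nodes`, `min_abs`, `top_k`, `rule`.
#' @export
sparsify_network <- function(correlation, min_abs = 0.4, top_k = 3,
                             rule = c("union", "mutual")) {
  rule <- match.arg(rule)
  stopifnot(min_abs >= 0, top_k >= 1)
  if (inherits(correlation, "protein_correlation")) {
    R <- correlation$r
    NP <- correlation$n_pairs
  } else {
    R <- correlation
    NP <- matrix(NA_integer_, nrow(R), ncol(R), dimnames = dimnames(R))
  }
  stopifnot(nrow(R) == ncol(R))
  if (is.null(rownames(R))) {
    dimnames(R) <- list(paste0("V", seq_len(nrow(R))), paste0("V", seq_len(nrow(R))))
    dimnames(NP) <- dimnames(R)
  }
  nodes <- rownames(R)
  idx <- which(upper.tri(R) & !is.na(R) & abs(R) >= min_abs, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    edges <- tibble(protein_a = character(), protein_b = character(),
                    r = numeric(), abs_r = numeric(), n_pairs = integer())
    return(new_coexpression_network(edges, nodes, min_abs, top_k, rule))
  }
  a <- nodes[idx[, 1]]; b <- nodes[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  cand <- tibble(
    protein_a = a, protein_b = b,
    r = R[idx], abs_r = abs(R[idx]),
    n_pairs = as.integer(NP[idx])
  )
  cand <- dplyr::arrange(cand, .data$protein_a, .data$protein_b)
  ## per-node marking of the top_k strongest incident edges
  incident <- tibble(
    node = c(cand$protein_a, cand$protein_b),
    partner = c(cand$protein_b, cand$protein_a),
    edge = rep(seq_len(nrow(cand)), 2),
    abs_r = rep(cand$abs_r, 2)
  )
  marked <- incident |>
    dplyr::group_by(.data$node) |>
    dplyr::arrange(dplyr::desc(.data$abs_r), .data$partner, .by_group = TRUE) |>
    dplyr::slice_head(n = top_k) |>
    dplyr::ungroup()
  n_marks <- tabulate(marked$edge, nbins = nrow(cand))
  keep <- if (rule == "union") n_marks >= 1 else n_marks == 2
  new_coexpression_network(cand[keep, ], nodes, min_abs, top_k, rule)
}

new_coexpression_network <- function(edges, nodes, min_abs, top_k, rule) {
  structure(edges,
            nodes = nodes, min_abs = min_abs, top_k = top_k, rule = rule,
            class = c("coexpression_network", class(tibble())))
}

#' Nodes of a co-expression network
#' @param network A `coexpression_network`.
#' @return Character vector of protein ids, including isolated nodes.
#' @export
network_nodes <- function(network) {
  attr(network, "nodes")
}

#' Convert a co-expression network to an igraph graph
#'
#' Edge weights are `abs_r` (the similarity used by [mcl()]); the signed
#' correlation is kept as edge attribute `r`.
#'
#' @param network A `coexpression_network`.
#' @param drop_negative Drop negatively correlated edges instead of using
#'   their magnitude (default `FALSE`).
#' @return An igraph object including isolated nodes.
#' @export
as_igraph <- function(network, drop_negative = FALSE) {
  edges <- as_tibble(network)
  if (drop_negative) edges <- dplyr::filter(edges, .data$r > 0)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$protein_a, to = edges$protein_b,
                   weight = edges$abs_r, r = edges$r),
    directed = FALSE,
    vertices = data.frame(name = network_nodes(network))
  )
  g
}

#' Write network edges to TSV
#' @param network A `coexpression_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  readr::write_tsv(as_tibble(network), path)
  invisible(path)
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("<coexpression_network> %d nodes, %d edges (|r| >= %.2f, top-%d %s rule)\n",
              length(network_nodes(x)), nrow(x), attr(x, "min_abs"),
              attr(x, "top_k"), attr(x, "rule")))
  NextMethod()
}

#' Plot a co-expression network
#'
#' Fruchterman–Reingold layout with edges shaded by `|r|`; intended for the
#' sparsified network, where the module structure is visible by eye.
#'
#' @param object A `coexpression_network`.
#' @param highlight Optional character vector of protein ids drawn in color.
#' @param seed Layout seed (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.coexpression_network <- function(object, highlight = NULL, seed = 1, ...) {
  g <- as_igraph(object)
  ## isolated nodes clutter the layout; keep connected nodes only
  deg <- igraph::degree(g)
  g <- igraph::induced_subgraph(g, which(deg > 0))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(name = igraph::V(g)$name, x = xy[, 1], y = xy[, 2],
                  highlighted = igraph::V(g)$name %in% (highlight %||% character()))
  el <- igraph::as_data_frame(g, what = "edges")
  el <- dplyr::left_join(el, dplyr::rename(nodes, xa = "x", ya = "y"), by = c(from = "name")) |>
    dplyr::left_join(dplyr::rename(nodes, xb = "x", yb = "y"), by = c(to = "name"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = el,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb,
                                       alpha = .data$weight),
                          color = "grey40") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     color = .data$highlighted), size = 1.5) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey30", `TRUE` = "firebrick"),
                                guide = "none") +
    ggplot2::scale_alpha_continuous(range = c(0.2, 0.8), guide = "none") +
    ggplot2::theme_void()
}
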