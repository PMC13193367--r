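#' Markov Cluster Algorithm on a co-expression network
#'
#' From-scratch MCL. The network's `|r|` weights (plus a self-loop on every
#' node) are column-normalized into a stochastic flow matrix which is then
#' alternately expanded (matrix power), inflated (elementwise power followed
#' by column renormalization) and pruned (entries below `prune_below` zeroed,
#' then renormalized) until the flow stops changing. Clusters are read off
#' the attractors of the converged flow: rows with positive diagonal mass are
#' attractors, attractors reaching one another form one attractor system, and
#' every other node joins the system of the attractor holding the largest
#' share of its column (ties resolved to the smallest cluster id). Because
#' flow never crosses between disconnected components, each graph component
#' is clustered independently — which also keeps the computation fast on
#' sparse networks.
#'
#' @param network A `coexpression_network` from [sparsify_network()], or an
#'   igraph object with a `weight` edge attribute.
#' @param inflation Inflation exponent (default 2.0, the canonical MCL
#'   default; larger values give finer clusters).
#' @param expansion Expansion power (default 2).
#' @param self_loop Self-loop weight added to every node (default 1.0).
#' @param prune_below Flow entries below this are zeroed each iteration
#'   (default 1e-5).
#' @param max_iter Iteration cap (default 100); non-convergence yields the
#'   current interpretation with a warning and `converged = FALSE`.
#' @param tol Convergence threshold on the max absolute flow change
#'   (default 1e-8).
#' @param drop_negative Passed to [as_igraph()] when `network` is a
#'   `coexpression_network` (default `FALSE`: negative correlations
#'   contribute their magnitude).
#' @return Tibble of class `mcl_result` with columns protein_id, cluster_id,
#'   cluster_size (clusters numbered 1.. by decreasing size, ties by smallest
#'   member id); attributes `converged`, `iterations`.
#' @export
mcl <- function(network, inflation = 2, expansion = 2, self_loop = 1,
                prune_below = 1e-5, max_iter = 100, tol = 1e-8,
                drop_negative = FALSE) {
  stopifnot(inflation > 1, expansion >= 2, expansion == round(expansion))
  g <- if (inherits(network, "coexpression_network")) {
    as_igraph(network, drop_negative = drop_negative)
  } else network
  stopifnot(inherits(g, "igraph"))
  comps <- igraph::components(g)
  all_nodes <- igraph::V(g)$name
  membership <- integer(length(all_nodes))
  names(membership) <- all_nodes
  converged <- TRUE
  iterations <- 0L
  next_id <- 1L
  for (ci in seq_len(comps$no)) {
    nodes <- all_nodes[comps$membership == ci]
    if (length(nodes) == 1) {
      membership[nodes] <- next_id
      next_id <- next_id + 1L
      next
    }
    sub <- igraph::induced_subgraph(g, nodes)
    W <- igraph::as_adjacency_matrix(sub, attr = "weight", sparse = FALSE)
    W <- W[nodes, nodes, drop = FALSE]
    fit <- mcl_dense(W, inflation = inflation, expansion = expansion,
                     self_loop = self_loop, prune_below = prune_below,
                     max_iter = max_iter, tol = tol)
    converged <- converged && fit$converged
    iterations <- max(iterations, fit$iterations)
    membership[nodes] <- fit$membership + next_id - 1L
    next_id <- next_id + max(fit$membership)
  }
  if (!converged) warn("MCL did not converge within max_iter; returning current interpretation.")
  ## renumber clusters by decreasing size, ties by smallest member id
  sizes <- table(membership)
  ord <- order(-as.integer(sizes),
               vapply(names(sizes), function(k) min(names(membership)[membership == k]),
                      character(1)))
  remap <- setNames(seq_along(ord), names(sizes)[ord])
  cluster_id <- unname(remap[as.character(membership)])
  out <- tibble(protein_id = all_nodes, cluster_id = cluster_id) |>
    dplyr::add_count(.data$cluster_id, name = "cluster_size") |>
    dplyr::arrange(.data$cluster_id, .data$protein_id)
  structure(out, converged = converged, iterations = iterations,
            inflation = inflation, expansion = expansion,
            class = c("mcl_result", class(tibble())))
}

# Core dense MCL on one weight matrix (no zero rows; symmetric input).
# Returns membership 1..k in input node order.
mcl_dense <- function(W, inflation, expansion, self_loop, prune_below,
                      max_iter, tol) {
  n <- nrow(W)
  diag(W) <- self_loop
  M <- normalize_cols(W)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    E <- M
    for (k in seq_len(expansion - 1)) E <- E %*% M
    E <- E^inflation
    E <- normalize_cols(E)
    E[E < prune_below] <- 0
    E <- normalize_cols(E)
    delta <- max(abs(E - M))
    M <- E
    if (delta < tol) { converged <- TRUE; break }
  }
  interpret_mcl_flow(M, converged = converged, iterations = it)
}

normalize_cols <- function(M) {
  cs <- colSums(M)
  cs[cs == 0] <- 1
  sweep(M, 2, cs, "/")
}

# Read clusters off a converged flow matrix: attractor systems are the
# connected components of the attractor-attractor reachability graph; other
# nodes join the system of the attractor with the largest column share.
interpret_mcl_flow <- function(M, converged, iterations) {
  n <- nrow(M)
  attractors <- which(diag(M) > 0)
  if (length(attractors) == 0) attractors <- seq_len(n)  # degenerate fallback
  A <- M[attractors, attractors, drop = FALSE]
  adj <- (A > 0) | t(A > 0)
  ga <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = TRUE)
  sys <- igraph::components(ga)$membership  # per attractor
  ## order systems by smallest attractor index for deterministic ids
  first <- vapply(seq_len(max(sys)), function(s) min(attractors[sys == s]), integer(1))
  sys <- rank(first)[sys]
  membership <- integer(n)
  membership[attractors] <- sys
  rest <- setdiff(seq_len(n), attractors)
  for (j in rest) {
    w <- M[attractors, j]
    if (all(w == 0)) {
      membership[j] <- max(sys) + 1L  # unreachable: own singleton (should not occur)
      next
    }
    best <- w == max(w)
    membership[j] <- min(sys[best])
  }
  ## compact ids
  membership <- as.integer(factor(membership, levels = unique(sort(membership))))
  list(membership = membership, converged = converged, iterations = iterations)
}

#' Keep clusters of at least a minimum size
#'
#' @param clusters An `mcl_result` (or tibble with protein_id, cluster_id,
#'   cluster_size).
#' @param min_size Inclusive size threshold (default 10).
#' @return Tibble restricted to clusters with `cluster_size >= min_size`;
#'   original cluster ids preserved.
#' @export
filter_clusters <- function(clusters, min_size = 10) {
  dplyr::filter(as_tibble(clusters), .data$cluster_size >= min_size)
}

#' @export
print.mcl_result <- function(x, ...) {
  k <- length(unique(x$cluster_id))
  cat(sprintf("<mcl_result> %d nodes in %d clusters (converged: %s, %d iterations)\n",
              nrow(x), k, attr(x, "converged"), attr(x, "iterations")))
  NextMethod()
}

#' Write cluster assignments to TSV
#' @param clusters An `mcl_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  readr::write_tsv(as_tibble(clusters), path)
  invisible(path)
}
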