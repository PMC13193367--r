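# Independent oracles and small fixtures, coded straightforwardly and kept
# separate from the package implementation they check.

# Brute-force two-sided Fisher p for a 2 x c table: enumerate the first row
# by nested loops over all admissible cell values, second row forced by the
# column margins. Probabilities from dmultinom-free factorial arithmetic.
oracle_fisher_2xc <- function(counts) {
  stopifnot(nrow(counts) == 2)
  cs <- colSums(counts)
  r1 <- sum(counts[1, ])
  tab_prob <- function(tt) {
    exp(sum(lfactorial(rowSums(tt))) + sum(lfactorial(colSums(tt))) -
          lfactorial(sum(tt)) - sum(lfactorial(tt)))
  }
  p_obs <- tab_prob(counts)
  cells <- expand.grid(lapply(cs, function(m) 0:m))
  total_p <- 0
  for (i in seq_len(nrow(cells))) {
    row1 <- as.numeric(cells[i, ])
    if (sum(row1) != r1) next
    tt <- rbind(row1, cs - row1)
    pr <- tab_prob(tt)
    if (pr <= p_obs * (1 + 1e-7)) total_p <- total_p + pr
  }
  total_p
}

# Exact two-sided Wilcoxon by full enumeration of rank assignments.
oracle_wilcoxon_exact <- function(x, y) {
  N <- length(x) + length(y)
  rk <- rank(c(x, y))
  W <- sum(rk[seq_along(x)])
  sets <- combn(N, length(x))
  sums <- colSums(matrix(seq_len(N)[sets], nrow = length(x)))
  min(1, 2 * min(mean(sums <= W), mean(sums >= W)))
}

# Naive dense MCL oracle: no pruning, plain matrix iteration, and an
# independently written attractor interpretation.
oracle_mcl <- function(W, inflation = 2, expansion = 2, self_loop = 1,
                       max_iter = 200, tol = 1e-8) {
  n <- nrow(W)
  diag(W) <- self_loop
  M <- sweep(W, 2, colSums(W), "/")
  for (it in seq_len(max_iter)) {
    E <- M
    for (k in seq_len(expansion - 1)) E <- E %*% M
    E <- E^inflation
    E <- sweep(E, 2, colSums(E), "/")
    if (max(abs(E - M)) < tol) { M <- E; break }
    M <- E
  }
  attract <- which(diag(M) > 0)
  ## attractor systems: transitive closure of "shares positive flow"
  sys <- seq_along(attract)
  repeat {
    changed <- FALSE
    for (i in seq_along(attract)) for (j in seq_along(attract)) {
      if (sys[i] != sys[j] &&
          (M[attract[i], attract[j]] > 0 || M[attract[j], attract[i]] > 0)) {
        sys[sys == max(sys[i], sys[j])] <- min(sys[i], sys[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  membership <- integer(n)
  for (v in seq_len(n)) {
    w <- M[attract, v]
    if (v %in% attract) {
      membership[v] <- sys[match(v, attract)]
    } else if (any(w > 0)) {
      membership[v] <- min(sys[w == max(w)])
    } else {
      membership[v] <- 0L
    }
  }
  membership
}

# Same partition up to label permutation?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# Small default-structure cohort for fast tests: the planted world scaled
# down in protein count only (the module model itself is untouched).
small_cohort <- function(seed = 1, n_proteins = 120, n_samples = 60, ...) {
  simulate_cohort(cohort_config(n_proteins = n_proteins, n_samples = n_samples,
                                n_matrisome = 30, ...), seed = seed)
}

# Network -> MCL -> ORA -> AJ-cluster selection -> K-means, without the DE
# and distance stages; returns NULL when no cluster is enriched.
recover_stratification <- function(cohort, config = pipeline_config(), seed = 1) {
  corr <- correlate_proteins(cohort$expression, min_pairs = config$min_pairs)
  net <- sparsify_network(corr, min_abs = config$corr_min_abs,
                          top_k = config$top_k, rule = config$topk_rule)
  cl <- filter_clusters(mcl(net, inflation = config$mcl_inflation), config$min_cluster_size)
  if (nrow(cl) == 0) return(NULL)
  universe <- rownames(cohort$expression)
  best <- NULL
  for (cid in unique(cl$cluster_id)) {
    members <- cl$protein_id[cl$cluster_id == cid]
    e <- suppressMessages(ora(members, cohort$gene_sets, universe))
    row <- e[e$set_name == config$aj_set_name & e$tested, ]
    if (nrow(row) == 1 && row$adj_p < config$ora_adj_p &&
        (is.null(best) || row$adj_p < best$adj_p)) {
      best <- list(adj_p = row$adj_p, members = members)
    }
  }
  if (is.null(best)) return(NULL)
  strat <- suppressMessages(
    kmeans_split(cohort$expression[best$members, , drop = FALSE],
                 n_restarts = config$n_restarts, seed = seed))
  list(aj_cluster = sort(best$members), stratification = strat)
}

# Majority-matched agreement between inferred labels and planted truth.
label_accuracy <- function(strat, cohort) {
  lab <- tidy(strat)
  truth <- cohort$truth$aj_label_true[lab$sample_id]
  acc <- mean(lab$aj_label == truth, na.rm = TRUE)
  max(acc, 1 - acc)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

clique_fixture <- function(ids, w) {
  pairs <- t(combn(ids, 2))
  data.frame(a = pairs[, 1], b = pairs[, 2], w = w)
}

# MCL on disjoint cliques of the given sizes, edge weight 0.9.
mcl_on_cliques <- function(sizes, w = 0.9) {
  edges <- NULL
  start <- 0
  for (k in sizes) {
    ids <- sprintf("C%d_%d", start, seq_len(k))
    edges <- rbind(edges, clique_fixture(ids, w))
    start <- start + 1
  }
  nodes <- sort(unique(c(edges$a, edges$b)))
  n <- length(nodes)
  R <- diag(n); dimnames(R) <- list(nodes, nodes)
  for (i in seq_len(nrow(edges))) {
    R[edges$a[i], edges$b[i]] <- R[edges$b[i], edges$a[i]] <- edges$w[i]
  }
  mcl(sparsify_network(R, min_abs = 0, top_k = n))
}
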