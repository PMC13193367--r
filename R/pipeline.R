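#' Pipeline configuration
#'
#' All tunables of [run_aj_pipeline()] with their defaults: the
#' absolute-correlation floor 0.4 and per-node top-3 retention of the network
#' sparsification, the minimum reported cluster size 10, the canonical MCL
#' inflation 2.0 / expansion 2, the two-group K-means, and the dual
#' differential-expression rule p < 0.05 with adjusted p < 0.2.
#'
#' @param corr_min_abs Absolute-correlation floor (default 0.4).
#' @param top_k Strongest correlations kept per node (default 3).
#' @param topk_rule `"union"` or `"mutual"` retention (default `"union"`).
#' @param min_pairs Minimum pairwise-complete support for a correlation
#'   (default 10).
#' @param min_cluster_size Minimum cluster size carried forward (default 10).
#' @param mcl_inflation,mcl_expansion MCL parameters (defaults 2.0 and 2).
#' @param kmeans_k Number of patient groups (default 2).
#' @param n_restarts K-means restarts (default 50).
#' @param de_p,de_adj_p Dual differential-expression thresholds
#'   (defaults 0.05, 0.2).
#' @param ora_adj_p Adjusted-p threshold for calling a cluster enriched
#'   (default 0.05).
#' @param aj_set_name Gene-set name identifying the adherens-junction set
#'   (default "ADHERENS_JUNCTION").
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(corr_min_abs = 0.4, top_k = 3,
                            topk_rule = c("union", "mutual"),
                            min_pairs = 10, min_cluster_size = 10,
                            mcl_inflation = 2, mcl_expansion = 2,
                            kmeans_k = 2, n_restarts = 50,
                            de_p = 0.05, de_adj_p = 0.2, ora_adj_p = 0.05,
                            aj_set_name = "ADHERENS_JUNCTION") {
  topk_rule <- match.arg(topk_rule)
  stopifnot(corr_min_abs >= 0, corr_min_abs <= 1, top_k >= 1,
            min_cluster_size >= 1, mcl_inflation > 1, kmeans_k >= 2,
            de_p > 0, de_p < 1, de_adj_p > 0, de_adj_p <= 1,
            ora_adj_p > 0, ora_adj_p <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full proteome-to-stratification pipeline
#'
#' End-to-end orchestration: Pearson correlation network over proteins,
#' sparsification (|r| floor then per-node top-k), Markov clustering, per
#' cluster overrepresentation analysis, selection of the adherens-junction
#' cluster (smallest adjusted ORA p for `aj_set_name` among clusters of at
#' least `min_cluster_size`, required to pass `ora_adj_p`), K-means patient
#' stratification on that cluster's proteins, per-therapy Fisher association
#' tests, moderated-t differential expression between the strata, matrisome
#' partitioning, and histology-subgroup distance analysis on both the module
#' subset and the full proteome.
#'
#' When no cluster is enriched for the target set the run completes with
#' `aj_cluster = NULL` and all label-dependent stages skipped.
#'
#' @param expr Numeric expression matrix, proteins x samples.
#' @param clinical Clinical tibble (see [read_clinical()]).
#' @param gene_sets Named list of protein sets (see [read_gmt()]).
#' @param matrisome Optional matrisome annotation (tibble or id vector).
#' @param config A [pipeline_config()].
#' @param seed Integer seed (K-means restarts).
#' @return List of class `aj_pipeline` with elements `network`, `clusters`,
#'   `cluster_enrichment` (list of `ora_result`, one per large cluster),
#'   `aj_cluster` (protein ids or `NULL`), `aj_cluster_id`, `stratification`,
#'   `associations`, `de`, `matrisome_counts`, `distances_subset`,
#'   `distances_full`, `config`, `seed`.
#' @export
run_aj_pipeline <- function(expr, clinical, gene_sets, matrisome = NULL,
                            config = pipeline_config(), seed = 1) {
  stopifnot(inherits(config, "pipeline_config"))
  clinical <- as_tibble(clinical)
  missing_clin <- setdiff(colnames(expr), clinical$sample_id)
  if (length(missing_clin) > 0) {
    abort(paste0("Samples without clinical rows: ", paste(missing_clin, collapse = ", ")),
          class = "ajnet_input_error")
  }
  extra <- setdiff(clinical$sample_id, colnames(expr))
  if (length(extra) > 0) {
    inform(sprintf("%d clinical row(s) without expression data ignored.", length(extra)))
  }
  if (!config$aj_set_name %in% names(gene_sets)) {
    abort(sprintf("Gene set '%s' absent from the collection.", config$aj_set_name),
          class = "ajnet_input_error")
  }

  inform(sprintf("Stage 1/7 correlation network: %d proteins, %d samples.",
                 nrow(expr), ncol(expr)))
  corr <- correlate_proteins(expr, min_pairs = config$min_pairs)
  network <- sparsify_network(corr, min_abs = config$corr_min_abs,
                              top_k = config$top_k, rule = config$topk_rule)
  inform(sprintf("Stage 2/7 MCL: %d edges over %d nodes.",
                 nrow(network), length(network_nodes(network))))
  clusters <- mcl(network, inflation = config$mcl_inflation,
                  expansion = config$mcl_expansion)
  large <- filter_clusters(clusters, min_size = config$min_cluster_size)
  universe <- rownames(expr)

  inform(sprintf("Stage 3/7 cluster ORA: %d cluster(s) of size >= %d.",
                 length(unique(large$cluster_id)), config$min_cluster_size))
  cluster_ids <- unique(large$cluster_id)
  enrich <- lapply(cluster_ids, function(cid) {
    members <- large$protein_id[large$cluster_id == cid]
    suppressMessages(ora(members, gene_sets, universe))
  })
  names(enrich) <- as.character(cluster_ids)

  aj_adj_p <- vapply(enrich, function(e) {
    row <- e[e$set_name == config$aj_set_name & e$tested, ]
    if (nrow(row) == 0) NA_real_ else row$adj_p[1]
  }, numeric(1))
  aj_cluster_id <- NULL
  aj_cluster <- NULL
  if (any(!is.na(aj_adj_p)) && min(aj_adj_p, na.rm = TRUE) < config$ora_adj_p) {
    aj_cluster_id <- as.integer(names(which.min(aj_adj_p)))
    aj_cluster <- sort(large$protein_id[large$cluster_id == aj_cluster_id])
    inform(sprintf("AJ cluster: id %d, %d proteins, adj p = %.3g.",
                   aj_cluster_id, length(aj_cluster), min(aj_adj_p, na.rm = TRUE)))
  } else {
    inform("No cluster enriched for the target set; stratification stages skipped.")
  }

  strat <- NULL; assoc <- NULL; de <- NULL; matri <- NULL
  dist_subset <- NULL; dist_full <- NULL
  if (!is.null(aj_cluster)) {
    inform("Stage 4/7 K-means stratification.")
    strat <- kmeans_split(expr[aj_cluster, , drop = FALSE],
                          k = config$kmeans_k, n_restarts = config$n_restarts,
                          seed = seed)
    inform("Stage 5/7 categorical associations.")
    assoc <- suppressMessages(build_tables(clinical, strat))
    inform("Stage 6/7 differential expression.")
    de <- suppressMessages(fit_moderated_t(expr, tidy(strat),
                                           de_p = config$de_p,
                                           de_adj_p = config$de_adj_p))
    if (!is.null(matrisome)) matri <- matrisome_partition(de, matrisome)
    inform("Stage 7/7 histology distance analysis.")
    dists <- histology_distances(expr, clinical, strat, aj_cluster)
    dist_subset <- dists$subset
    dist_full <- dists$full
  }

  structure(list(
    network = network, clusters = clusters, cluster_enrichment = enrich,
    aj_cluster = aj_cluster, aj_cluster_id = aj_cluster_id,
    stratification = strat, associations = assoc, de = de,
    matrisome_counts = matri,
    distances_subset = dist_subset, distances_full = dist_full,
    config = config, seed = as.integer(seed)
  ), class = "aj_pipeline")
}

# Distance comparisons between tubular AJ-low/AJ-high, diffuse and mixed
# subgroups, on the module subset and the full proteome. Groups with < 2
# members are dropped with a message; NULL when the reference group is
# unusable.
histology_distances <- function(expr, clinical, strat, aj_cluster) {
  lab <- tidy(strat)
  df <- dplyr::left_join(clinical, lab[, c("sample_id", "aj_label")], by = "sample_id")
  grp <- dplyr::case_when(
    df$histology == "tubular" & df$aj_label == "low" ~ "tubular_aj_low",
    df$histology == "tubular" & df$aj_label == "high" ~ "tubular_aj_high",
    df$histology == "diffuse" ~ "diffuse",
    df$histology == "mixed" ~ "mixed",
    TRUE ~ NA_character_
  )
  groups <- setNames(grp, df$sample_id)
  ## samples lacking any module-protein value cannot enter the subset
  ## comparison; excluding them keeps 4C/4D-style panels on the same samples
  complete_samples <- colnames(expr)[colSums(is.na(expr[aj_cluster, , drop = FALSE])) == 0]
  dropped <- sum(!is.na(groups)) - sum(names(groups)[!is.na(groups)] %in% complete_samples)
  if (dropped > 0) {
    inform(sprintf("%d sample(s) with incomplete module data excluded from distance analysis.",
                   dropped))
  }
  groups <- groups[names(groups) %in% complete_samples]
  counts <- table(groups)
  if (is.na(counts["tubular_aj_low"]) || counts["tubular_aj_low"] < 2) {
    inform("Too few tubular AJ-low samples for distance analysis; skipped.")
    return(list(subset = NULL, full = NULL))
  }
  others <- intersect(c("tubular_aj_high", "diffuse", "mixed"),
                      names(counts)[counts >= 1])
  pairs <- c(lapply(others, function(g) c("tubular_aj_low", g)),
             list(c("tubular_aj_low", "tubular_aj_low")))
  list(
    subset = group_distances(expr, groups, subset = aj_cluster, pairs = pairs),
    full = group_distances(expr, groups, subset = NULL, pairs = pairs)
  )
}

#' @export
print.aj_pipeline <- function(x, ...) {
  cat(sprintf("<aj_pipeline> %d nodes, %d edges, %d clusters\n",
              length(network_nodes(x$network)), nrow(x$network),
              length(unique(x$clusters$cluster_id))))
  if (is.null(x$aj_cluster)) {
    cat("  no cluster enriched for the target set\n")
  } else {
    cat(sprintf("  AJ cluster %d (%d proteins); %s\n", x$aj_cluster_id,
                length(x$aj_cluster),
                paste(utils::head(x$aj_cluster, 5), collapse = ", ")))
    g <- glance(x$stratification)
    cat(sprintf("  stratification: %d high / %d low (%d excluded)\n",
                g$n_high, g$n_low, g$n_excluded))
    cat(sprintf("  differential expression: %d / %d proteins significant\n",
                sum(x$de$results$significant), nrow(x$de$results)))
  }
  invisible(x)
}

#' Flat key-value summary of a pipeline run
#'
#' @param x An `aj_pipeline`.
#' @param ... Unused.
#' @return Tibble (key, value) covering every stage: network size, cluster
#'   counts, AJ-cluster identity and enrichment, stratification sizes,
#'   association p-values, differential-expression and matrisome counts, and
#'   distance medians.
#' @exportS3Method generics::glance
glance.aj_pipeline <- function(x, ...) {
  kv <- list(
    n_nodes = length(network_nodes(x$network)),
    n_edges = nrow(x$network),
    n_clusters = length(unique(x$clusters$cluster_id)),
    n_large_clusters = length(x$cluster_enrichment),
    aj_cluster_found = as.numeric(!is.null(x$aj_cluster)),
    aj_cluster_id = x$aj_cluster_id %||% NA_real_,
    aj_cluster_size = if (is.null(x$aj_cluster)) NA_real_ else length(x$aj_cluster)
  )
  if (!is.null(x$stratification)) {
    g <- glance(x$stratification)
    kv$n_high <- g$n_high; kv$n_low <- g$n_low; kv$n_excluded <- g$n_excluded
  }
  if (!is.null(x$associations)) {
    for (i in seq_len(nrow(x$associations))) {
      nm <- paste0("p_", x$associations$association[i],
                   ifelse(is.na(x$associations$therapy[i]), "",
                          paste0("_", x$associations$therapy[i])))
      kv[[nm]] <- x$associations$p[i]
    }
  }
  if (!is.null(x$de)) {
    kv$de_n_tested <- nrow(x$de$results)
    kv$de_n_significant <- sum(x$de$results$significant)
  }
  if (!is.null(x$matrisome_counts)) {
    kv$matrisome_up_in_low <- x$matrisome_counts$n_up_in_low
    kv$matrisome_up_in_high <- x$matrisome_counts$n_up_in_high
  }
  add_dist <- function(kv, d, tag) {
    if (is.null(d)) return(kv)
    for (i in seq_len(nrow(d))) {
      kv[[paste0("median_", tag, "_", d$group_a[i], "_vs_", d$group_b[i])]] <- d$median[i]
    }
    kv
  }
  kv <- add_dist(kv, x$distances_subset, "subset")
  kv <- add_dist(kv, x$distances_full, "full")
  tibble(key = names(kv), value = as.numeric(unlist(kv)))
}

#' Write all pipeline reports to a directory
#'
#' Emits edges.tsv, clusters.tsv, enrichment_cluster_<id>.tsv,
#' stratification.tsv, associations.tsv, de.tsv, distances_subset.tsv,
#' distances_full.tsv and summary.tsv (flat key-value), as applicable.
#'
#' @param pipeline An `aj_pipeline`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_pipeline_reports <- function(pipeline, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_network(pipeline$network, file.path(dir, "edges.tsv"))
  write_clusters(pipeline$clusters, file.path(dir, "clusters.tsv"))
  for (cid in names(pipeline$cluster_enrichment)) {
    write_enrichment(pipeline$cluster_enrichment[[cid]],
                     file.path(dir, sprintf("enrichment_cluster_%s.tsv", cid)))
  }
  if (!is.null(pipeline$stratification)) {
    write_stratification(pipeline$stratification, file.path(dir, "stratification.tsv"))
  }
  if (!is.null(pipeline$associations)) {
    write_associations(pipeline$associations, file.path(dir, "associations.tsv"))
  }
  if (!is.null(pipeline$de)) write_de(pipeline$de, file.path(dir, "de.tsv"))
  if (!is.null(pipeline$distances_subset)) {
    write_distances(pipeline$distances_subset, file.path(dir, "distances_subset.tsv"))
    write_distances(pipeline$distances_full, file.path(dir, "distances_full.tsv"))
  }
  readr::write_tsv(glance(pipeline), file.path(dir, "summary.tsv"))
  invisible(dir)
}
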