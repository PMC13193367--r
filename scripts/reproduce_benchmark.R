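#!/usr/bin/env Rscript

# Optional cohort-scale reproduction on the deposited study matrix.
#
# Requires a local download (not fetched here; the script runs offline):
#   * the preprocessed log2 protein x sample expression TSV
#   * a clinical annotation CSV in the package's format (see ?read_clinical)
#   * the adherens-junction gene set in GMT format
#
# Usage:
#   Rscript scripts/reproduce_benchmark.R \
#     --expression expr.tsv --clinical clinical.csv --gmt sets.gmt \
#     [--out results/benchmark] [--seed 1]
#
# It reruns the pipeline on the real matrix and prints the quantities to
# compare with the published analysis: the number of differentially
# expressed proteins under the dual rule (p < 0.05 and adjusted p < 0.2),
# and the median Euclidean distances between tubular AJ-low samples and the
# other histological subgroups on the module subset and the full proteome.

suppressPackageStartupMessages(library(ajnet))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}

expr_path <- get_arg("--expression")
clin_path <- get_arg("--clinical")
gmt_path <- get_arg("--gmt")
out_dir <- get_arg("--out", "results/benchmark")
seed <- as.integer(get_arg("--seed", "1"))

if (is.null(expr_path) || is.null(clin_path) || is.null(gmt_path)) {
  stop("--expression, --clinical and --gmt are required; see the header comment.")
}

expr <- read_expression(expr_path)
clinical <- read_clinical(clin_path)
gene_sets <- read_gmt(gmt_path)

pipeline <- run_aj_pipeline(expr, clinical, gene_sets, seed = seed)
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
write_pipeline_reports(pipeline, out_dir)

if (!is.null(pipeline$de)) {
  cat(sprintf("Differentially expressed proteins (dual rule): %d of %d\n",
              sum(tidy(pipeline$de)$significant), nrow(tidy(pipeline$de))))
}
show_medians <- function(d, what) {
  if (is.null(d)) return(invisible())
  cat(what, "distance medians:\n")
  for (i in seq_len(nrow(d))) {
    cat(sprintf("  %s vs %s: %.2f (n_pairs = %d)\n",
                d$group_a[i], d$group_b[i], d$median[i], d$n_pairs[i]))
  }
}
show_medians(pipeline$distances_subset, "Module-subset")
show_medians(pipeline$distances_full, "Full-proteome")
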