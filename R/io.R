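#' Read a protein expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds protein ids, whose
#' header row holds sample ids, and whose cells hold decimal log2 intensities.
#' Empty cells (and, case-insensitively, `NA`/`NaN`) are missing values.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, proteins in rows, samples in columns.
#' @export
read_expression <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        na = character(), progress = FALSE)
  if (ncol(df) < 3) abort("Expression TSV needs >= 2 sample columns.", class = "ajnet_format_error")
  ids <- df[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate protein id(s): ", paste(unique(dup), collapse = ", ")),
          class = "ajnet_format_error")
  }
  samp <- colnames(df)[-1]
  if (anyDuplicated(samp)) {
    abort(paste0("Duplicate sample id(s): ",
                 paste(unique(samp[duplicated(samp)]), collapse = ", ")),
          class = "ajnet_format_error")
  }
  cells <- as.matrix(df[, -1])
  cells[grepl("^\\s*(na|nan)?\\s*$", cells, ignore.case = TRUE)] <- NA_character_
  X <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(X) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("Non-numeric cell at protein %s, sample %s: '%s'",
                  ids[bad[1, 1]], samp[bad[1, 2]], cells[bad[1, 1], bad[1, 2]]),
          class = "ajnet_format_error")
  }
  dimnames(X) <- list(ids, samp)
  empty_rows <- rownames(X)[rowSums(!is.na(X)) == 0]
  if (length(empty_rows) > 0) {
    abort(paste0("All-missing protein row(s): ", paste(empty_rows, collapse = ", ")),
          class = "ajnet_format_error")
  }
  if (nrow(X) < 2) abort("Expression matrix needs >= 2 proteins.", class = "ajnet_format_error")
  inform(sprintf("Read expression matrix: %d proteins x %d samples, %.1f%% missing.",
                 nrow(X), ncol(X), 100 * mean(is.na(X))))
  X
}

#' Write a protein expression matrix to TSV
#'
#' Canonical format: 6-decimal fixed notation, empty cell for missing; a
#' `write_expression()` / [read_expression()] round trip is byte-identical.
#'
#' @param x Numeric matrix with protein row names and sample column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  cells <- matrix(sprintf("%.6f", x), nrow = nrow(x))
  cells[is.na(x)] <- ""
  lines <- c(paste(c("protein_id", colnames(x)), collapse = "\t"),
             vapply(seq_len(nrow(x)),
                    function(i) paste(c(rownames(x)[i], cells[i, ]), collapse = "\t"),
                    character(1)))
  writeLines(lines, path)
  invisible(path)
}

.clinical_vocab <- list(
  therapy = c("FLOT", "CROSS"),
  response = c("major", "minor"),
  histology = c("tubular", "diffuse", "mixed", "other"),
  ypT = as.character(0:4),
  ypN = as.character(0:3),
  L = c("0", "1", "unknown"),
  V = c("0", "1", "unknown"),
  Pn = c("0", "1", "unknown"),
  ulceration = c("none", "few", "abundant"),
  inflammation = c("none", "few", "abundant"),
  gender = c("male", "female"),
  age_class = c("lt65", "ge65")
)

#' Read a clinical annotation table from CSV
#'
#' Columns: sample_id plus any of therapy, response, histology, ypT, ypN, L,
#' V, Pn, ulceration, inflammation, gender, age_class. Vocabularies are
#' closed: an unrecognized token is an error, while an empty cell or `NA` is
#' a missing value.
#'
#' @param path Path to the CSV file.
#' @return Tibble with one row per sample.
#' @export
read_clinical <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!"sample_id" %in% colnames(df)) {
    abort("Clinical CSV must have a sample_id column.", class = "ajnet_format_error")
  }
  if (anyDuplicated(df$sample_id)) {
    abort("Duplicate sample_id in clinical table.", class = "ajnet_format_error")
  }
  for (col in intersect(names(.clinical_vocab), colnames(df))) {
    vals <- df[[col]]
    bad <- setdiff(unique(vals[!is.na(vals)]), .clinical_vocab[[col]])
    if (length(bad) > 0) {
      abort(sprintf("Unknown token(s) in clinical column %s: %s", col,
                    paste(bad, collapse = ", ")),
            class = "ajnet_format_error")
    }
  }
  as_tibble(df)
}

#' Write a clinical annotation table to CSV
#' @param clinical Tibble as returned by [read_clinical()] or [simulate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  readr::write_csv(clinical, path, na = "")
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields name, description,
#' then member ids.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors; descriptions kept as an attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    abort(sprintf("GMT line %d has fewer than 3 fields.", bad[1]),
          class = "ajnet_format_error")
  }
  nms <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nms)) {
    abort("Duplicate gene-set names in GMT file.", class = "ajnet_format_error")
  }
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- nms
  attr(sets, "description") <- setNames(vapply(parts, `[[`, character(1), 2), nms)
  sets
}

#' Write a gene-set collection to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional named descriptions; defaults to the set name.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  desc <- description %||% attr(sets, "description") %||% setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a matrisome annotation table from TSV
#'
#' Two tab-separated columns: protein_id and category (e.g. "Core matrisome",
#' "ECM Regulators").
#'
#' @param path Path to the TSV file.
#' @return Tibble (protein_id, category).
#' @export
read_matrisome <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!all(c("protein_id", "category") %in% colnames(df))) {
    abort("Matrisome TSV needs protein_id and category columns.",
          class = "ajnet_format_error")
  }
  if (anyDuplicated(df$protein_id)) {
    abort("Duplicate protein_id in matrisome table.", class = "ajnet_format_error")
  }
  as_tibble(df)
}

#' Write a matrisome annotation table to TSV
#' @param matrisome Tibble (protein_id, category).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrisome <- function(matrisome, path) {
  readr::write_tsv(matrisome, path)
  invisible(path)
}

#' Write a simulated cohort to a directory
#'
#' Emits expression.tsv, clinical.csv, gene_sets.gmt, matrisome.tsv and
#' ground_truth.tsv (sample-level true labels; module membership is recorded
#' in the GMT-like truth columns).
#'
#' @param cohort An `aj_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "aj_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.csv"))
  write_gmt(cohort$gene_sets, file.path(dir, "gene_sets.gmt"))
  write_matrisome(cohort$matrisome, file.path(dir, "matrisome.tsv"))
  truth <- tibble(
    sample_id = names(cohort$truth$aj_label_true),
    aj_label_true = unname(cohort$truth$aj_label_true)
  )
  readr::write_tsv(truth, file.path(dir, "ground_truth.tsv"))
  writeLines(cohort$truth$module_proteins, file.path(dir, "module_proteins.txt"))
  invisible(dir)
}
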