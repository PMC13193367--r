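test_that("cohort generation is deterministic in config + seed", {
  cfg <- cohort_config(n_proteins = 80, n_samples = 40)
  a <- simulate_cohort(cfg, seed = 1)
  b <- simulate_cohort(cfg, seed = 1)
  c <- simulate_cohort(cfg, seed = 2)
  expect_identical(a$expression, b$expression)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$gene_sets, b$gene_sets)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$expression, c$expression))
})

test_that("configuration is validated", {
  expect_error(cohort_config(module_size = 50, n_proteins = 40),
               class = "ajnet_config_error")
  expect_error(cohort_config(missing_rate = 1), class = "ajnet_config_error")
  expect_error(cohort_config(histology_mix = c(tubular = 0.5, diffuse = 0.2,
                                               mixed = 0.2, other = 0.2)),
               class = "ajnet_config_error")
})

test_that("planted module matches the closed-form correlation r = l^2/(l^2+s^2)", {
  ## theory: shared factor with loading 1.5 over unit noise gives
  ## 2.25 / 3.25 ~ 0.69 expected pairwise correlation inside the module
  co <- simulate_cohort(cohort_config(n_proteins = 100, n_samples = 300,
                                      missing_rate = 0), seed = 42)
  mod <- co$truth$module_proteins
  R <- cor(t(co$expression[mod, ]))
  mean_abs_r <- mean(abs(R[upper.tri(R)]))
  expect_gt(mean_abs_r, 0.5)
  expect_lt(abs(mean_abs_r - 2.25 / 3.25), 0.12)
  ## background proteins are uncorrelated
  bg <- setdiff(rownames(co$expression), unlist(c(mod, co$truth$decoy_modules,
                                                  co$truth$ecm_up_proteins)))[1:20]
  Rb <- cor(t(co$expression[bg, ]))
  expect_lt(mean(abs(Rb[upper.tri(Rb)])), 0.12)
})

test_that("marginal AJ-low frequency per histology matches the config", {
  co <- simulate_cohort(cohort_config(n_samples = 1000, n_proteins = 30,
                                      module_size = 5, n_decoy_modules = 2,
                                      n_matrisome = 5, n_ecm_up = 2), seed = 3)
  truth_low <- co$truth$aj_label_true == "low"
  for (h in c("tubular", "diffuse", "mixed")) {
    sel <- co$clinical$histology == h
    expect_lt(abs(mean(truth_low[sel]) - co$config$frac_aj_low_by_histology[[h]]),
              0.05)
  }
})

test_that("clinical vocabularies and structure are respected", {
  co <- small_cohort(seed = 5)
  cl <- co$clinical
  expect_identical(cl$sample_id, colnames(co$expression))
  expect_true(all(cl$therapy %in% c("FLOT", "CROSS")))
  expect_true(all(cl$response %in% c("major", "minor")))
  expect_true(all(cl$ulceration %in% c("none", "few", "abundant")))
  expect_true(all(cl$Pn %in% c("0", "1", "unknown")))
  ## every expression row keeps at least one observed value
  expect_true(all(rowSums(!is.na(co$expression)) >= 1))
  ## the AJ gene set contains the full planted module
  expect_true(all(co$truth$module_proteins %in% co$gene_sets$ADHERENS_JUNCTION))
})

test_that("with no planted signal the stratification carries no label information", {
  ## null world: lambda = 0, delta = 0; K-means on the (pure noise) module
  ## splits at random, so downstream Fisher p-values are ~uniform and
  ## accuracy stays at chance
  accs <- numeric(50)
  ps <- numeric(50)
  for (s in seq_len(50)) {
    co <- simulate_cohort(cohort_config(n_proteins = 60, module_loading = 0,
                                        module_shift = 0, n_decoy_modules = 1,
                                        n_matrisome = 10, n_random_sets = 3),
                          seed = 7000 + s)
    st <- suppressMessages(kmeans_split(co$expression[co$truth$module_proteins, ],
                                        seed = s))
    accs[s] <- label_accuracy(st, co)
    cl <- co$clinical
    cl$aj <- tidy(st)$aj_label[match(cl$sample_id, tidy(st)$sample_id)]
    fl <- cl[cl$therapy == "FLOT", ]
    tab <- table(fl$aj, fl$response)
    ps[s] <- if (all(dim(tab) >= 2)) fisher_exact(unclass(tab)) else NA
  }
  expect_lte(mean(accs), 0.6)
  expect_lt(abs(mean(ps < 0.05, na.rm = TRUE) - 0.05), 0.1)
})

test_that("cohort round-trips through the on-disk formats", {
  co <- small_cohort(seed = 11)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expr2 <- suppressMessages(read_expression(file.path(dir, "expression.tsv")))
  expect_equal(expr2, co$expression, tolerance = 1e-6)
  clin2 <- read_clinical(file.path(dir, "clinical.csv"))
  expect_identical(clin2, co$clinical)
  sets2 <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_identical(sets2$ADHERENS_JUNCTION, co$gene_sets$ADHERENS_JUNCTION)
  mat2 <- read_matrisome(file.path(dir, "matrisome.tsv"))
  expect_identical(mat2, co$matrisome)
})
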