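test_that("fisher_exact reproduces the study's printed statistics", {
  ## therapy arms vs response
  expect_equal(round(fisher_exact(matrix(c(17, 55, 22, 63), 2, byrow = TRUE)), 2),
               0.85)
  ## lymphovascular invasion in FLOT major/minor responders
  expect_equal(signif(fisher_exact(matrix(c(17, 0, 23, 32), 2, byrow = TRUE)), 3),
               8.36e-6)
  ## vascular invasion
  expect_equal(round(fisher_exact(matrix(c(17, 0, 37, 18), 2, byrow = TRUE)), 4),
               0.0041)
  ## nodal stage, 4 levels x 2 response groups
  ypN <- matrix(c(13, 16, 4, 15, 0, 6, 0, 18), nrow = 2)
  expect_equal(round(fisher_exact(ypN), 4), 0.0011)
  ## module-expression group vs FLOT response
  expect_equal(signif(fisher_exact(matrix(c(16, 1, 30, 23), 2, byrow = TRUE)), 3),
               6.74e-3)
})

test_that("fisher_exact equals the brute-force oracle on random small tables", {
  set.seed(13)
  for (rep in 1:60) {
    dims <- sample(list(c(2, 2), c(2, 3)), 1)[[1]]
    tab <- matrix(rpois(prod(dims), 2), dims[1], dims[2])
    if (sum(tab) == 0 || sum(tab) > 20) next
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab), oracle_fisher_2xc(tab), tolerance = 1e-10)
    ## and against the reference implementation
    expect_equal(fisher_exact(tab), fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("fisher_exact invariances and degenerate cases", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  set.seed(17)
  for (rep in 1:10) {
    tab <- matrix(rpois(6, 3) + 1, 2, 3)
    p <- fisher_exact(tab)
    expect_equal(fisher_exact(t(tab)), p, tolerance = 1e-10)
    expect_equal(fisher_exact(tab[, sample(3)]), p, tolerance = 1e-10)
    expect_equal(fisher_exact(tab[2:1, ]), p, tolerance = 1e-10)
  }
  ## proportional rows carry no association
  expect_equal(fisher_exact(matrix(c(2, 4, 3, 6), 2)), 1, tolerance = 1e-10)
  ## zero margin is degenerate, not an error
  expect_warning(p <- fisher_exact(matrix(c(3, 5, 0, 0), 2)), "Degenerate")
  expect_equal(p, 1)
  expect_error(fisher_exact(matrix(c(600, 1, 1, 600), 2)),
               class = "ajnet_input_error")
  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), 2)),
               class = "ajnet_input_error")
})

test_that("Monte Carlo mode converges to the exact p-value", {
  tab <- matrix(c(8, 3, 2, 9), 2)
  p_exact <- fisher_exact(tab)
  p_mc <- fisher_exact(tab, monte_carlo = TRUE, n_mc = 1e5, seed = 4)
  se <- sqrt(p_exact * (1 - p_exact) / 1e5)
  expect_lt(abs(p_mc - p_exact), 3 * se + 2e-5)
})

test_that("wilcoxon_ranksum exact values and enumeration equivalence", {
  ## extreme configuration: all of x below all of y
  expect_equal(wilcoxon_ranksum(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)
  expect_equal(wilcoxon_ranksum(5, 5), 1)
  set.seed(23)
  for (rep in 1:30) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(100, nx); y <- sample(200 + seq_len(100), ny)
    x <- x + runif(nx) * 0.1; y <- y + runif(ny) * 0.1  # no ties
    xy <- sample(c(x, y)); x <- xy[seq_len(nx)]; y <- xy[-seq_len(nx)]
    expect_equal(wilcoxon_ranksum(x, y), oracle_wilcoxon_exact(x, y),
                 tolerance = 1e-12)
    expect_equal(wilcoxon_ranksum(x, y),
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("wilcoxon normal approximation with ties tracks the reference", {
  set.seed(29)
  for (rep in 1:10) {
    x <- sample(5, 15, replace = TRUE)
    y <- sample(6, 18, replace = TRUE)
    got <- wilcoxon_ranksum(x, y)
    want <- suppressWarnings(wilcox.test(x, y, correct = TRUE)$p.value)
    expect_equal(got, want, tolerance = 1e-8)
  }
  expect_error(wilcoxon_ranksum(numeric(), 1:3), class = "ajnet_input_error")
})

test_that("wilcoxon type-I error at 8+8 is nominal", {
  set.seed(31)
  rej <- vapply(1:400, function(i) {
    wilcoxon_ranksum(rnorm(8), rnorm(8)) < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.035)
})

test_that("build_tables reconstructs the association surface", {
  co <- small_cohort(seed = 51)
  mod <- co$truth$module_proteins
  st <- suppressMessages(kmeans_split(co$expression[mod, ], seed = 51))
  tests <- suppressMessages(build_tables(co$clinical, st))
  expect_s3_class(tests, "association_tests")
  expect_true(all(c("aj_x_response", "aj_x_histology", "histology_x_response")
                  %in% tests$association))
  expect_true(all(tests$p >= 0 & tests$p <= 1))
  ## n never exceeds the cohort and excludes unknowns
  expect_true(all(tests$n <= nrow(co$clinical)))
  pn <- tests[tests$association == "response_x_Pn", ]
  if (nrow(pn) > 0) {
    expect_false(any(vapply(pn$table, function(tt) "unknown" %in% colnames(tt),
                            logical(1))))
  }
  ## degenerate clinical: all responses identical -> response tables skipped
  cl2 <- co$clinical
  cl2$response <- "minor"
  t2 <- suppressMessages(build_tables(cl2, st))
  expect_false(any(grepl("response", t2$association)))
})

test_that("reconstructed module-vs-response table from printed percentages", {
  ## 94% / 6% of 17 major responders and 57% / 43% of 53 minor responders
  tab <- matrix(c(16, 1, 30, 23), 2, byrow = TRUE,
                dimnames = list(c("major", "minor"), c("high", "low")))
  expect_equal(signif(fisher_exact(tab), 3), 6.74e-3)
})
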