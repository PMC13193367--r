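make_two_group <- function(n_prot = 50, n1 = 8, n2 = 8, shift = 0, seed = 1,
                           var_spread = TRUE) {
  set.seed(seed)
  x <- matrix(rnorm(n_prot * (n1 + n2)), n_prot)
  if (var_spread) x <- x * sqrt(1 / rchisq(n_prot, df = 6) * 6)
  x[, seq_len(n1)] <- x[, seq_len(n1)] + shift
  dimnames(x) <- list(sprintf("P%03d", seq_len(n_prot)),
                      sprintf("S%03d", seq_len(n1 + n2)))
  labels <- setNames(rep(c("low", "high"), c(n1, n2)), colnames(x))
  list(x = x, labels = labels)
}

test_that("with d0 = 0 the moderated t reduces to the ordinary two-sample t", {
  d <- make_two_group(shift = 0.5, seed = 2)
  fit <- fit_moderated_t(d$x, d$labels, d0_override = 0)
  res <- tidy(fit)
  for (i in c(1, 17, 50)) {
    tt <- t.test(d$x[i, d$labels == "low"], d$x[i, d$labels == "high"],
                 var.equal = TRUE)
    expect_equal(res$t_mod[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-10)
    expect_equal(res$log2fc[i], unname(diff(rev(tt$estimate))), tolerance = 1e-10)
  }
})

test_that("moderated results agree with the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  d <- make_two_group(n_prot = 300, shift = 0.4, seed = 5)
  fit <- fit_moderated_t(d$x, d$labels)
  design <- cbind(1, as.numeric(d$labels == "low"))
  lf <- limma::eBayes(limma::lmFit(d$x, design))
  expect_equal(fit$prior$d0, lf$df.prior, tolerance = 1e-6)
  expect_equal(fit$prior$s0_sq, lf$s2.prior, tolerance = 1e-6)
  expect_equal(tidy(fit)$t_mod, lf$t[, 2], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(tidy(fit)$p, lf$p.value[, 2], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("type-I error is nominal under the null", {
  ## scaled-down version of the 100-seed null harness (full version in the
  ## acceptance suite)
  fracs <- vapply(1:10, function(s) {
    d <- make_two_group(n_prot = 400, n1 = 20, n2 = 20, seed = 100 + s)
    mean(tidy(fit_moderated_t(d$x, d$labels))$p < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.05), 0.015)
})

test_that("planted shift is detected with the right sign", {
  ## low group shifted down by 2: log2fc (low - high) < 0, all significant
  hits <- 0
  for (s in 1:10) {
    ## unit noise as in the planted world: shift 2, sd 1, n = 20 + 20
    d <- make_two_group(n_prot = 200, n1 = 20, n2 = 20, seed = 200 + s,
                        var_spread = FALSE)
    mod <- sample(rownames(d$x), 10)
    d$x[mod, d$labels == "low"] <- d$x[mod, d$labels == "low"] - 2
    res <- tidy(suppressMessages(fit_moderated_t(d$x, d$labels)))
    sub <- res[res$protein_id %in% mod, ]
    if (all(sub$significant) && all(sub$log2fc < 0)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("invariants: df bookkeeping, sign coherence, dual rule, order invariance", {
  d <- make_two_group(n_prot = 120, shift = 0.6, seed = 9)
  d$x[3, 1:14] <- NA  # force exclusion: < 3 obs in the low group (n1 = 8)
  fit <- suppressMessages(fit_moderated_t(d$x, d$labels))
  res <- tidy(fit)
  expect_false("P003" %in% res$protein_id)
  expect_equal(res$df_total, fit$prior$d0 + res$n_low + res$n_high - 2,
               tolerance = 1e-12)
  expect_true(all(sign(res$t_mod) == sign(res$log2fc)))
  expect_identical(res$significant, res$p < 0.05 & res$adj_p < 0.2)
  expect_true(all(res$adj_p >= res$p - 1e-12))
  ## permuting protein rows does not change any per-protein result
  perm <- sample(nrow(d$x))
  fit2 <- suppressMessages(fit_moderated_t(d$x[perm, ], d$labels))
  res2 <- tidy(fit2)
  expect_equal(res2[order(res2$protein_id), ], res[order(res$protein_id), ],
               tolerance = 1e-12)
})

test_that("prior estimation recovers known hyperparameters", {
  ## simulate variances from the scaled inverse-chi-square prior d0 = 4,
  ## s0^2 = 1 at residual df 18 and check moment recovery within 20%
  set.seed(77)
  n_prot <- 5000; df <- 18
  true_s2 <- 4 * 1 / rchisq(n_prot, df = 4)
  s2 <- true_s2 * rchisq(n_prot, df = df) / df
  prior <- ajnet:::fit_variance_prior(s2, rep(df, n_prot))
  expect_lt(abs(prior$d0 - 4) / 4, 0.2)
  expect_lt(abs(prior$s0_sq - 1), 0.2)
})

test_that("matrisome partition counts significant proteins by direction", {
  d <- make_two_group(n_prot = 150, n1 = 20, n2 = 20, seed = 33)
  up_in_low <- sprintf("P%03d", 1:5)
  up_in_high <- sprintf("P%03d", 6:8)
  d$x[up_in_low, d$labels == "low"] <- d$x[up_in_low, d$labels == "low"] + 3
  d$x[up_in_high, d$labels == "high"] <- d$x[up_in_high, d$labels == "high"] + 3
  fit <- fit_moderated_t(d$x, d$labels)
  matri <- c(up_in_low, up_in_high, sprintf("P%03d", 100:120))
  part <- matrisome_partition(fit, matri)
  expect_equal(part$n_up_in_low, 5)
  expect_equal(part$n_up_in_high, 3)
  ## empty matrisome
  empty <- matrisome_partition(fit, character())
  expect_equal(empty$n_up_in_low + empty$n_up_in_high, 0)
})
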