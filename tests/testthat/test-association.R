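std_design <- function(seed = 1, n = 40, n_taxa = 12) {
  cfg <- sim_config(n_samples = n, n_taxa = n_taxa, n_loci = 5, seed = seed)
  taxa <- filter_taxa(simulate_taxa_table(cfg))
  build_design(taxa)
}

test_that("build_design standardizes, drops degenerate columns and inverts", {
  cfg <- sim_config(n_samples = 30, n_taxa = 10, seed = 4)
  taxa <- filter_taxa(simulate_taxa_table(cfg))
  d <- build_design(taxa)
  expect_lt(max(abs(colMeans(d$X))), 1e-10)
  expect_lt(max(abs(apply(d$X, 2, sd) - 1)), 1e-10)
  expect_setequal(unique(d$col_info$predictor_class), c("taxon", "covariate"))
  # round trip: de-standardizing recovers CLR values
  raw <- destandardize_design(d)
  clr <- clr_transform(taxa)
  expect_lt(max(abs(raw[, colnames(clr)] - clr)), 1e-10)
  # constant covariate is dropped with a message
  meta2 <- taxa$sample_meta
  meta2$subtype <- 1
  expect_message(d2 <- build_design(taxa, meta2), "zero-variance")
  expect_false("subtype" %in% d2$col_info$predictor_id)
  # sample mismatch errors
  meta3 <- taxa$sample_meta
  meta3$sample_id[1] <- "nope"
  expect_error(build_design(taxa, meta3), "mismatch")
})

test_that("locus lasso honours the penalty: full shrinkage, OLS limit, support recovery", {
  # full-rank gaussian design (a CLR design is rank-deficient by one, so
  # the least-squares limit would not be unique there)
  set.seed(5)
  n <- 40
  X <- scale(matrix(rnorm(n * 12), n, 12))
  colnames(X) <- paste0("x", 1:12)
  y <- drop(X %*% rnorm(ncol(X), 0, 0.3)) + rnorm(n)
  # enormous penalty shrinks everything to zero
  b_inf <- fit_locus_lasso(y, X, lambda_rule = 100)
  expect_true(all(b_inf == 0))
  # zero penalty reproduces least squares
  b0 <- fit_locus_lasso(y, X, lambda_rule = 0)
  ols <- coef(lm(y ~ X))
  expect_lt(max(abs(b0 - ols[-1])), 1e-6)
  # a perfect single predictor is the only active variable at modest penalty
  y2 <- X[, 3]
  b2 <- fit_locus_lasso(y2, X, lambda_rule = 0.2)
  expect_true(b2[3] > 0)
  expect_true(all(b2[-3] == 0))
  # CV fit is deterministic given the seed
  bcv1 <- fit_locus_lasso(y, X, seed = 9)
  bcv2 <- fit_locus_lasso(y, X, seed = 9)
  expect_identical(bcv1, bcv2)
})

test_that("debiased inference reduces to OLS in low dimension", {
  set.seed(1)
  n <- 100; p <- 5
  X <- scale(matrix(rnorm(n * p), n, p))
  colnames(X) <- paste0("x", 1:p)
  y <- drop(X %*% c(1, -0.5, 0, 0.3, 0)) + rnorm(n)
  res <- debiased_inference(y, X, lambda = 1e-8)
  fit <- lm(y ~ X)
  expect_lt(max(abs(res$beta_debiased - coef(fit)[-1])), 1e-6)
  # p-values agree with the t-test within 10% where they are not degenerate
  pt <- summary(fit)$coefficients[-1, 4]
  mod <- pt > 1e-3
  expect_true(all(abs(res$p[mod] - pt[mod]) / pt[mod] < 0.10))
})

test_that("duplicated predictors are flagged unidentifiable, not given small p", {
  set.seed(3)
  n <- 60
  X <- matrix(rnorm(n * 6), n, 6)
  X[, 6] <- X[, 5]
  X <- scale(X)
  colnames(X) <- paste0("x", 1:6)
  y <- drop(X[, 1] + rnorm(n))
  res <- debiased_inference(y, X, lambda = 1e-6)
  expect_false(res$identifiable[5])
  expect_false(res$identifiable[6])
  expect_equal(unname(res$p[5:6]), c(1, 1))
  expect_true(res$identifiable[1])
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(8)
  p <- runif(50)
  q <- bh_adjust(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
  expect_true(all(q >= p - 1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("stability selection is deterministic and finds a perfect predictor", {
  d <- std_design(6, n = 40, n_taxa = 15)
  X <- d$X
  set.seed(2)
  y <- X[, 4] + rnorm(nrow(X), 0, 0.01)
  s1 <- stability_selection(y, X, B = 25, seed = 3)
  s2 <- stability_selection(y, X, B = 25, seed = 3)
  expect_identical(s1$stab_freq, s2$stab_freq)
  expect_equal(s1$stab_freq[4], 1.0)
  expect_true(s1$selected[4])
  expect_gt(attr(s1, "pfer_bound"), 0)
  expect_error(stability_selection(y, X, cutoff = 0.5), "cutoff")
  expect_error(stability_selection(y[1:10], X[1:10, ]), "n >= 20")
})

test_that("covariate filtering is targeted and idempotent", {
  res <- tibble::tibble(
    locus_id = "L1", predictor_id = c("T001", "age"),
    predictor_class = c("taxon", "covariate"),
    passed_fdr = TRUE, passed_stability = TRUE, retained = TRUE)
  out <- filter_covariate_associations(res)
  expect_true(out$retained[out$predictor_class == "taxon"])
  expect_false(out$retained[out$predictor_class == "covariate"])
  expect_identical(filter_covariate_associations(out), out)
})

test_that("the screen's retained set is the intersection of its gates", {
  rec <- assoc_recovery(301, n_assoc = 6)
  scr <- rec$screen
  expect_true(all(scr$retained == (scr$passed_fdr & scr$passed_stability &
                                     scr$predictor_class == "taxon")))
  expect_true(all(scr$stab_freq >= 0 & scr$stab_freq <= 1))
  expect_true(all(scr$q >= scr$p - 1e-15))
  g <- glance(scr)
  expect_equal(g$n_retained, sum(scr$retained))
  # per-locus BH family option keeps the same schema
  cfg <- sim_config(n_samples = 30, n_taxa = 10, n_loci = 8,
                    spacing_bp = 1000, seed = 12)
  truth <- planted_truth(cfg)
  taxa <- filter_taxa(simulate_taxa_table(cfg))
  meth <- simulate_methylome(cfg, taxa, truth)
  scr2 <- suppressMessages(
    run_association_screen(meth, taxa, family = "per_locus", B = 10,
                           seed = 12))
  expect_setequal(names(scr2), names(scr))
})

test_that("global methylation-taxa correlation behaves as a rank statistic", {
  lev <- c(S1 = 0.2, S2 = 0.3, S3 = 0.4, S4 = 0.5, S5 = 0.6, S6 = 0.7)
  ab <- cbind(t1 = lev / 2, t2 = rev(lev) / 3, t3 = rep(0.1, 6))
  ab <- ab / rowSums(ab)
  rownames(ab) <- names(lev)
  tt <- make_taxa(ab, is_relative = TRUE)
  res <- global_methylation_taxa_correlation(tt, lev)
  expect_equal(res$rho[res$taxon_id == "t1"], 1)
  # monotone transform of the abundances leaves rho unchanged
  ab2 <- cbind(t1 = ab[, "t1"]^2, t2 = ab[, "t2"])
  ab2 <- cbind(ab2, t3 = 1 - rowSums(ab2))
  tt2 <- make_taxa(ab2, is_relative = TRUE)
  res2 <- global_methylation_taxa_correlation(tt2, lev)
  expect_equal(res2$rho[res2$taxon_id == "t1"],
               res$rho[res$taxon_id == "t1"])
  # constant abundance is skipped with a message
  ab3 <- cbind(t1 = rep(0.5, 6), t2 = lev / 3)
  ab3 <- cbind(ab3, t3 = 1 - rowSums(ab3))
  rownames(ab3) <- names(lev)
  expect_message(
    res3 <- global_methylation_taxa_correlation(
      make_taxa(ab3, is_relative = TRUE), lev),
    "constant")
  expect_false("t1" %in% res3$taxon_id)
})
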