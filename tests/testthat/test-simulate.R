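test_that("taxa simulation is deterministic, closed and respects degenerate variance", {
  cfg <- sim_config(n_samples = 12, n_taxa = 20, seed = 42)
  t1 <- simulate_taxa_table(cfg)
  t2 <- simulate_taxa_table(cfg)
  expect_identical(t1$abundance, t2$abundance)
  expect_identical(t1$true_composition, t2$true_composition)

  rel <- relative_abundance(t1)$abundance
  expect_lt(max(abs(rowSums(rel) - 1)), 1e-12)
  expect_lt(max(abs(rowSums(t1$true_composition) - 1)), 1e-12)

  cfg0 <- sim_config(n_samples = 8, n_taxa = 15, taxa_lognormal_sd = 0,
                     seed = 7)
  t0 <- simulate_taxa_table(cfg0)
  # all samples share the single community composition
  expect_equal(max(apply(t0$true_composition, 2, sd)), 0)
  # and observed relative abundances agree within multinomial noise
  rel0 <- relative_abundance(t0)$abundance
  se <- sqrt(t0$true_composition[1, ] / cfg0$total_reads)
  expect_true(all(abs(t(rel0) - t0$true_composition[1, ]) < 6 * se + 1e-6))
})

test_that("dirichlet-multinomial option keeps closure and determinism", {
  cfg <- sim_config(n_samples = 10, n_taxa = 12, dirichlet = TRUE, seed = 3)
  t1 <- simulate_taxa_table(cfg)
  expect_identical(t1$abundance, simulate_taxa_table(cfg)$abundance)
  expect_lt(max(abs(rowSums(t1$true_composition) - 1)), 1e-12)
})

test_that("methylome means follow the logistic baseline when no effects are planted", {
  cfg <- sim_config(n_samples = 400, n_taxa = 10, n_loci = 25, n_assoc = 0,
                    covariate_effects = c(gender = 0, age = 0, subtype = 0),
                    seed = 11)
  truth <- planted_truth(cfg)
  taxa <- simulate_taxa_table(cfg)
  calls <- simulate_methylome(cfg, taxa, truth)
  p_true <- plogis(truth$baseline_logit)
  prop <- calls$X / calls$N
  emp <- rowMeans(prop)
  # MC standard error of the mean over 400 beta-binomial draws
  se <- sqrt(rowMeans(prop^2) - emp^2) / sqrt(ncol(prop))
  expect_true(all(abs(emp - p_true[rownames(calls$N)]) < 5 * se + 0.005))
})

test_that("phi = 0 gives binomial variance and phi > 0 matches beta-binomial moments", {
  cfg0 <- sim_config(n_samples = 500, n_taxa = 5, n_loci = 40, n_assoc = 0,
                     dispersion_phi = 0, coverage_mean = 40,
                     covariate_effects = c(gender = 0, age = 0, subtype = 0),
                     seed = 19)
  truth0 <- planted_truth(cfg0)
  calls0 <- simulate_methylome(cfg0, simulate_taxa_table(cfg0), truth0)
  p0 <- plogis(truth0$baseline_logit)
  obs <- apply(calls0$X / calls0$N, 1, var)
  expected <- rowMeans(p0 * (1 - p0) / calls0$N)
  ratio <- obs / expected
  # variance-ratio concentrated around 1 under pure binomial sampling
  expect_lt(abs(median(ratio) - 1), 0.15)

  cfg1 <- sim_config(n_samples = 500, n_taxa = 5, n_loci = 40, n_assoc = 0,
                     dispersion_phi = 0.2, coverage_mean = 40,
                     covariate_effects = c(gender = 0, age = 0, subtype = 0),
                     seed = 23)
  truth1 <- planted_truth(cfg1)
  calls1 <- simulate_methylome(cfg1, simulate_taxa_table(cfg1), truth1)
  p1 <- plogis(truth1$baseline_logit)
  obs1 <- apply(calls1$X / calls1$N, 1, var)
  exp1 <- rowMeans(p1 * (1 - p1) * (1 + (calls1$N - 1) * 0.2) / calls1$N)
  expect_lt(abs(median(obs1 / exp1) - 1), 0.15)
  # over-dispersion clearly inflates the binomial variance
  expect_gt(median(obs1 / rowMeans(p1 * (1 - p1) / calls1$N)), 2)
})

test_that("methylome simulation is deterministic and validates its inputs", {
  cfg <- sim_config(n_samples = 6, n_taxa = 8, n_loci = 15, seed = 2)
  truth <- planted_truth(cfg)
  taxa <- simulate_taxa_table(cfg)
  m1 <- simulate_methylome(cfg, taxa, truth)
  m2 <- simulate_methylome(cfg, taxa, truth)
  expect_identical(m1$X, m2$X)
  expect_identical(m1$N, m2$N)
  expect_true(all(m1$X <= m1$N))

  bad <- truth
  bad$assoc_pairs$taxon_id[1] <- "T999"
  expect_error(simulate_methylome(cfg, taxa, bad),
               class = "mbmeth_config_error")
})

test_that("group methylome plants the stated delta and errors outside (0,1)", {
  cfg <- sim_config(n_samples = 200, n_loci = 60, n_assoc = 0,
                    dispersion_phi = 0, coverage_mean = 50,
                    spacing_bp = 1000, seed = 5)
  truth <- planted_truth(cfg, n_dml = 10, dml_delta = 0.3)
  sim <- simulate_group_methylome(cfg, truth)
  emp_delta <- rowMeans(sim$tumor$X / sim$tumor$N) -
    rowMeans(sim$normal$X / sim$normal$N)
  idx <- match(truth$dml$locus_id, sim$tumor$loci$locus_id)
  expect_lt(max(abs(emp_delta[idx] - truth$dml$delta)), 0.05)
  others <- setdiff(seq_along(emp_delta), idx)
  expect_lt(max(abs(emp_delta[others])), 0.08)

  bad <- truth
  bad$dml$delta <- rep(0.999, nrow(bad$dml))
  expect_error(simulate_group_methylome(cfg, bad),
               class = "mbmeth_config_error")
})

test_that("without planted DML the two groups are exchangeable", {
  cfg <- sim_config(n_samples = 10, n_loci = 300, n_assoc = 0,
                    spacing_bp = 1000, seed = 31)
  truth <- planted_truth(cfg, n_dml = 0)
  sim <- simulate_group_methylome(cfg, truth)
  st <- test_dml(sim$tumor, sim$normal)
  expect_lt(abs(mean(st$z)), 0.2)
  expect_gt(mean(st$p < 0.05), 0.0 - 1e-9)
  expect_lt(mean(st$p < 0.05), 0.12)
  # group-label swap mirrors the statistic
  st_swap <- test_dml(sim$normal, sim$tumor)
  expect_equal(st_swap$z, -st$z, tolerance = 1e-12)
})

test_that("meta cohort simulator is deterministic and consistent at large n", {
  t1 <- simulate_meta_cohorts(4, 0.4, 0.01, per_study_n = 30, seed = 9)
  t2 <- simulate_meta_cohorts(4, 0.4, 0.01, per_study_n = 30, seed = 9)
  expect_identical(t1, t2)
  expect_true(all(vapply(t1, function(d) all(d$PWY_effect >= 0 &
                                               d$PWY_effect <= 1), TRUE)))
  expect_error(simulate_meta_cohorts(1, 0, 0, 10, 1),
               class = "mbmeth_config_error")
  expect_error(simulate_meta_cohorts(3, 0, -0.1, 10, 1),
               class = "mbmeth_config_error")

  # tau2 = 0, large per-group n: pooled estimate near truth, low I2
  tabs <- simulate_meta_cohorts(10, 0.5, 0, per_study_n = 400, seed = 13)
  sc <- meta_screen(tabs)
  expect_lt(abs(sc$pooled_mu[1] - 0.5), 0.1)
  expect_lt(sc$I2[1], 30)
})
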