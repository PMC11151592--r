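test_that("arcsine-square-root transform hits its boundaries and closed form", {
  expect_equal(arcsine_sqrt(0), 0)
  expect_equal(arcsine_sqrt(1), pi / 2)
  expect_equal(arcsine_sqrt(0.25), pi / 6, tolerance = 1e-12)
  expect_error(arcsine_sqrt(1.01), "\\[0, 1\\]")
  expect_error(arcsine_sqrt(-0.1), "\\[0, 1\\]")
})

test_that("SMD matches the textbook formulas exactly on random inputs", {
  expect_equal(
    smd_effect(data.frame(n1 = 10, n2 = 10, m1 = 1, m2 = 0,
                          s1 = 1, s2 = 1))[c("g", "v")],
    tibble::tibble(g = (1 - 3 / 71) * 1,
                   v = 20 / 100 + ((1 - 3 / 71))^2 / 40),
    tolerance = 1e-12)
  set.seed(10)
  for (i in 1:200) {
    n1 <- sample(5:80, 1); n2 <- sample(5:80, 1)
    m1 <- rnorm(1); m2 <- rnorm(1)
    s1 <- runif(1, 0.2, 2); s2 <- runif(1, 0.2, 2)
    e <- smd_effect(data.frame(n1 = n1, n2 = n2, m1 = m1, m2 = m2,
                               s1 = s1, s2 = s2))
    sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
    J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
    g <- J * (m1 - m2) / sp
    expect_equal(e$g, g, tolerance = 1e-12)
    expect_equal(e$v, (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2)),
                 tolerance = 1e-12)
  }
  # swapping groups flips the sign, not the variance
  a <- smd_effect(data.frame(n1 = 12, n2 = 9, m1 = 0.8, m2 = 0.3,
                             s1 = 0.5, s2 = 0.4))
  b <- smd_effect(data.frame(n1 = 9, n2 = 12, m1 = 0.3, m2 = 0.8,
                             s1 = 0.4, s2 = 0.5))
  expect_equal(a$g, -b$g, tolerance = 1e-12)
  expect_equal(a$v, b$v, tolerance = 1e-12)
  expect_error(smd_effect(data.frame(n1 = 5, n2 = 5, m1 = 1, m2 = 0,
                                     s1 = 0, s2 = 0)), "pooled SD")
})

test_that("DL pooling matches the closed-form oracle and metafor", {
  # homogeneous effects: tau2 = Q = 0, pooled equals the common value
  hom <- pool_random_effects(data.frame(g = rep(0.5, 4), v = rep(0.1, 4)))
  expect_equal(hom$pooled_mu, 0.5, tolerance = 1e-12)
  expect_equal(hom$tau2, 0)
  expect_equal(hom$Q, 0)
  # two symmetric studies: Q = 5, pooled = 0.5 by symmetry
  two <- pool_random_effects(data.frame(g = c(0, 1), v = c(0.1, 0.1)))
  expect_equal(two$Q, 5, tolerance = 1e-12)
  expect_equal(two$pooled_mu, 0.5, tolerance = 1e-12)
  w <- 10
  expect_equal(two$tau2, (5 - 1) / (2 * w - 2 * w^2 / (2 * w)),
               tolerance = 1e-12)

  set.seed(20)
  for (i in 1:50) {
    k <- sample(3:12, 1)
    g <- rnorm(k, 0.3, 0.4)
    v <- runif(k, 0.02, 0.3)
    me <- pool_random_effects(data.frame(g = g, v = v))
    w <- 1 / v
    Q <- sum(w * (g - sum(w * g) / sum(w))^2)
    tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    wr <- 1 / (v + tau2)
    expect_equal(me$Q, Q, tolerance = 1e-12)
    expect_equal(me$tau2, tau2, tolerance = 1e-12)
    expect_equal(me$pooled_mu, sum(wr * g) / sum(wr), tolerance = 1e-12)
    expect_equal(me$pooled_se, sqrt(1 / sum(wr)), tolerance = 1e-12)
  }

  skip_if_not_installed("metafor")
  set.seed(21)
  g <- rnorm(8, 0.4, 0.3); v <- runif(8, 0.05, 0.2)
  me <- pool_random_effects(data.frame(g = g, v = v))
  rm <- metafor::rma(yi = g, vi = v, method = "DL")
  expect_equal(me$pooled_mu, as.numeric(rm$b), tolerance = 1e-10)
  expect_equal(me$tau2, rm$tau2, tolerance = 1e-10)
  expect_equal(me$I2, rm$I2, tolerance = 1e-6)
})

test_that("REML and DL agree on homogeneous data", {
  set.seed(22)
  agree <- replicate(20, {
    g <- rnorm(10, 0.5, sqrt(0.05))  # sampling variance only
    v <- rep(0.05, 10)
    dl <- pool_random_effects(data.frame(g = g, v = v), method = "DL")
    re <- pool_random_effects(data.frame(g = g, v = v), method = "REML")
    abs(re$pooled_mu - dl$pooled_mu) / max(abs(dl$pooled_mu), 0.1)
  })
  expect_lt(median(agree), 0.10)
})

test_that("I2 follows its definition with truncation at zero", {
  expect_equal(heterogeneity_i2(0.5, 9), 0)
  expect_equal(heterogeneity_i2(20, 10), 50)
  expect_equal(heterogeneity_i2(10, 10), 0)
  expect_error(heterogeneity_i2(-1, 5), "Q")
  expect_error(heterogeneity_i2(5, 0), "df")
})

test_that("the meta screen applies the heterogeneity and FDR gates jointly", {
  tabs <- simulate_meta_cohorts(6, 0.8, 0, per_study_n = 60, seed = 30,
                                n_null = 2)
  sc <- meta_screen(tabs)
  expect_true(sc$significant[sc$pathway_id == "PWY_effect"])
  expect_true(all(sc$I2 >= 0 & sc$I2 <= 100))
  expect_true(all(sc$ci_low <= sc$pooled_mu & sc$pooled_mu <= sc$ci_high))
  # strong effect but extreme heterogeneity: blocked by the I2 gate
  tabs2 <- simulate_meta_cohorts(8, 0.8, 0.5, per_study_n = 200, seed = 31)
  sc2 <- meta_screen(tabs2)
  i2 <- sc2$I2[sc2$pathway_id == "PWY_effect"]
  q <- sc2$q[sc2$pathway_id == "PWY_effect"]
  expect_gt(i2, 50)
  expect_false(sc2$significant[sc2$pathway_id == "PWY_effect"])
  # same row would pass on FDR alone
  expect_lt(q, 0.05)
})

test_that("forest data is consistent with the pooled fit", {
  set.seed(33)
  eff <- data.frame(study_id = paste0("study", 1:6),
                    g = rnorm(6, 0.4, 0.2), v = runif(6, 0.04, 0.1))
  me <- pool_random_effects(eff[c("g", "v")])
  me$studies$study_id <- eff$study_id
  fd <- forest_data(me)
  pooled <- fd[fd$type == "pooled", ]
  expect_equal(pooled$g, me$pooled_mu)
  expect_equal(pooled$ci_low, me$ci_low)
  expect_equal(nrow(fd), 7)
  # CI width shrinks monotonically in n at fixed g
  ns <- c(10, 20, 40, 80)
  widths <- vapply(ns, function(n) {
    e <- smd_effect(data.frame(n1 = n, n2 = n, m1 = 0.6, m2 = 0.4,
                               s1 = 0.3, s2 = 0.3))
    2 * qnorm(0.975) * sqrt(e$v)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  # a dominant study keeps the pooled estimate inside its CI
  dom <- pool_random_effects(data.frame(g = c(0.5, 0.1), v = c(0.001, 1)))
  expect_true(dom$pooled_mu > 0.5 - 1.96 * sqrt(0.001) &&
                dom$pooled_mu < 0.5 + 1.96 * sqrt(0.001))
})
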