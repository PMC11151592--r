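make_calls <- function(pos, N, X, chrom = "chr1") {
  loci <- tibble::tibble(locus_id = sprintf("%s:%d", chrom, pos),
                         chrom = chrom, pos = pos)
  meth_calls(loci, N, X)
}

test_that("depth filter keeps loci covered in every sample", {
  N <- rbind(c(30, 30, 30), c(9, 50, 50), c(10, 10, 10))
  colnames(N) <- paste0("s", 1:3)
  X <- N - 5L
  calls <- make_calls(c(100L, 200L, 300L), N, X)
  kept <- depth_filter(calls, 10)
  expect_equal(kept$loci$pos, c(100L, 300L))
  # min_depth 0 is the identity
  expect_equal(depth_filter(calls, 0)$loci$pos, calls$loci$pos)
  expect_error(depth_filter(calls, 100), "removed all")
})

test_that("smoothing is a coverage-weighted moving average", {
  N <- matrix(10L, 3, 2, dimnames = list(NULL, c("s1", "s2")))
  X <- matrix(c(2L, 4L, 9L, 2L, 4L, 9L), 3, 2)
  # two loci 100 bp apart plus one isolated locus
  calls <- make_calls(c(1000L, 1100L, 50000L), N, X)
  sm <- smooth_methylation(calls, window_bp = 500)
  expect_equal(unname(sm[1:2, 1]), c(0.3, 0.3))
  expect_equal(unname(sm[3, 1]), 0.9)  # isolated: raw X/N
  # unequal coverage weights the average
  N2 <- matrix(c(30L, 10L), 2, 1, dimnames = list(NULL, "s1"))
  X2 <- matrix(c(6L, 4L), 2, 1)
  calls2 <- make_calls(c(1000L, 1100L), N2, X2)
  sm2 <- smooth_methylation(calls2, 500)
  expect_equal(unname(sm2[1, 1]), 10 / 40)
  # window 0 is the identity
  expect_equal(unname(smooth_methylation(calls, 0)),
               unname(calls$X / calls$N))
  expect_error(smooth_methylation(calls, -1), "window_bp")
})

test_that("the vectorized DML test matches a brute-force per-locus oracle", {
  sc <- dml_scenario(101, n_samples = 8, n_loci = 1000, n_dml = 40)
  st <- test_dml(sc$tumor, sc$normal)
  sm_a <- smooth_methylation(sc$tumor, 500)
  sm_b <- smooth_methylation(sc$normal, 500)
  idx <- match(st$locus_id, sc$tumor$loci$locus_id)
  worst <- 0
  for (k in seq_along(idx)) {
    i <- idx[k]
    o <- oracle_dml_stat(sm_a[i, ], sc$tumor$N[i, ], sm_b[i, ],
                         sc$normal$N[i, ])
    worst <- max(worst, abs(o$mu1 - st$mu1[k]), abs(o$mu2 - st$mu2[k]),
                 abs(o$se - st$se[k]), abs(o$z - st$z[k]),
                 abs(o$p - st$p[k]))
  }
  expect_lt(worst, 1e-10)
})

test_that("identical groups give zero delta; phi=0 data matches the pooled-count z", {
  sc <- dml_scenario(7, n_samples = 6, n_loci = 200, n_dml = 0)
  st0 <- test_dml(sc$tumor, sc$tumor)
  expect_equal(max(abs(st0$delta)), 0)

  cfg <- sim_config(n_samples = 13, n_loci = 1000, n_assoc = 0,
                    dispersion_phi = 0, spacing_bp = 1000, seed = 17)
  truth <- planted_truth(cfg, n_dml = 0)
  sim <- simulate_group_methylome(cfg, truth)
  st <- test_dml(sim$tumor, sim$normal)
  # pooled two-proportion z from raw counts (phi = 0 ground truth)
  ia <- match(st$locus_id, sim$tumor$loci$locus_id)
  xa <- rowSums(sim$tumor$X)[ia]; na <- rowSums(sim$tumor$N)[ia]
  xb <- rowSums(sim$normal$X)[ia]; nb <- rowSums(sim$normal$N)[ia]
  pp <- (xa + xb) / (na + nb)
  z2 <- (xa / na - xb / nb) / sqrt(pp * (1 - pp) * (1 / na + 1 / nb))
  keep <- pp > 0.05 & pp < 0.95 & abs(z2) > 0.2
  rel <- abs(st$z[keep] - z2[keep]) / pmax(abs(z2[keep]), 1)
  expect_lt(median(rel), 0.05)
  expect_lt(mean(rel), 0.10)
})

test_that("DML calling applies both thresholds with the right direction", {
  stats <- tibble::tibble(
    locus_id = c("a", "b", "c", "d"), chrom = "chr1", pos = 1:4 * 100L,
    delta = c(0.25, 0.15, 0.25, -0.30),
    q = c(0.01, 0.001, 0.20, 0.01))
  out <- call_dml(stats)
  expect_equal(out$hyper$locus_id, "a")   # passes both
  expect_equal(out$hypo$locus_id, "d")
  expect_false("b" %in% c(out$hyper$locus_id, out$hypo$locus_id))  # |delta| low
  expect_false("c" %in% c(out$hyper$locus_id, out$hypo$locus_id))  # q high
})

test_that("DMR construction follows gap, size, fraction and sign rules", {
  base <- tibble::tibble(chrom = "chr1", delta = 0.3, q = 0.01)
  # five consecutive qualifying loci, 50-bp spacing -> one DMR
  st1 <- dplyr::mutate(base[rep(1, 5), ],
                       locus_id = paste0("l", 1:5), pos = 1000L + 0:4 * 50L)
  d1 <- call_dmr(st1)
  expect_equal(nrow(d1), 1)
  expect_equal(d1$start, 1000L)
  expect_equal(d1$end, 1200L)
  expect_equal(d1$n_cpg, 5L)
  expect_equal(d1$mean_delta, 0.3)
  expect_equal(d1$sig_fraction, 1)
  # two qualifying loci only: below min_cpg
  expect_equal(nrow(call_dmr(st1[1:2, ])), 0)
  # two runs separated by 10 kb -> two DMRs
  st2 <- dplyr::bind_rows(st1, dplyr::mutate(st1, pos = pos + 10000L,
                                             locus_id = paste0("m", 1:5)))
  expect_equal(nrow(call_dmr(st2)), 2)
  # a sign flip splits the run
  st3 <- st1
  st3$delta[3] <- -0.3
  expect_equal(nrow(call_dmr(st3)), 0)  # fragments of 2, 1, 2 loci
  # sub-threshold significance fraction removes the region
  st4 <- st1
  st4$q <- c(0.01, 0.5, 0.5, 0.5, 0.01)
  expect_equal(nrow(call_dmr(st4)), 0)
  expect_equal(nrow(call_dmr(st4, min_sig_fraction = 0.3)), 1)
  # per-chromosome split/concatenation is invariant
  st5 <- dplyr::bind_rows(st1, dplyr::mutate(st1, chrom = "chr2",
                                             locus_id = paste0("n", 1:5)))
  whole <- call_dmr(st5)
  parts <- dplyr::bind_rows(call_dmr(st5[st5$chrom == "chr1", ]),
                            call_dmr(st5[st5$chrom == "chr2", ]))
  expect_equal(whole, dplyr::arrange(parts, chrom, start))
})

test_that("global methylation level averages X/N and guards empty input", {
  N <- matrix(10L, 2, 2, dimnames = list(NULL, c("s1", "s2")))
  X <- matrix(c(2L, 4L, 10L, 10L), 2, 2)
  calls <- make_calls(c(100L, 1000L), N, X)
  lev <- global_methylation_level(calls)
  expect_equal(unname(lev), c(0.3, 1.0))
  empty <- make_calls(c(100L, 1000L),
                      matrix(c(10L, 10L, 0L, 0L), 2, 2,
                             dimnames = list(NULL, c("s1", "s2"))),
                      matrix(c(1L, 1L, 0L, 0L), 2, 2))
  expect_error(global_methylation_level(empty), "no covered locus")
})

test_that("paired global comparison uses the exact signed-rank distribution", {
  expect_equal(paired_global_comparison(rep(0.5, 6), rep(0.5, 6))$p, 1)
  set.seed(1)
  nor <- runif(13, 0.4, 0.6)
  tum <- nor - runif(13, 0.01, 0.2)  # tumor below normal in all pairs
  r <- paired_global_comparison(tum, nor)
  expect_equal(r$p, 2 / 2^13, tolerance = 1e-12)
  r_swap <- paired_global_comparison(nor, tum)
  expect_equal(r_swap$statistic, -r$statistic)
  expect_equal(r_swap$p, r$p)
  expect_error(paired_global_comparison(1:3 / 10, 2:4 / 10), "at least 5")
})

test_that("null DML calling is calibrated across replicate datasets", {
  rej <- vapply(1:10, function(s) {
    sc <- dml_scenario(200 + s, n_samples = 8, n_loci = 150, n_dml = 0)
    st <- test_dml(sc$tumor, sc$normal)
    mean(st$q < 0.05)
  }, numeric(1))
  expect_lte(mean(rej), 0.05)
})
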