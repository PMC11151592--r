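#' Beta-binomial Wald test for differential methylation
#'
#' For every locus covered in both groups, smoothed methylation levels
#' (coverage-weighted 500-bp moving averages, see [smooth_methylation()])
#' are compared between the two groups with a Wald test. Group means are
#' coverage-weighted means of the smoothed per-sample proportions; the
#' per-group variance comes from the beta-binomial model
#' `Var(X/N) = p (1 - p) (1 + (N - 1) phi) / N`, with the over-dispersion
#' `phi` estimated per locus and group by method of moments (floored at 0).
#' Two-sided normal p-values are adjusted across all tested loci with
#' Benjamini-Hochberg in a single family.
#'
#' @param groupA,groupB [meth_calls()] for the two groups (e.g. tumor and
#'   adjacent normal), ideally already through [depth_filter()]; each needs
#'   >= 2 samples. Only loci present in both groups are tested.
#' @param window_bp Smoothing window passed to [smooth_methylation()].
#' @param se_floor Lower bound on the standard error, applied (with a
#'   warning) when a locus is constant at 0 or 1 in both groups.
#' @return A tibble with one row per locus: `locus_id`, `chrom`, `pos`,
#'   `mu1`, `mu2`, `delta = mu1 - mu2`, `phi1`, `phi2`, `se`, `z`, `p`, `q`.
#' @export
test_dml <- function(groupA, groupB, window_bp = 500L, se_floor = 1e-8) {
  stopifnot(inherits(groupA, "meth_calls"), inherits(groupB, "meth_calls"))
  if (ncol(groupA$N) < 2 || ncol(groupB$N) < 2) {
    stop("each group needs at least two samples")
  }
  key_a <- paste(groupA$loci$chrom, groupA$loci$pos)
  key_b <- paste(groupB$loci$chrom, groupB$loci$pos)
  common <- intersect(key_a, key_b)
  if (length(common) == 0) stop("no locus shared between the groups")
  ia <- match(common, key_a)
  ib <- match(common, key_b)
  sm_a <- smooth_methylation(groupA, window_bp)[ia, , drop = FALSE]
  sm_b <- smooth_methylation(groupB, window_bp)[ib, , drop = FALSE]
  na <- groupA$N[ia, , drop = FALSE]
  nb <- groupB$N[ib, , drop = FALSE]
  ga <- group_moments(sm_a, na)
  gb <- group_moments(sm_b, nb)
  se <- sqrt(ga$var_mu + gb$var_mu)
  n_floor <- sum(se < se_floor)
  if (n_floor > 0) {
    warning(n_floor, " locus/loci with degenerate variance: se floored")
    se <- pmax(se, se_floor)
  }
  delta <- ga$mu - gb$mu
  z <- delta / se
  p <- 2 * pnorm(-abs(z))
  groupA$loci[ia, ] |>
    mutate(mu1 = ga$mu, mu2 = gb$mu, delta = delta,
           phi1 = ga$phi, phi2 = gb$phi,
           se = se, z = z, p = p, q = bh_adjust(p))
}

# Per-locus coverage-weighted mean, method-of-moments phi and Var(mean)
# for one group; prop = smoothed proportions, N = raw coverages.
group_moments <- function(prop, N) {
  wsum <- rowSums(N)
  mu <- rowSums(N * prop) / wsum
  n <- ncol(prop)
  s2 <- rowSums((prop - mu)^2) / (n - 1)
  pq <- mu * (1 - mu)
  mean_inv <- rowMeans(1 / N)
  mean_frac <- rowMeans((N - 1) / N)
  phi <- ifelse(pq > 0 & mean_frac > 0,
                (s2 / pmax(pq, .Machine$double.eps) - mean_inv) / mean_frac,
                0)
  phi <- pmin(pmax(phi, 0), 1 - 1e-8)
  var_cell <- pq * (1 + (N - 1) * phi) / N
  var_mu <- rowSums(N^2 * var_cell) / wsum^2
  list(mu = mu, phi = phi, var_mu = var_mu)
}

#' Call differentially methylated loci
#'
#' A locus is a DML when `|delta| > min_delta` and `q < max_q`; the sign of
#' `delta` (group A minus group B) partitions hyper- from hypomethylated
#' loci.
#'
#' @param stats Output of [test_dml()].
#' @param min_delta Methylation-difference threshold (strict).
#' @param max_q FDR threshold (strict).
#' @return A list with tibbles `hyper` and `hypo`.
#' @export
call_dml <- function(stats, min_delta = 0.20, max_q = 0.05) {
  stopifnot(all(c("delta", "q") %in% names(stats)))
  is_dml <- abs(stats$delta) > min_delta & stats$q < max_q
  list(hyper = stats[is_dml & stats$delta > 0, , drop = FALSE],
       hypo = stats[is_dml & stats$delta < 0, , drop = FALSE])
}

#' Call differentially methylated regions
#'
#' Greedy construction: loci with `|delta| > min_delta` are candidates;
#' consecutive candidates of the same sign on one chromosome are merged
#' while the gap between neighbours stays `<= max_gap_bp`. A merged run
#' becomes a DMR when it holds at least `min_cpg` loci, at least
#' `min_sig_fraction` of them reach `q < max_q`, and the absolute mean
#' delta exceeds `min_delta`.
#'
#' @param stats Output of [test_dml()], sorted by position.
#' @param min_delta,max_q Per-locus thresholds as in [call_dml()].
#' @param max_gap_bp Maximum distance between consecutive member loci.
#' @param min_cpg Minimum number of CpGs per region.
#' @param min_sig_fraction Minimum fraction of member loci with `q < max_q`.
#' @return A tibble of regions: `chrom`, `start`, `end` (1-based
#'   inclusive), `n_cpg`, `mean_delta`, `sig_fraction`, `direction`.
#' @export
call_dmr <- function(stats, min_delta = 0.20, max_q = 0.05,
                     max_gap_bp = 100L, min_cpg = 3L,
                     min_sig_fraction = 0.5) {
  stopifnot(all(c("chrom", "pos", "delta", "q") %in% names(stats)))
  cand <- stats |>
    filter(abs(.data$delta) > min_delta) |>
    arrange(.data$chrom, .data$pos)
  if (nrow(cand) == 0) return(empty_dmr_tbl())
  new_run <- c(TRUE,
               cand$chrom[-1] != cand$chrom[-nrow(cand)] |
                 cand$pos[-1] - cand$pos[-nrow(cand)] > max_gap_bp |
                 sign(cand$delta[-1]) != sign(cand$delta[-nrow(cand)]))
  cand$run <- cumsum(new_run)
  cand |>
    group_by(.data$run) |>
    summarise(chrom = .data$chrom[1], start = min(.data$pos),
              end = max(.data$pos), n_cpg = n(),
              mean_delta = mean(.data$delta),
              sig_fraction = mean(.data$q < max_q), .groups = "drop") |>
    filter(.data$n_cpg >= min_cpg,
           .data$sig_fraction >= min_sig_fraction,
           abs(.data$mean_delta) > min_delta) |>
    mutate(direction = ifelse(.data$mean_delta > 0, "hyper", "hypo")) |>
    select(-"run") |>
    arrange(.data$chrom, .data$start)
}

empty_dmr_tbl <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         n_cpg = integer(), mean_delta = numeric(),
         sig_fraction = numeric(), direction = character())
}

#' Paired comparison of per-sample global methylation levels
#'
#' Wilcoxon signed-rank test on matched tumor/normal pairs. The reported
#' statistic is the signed-rank sum centred at its null expectation
#' (`V - n (n + 1) / 4`), so swapping the groups flips its sign.
#'
#' @param levels_tumor,levels_normal Matched numeric vectors (same subject
#'   order) of per-sample global methylation, `n >= 5` pairs.
#' @return A tibble with `statistic`, `p`, `n`.
#' @export
paired_global_comparison <- function(levels_tumor, levels_normal) {
  n <- length(levels_tumor)
  if (length(levels_normal) != n) stop("groups are not matched")
  if (n < 5) stop("need at least 5 matched pairs")
  d <- levels_tumor - levels_normal
  if (all(d == 0)) {
    return(tibble(statistic = 0, p = 1, n = n))
  }
  wt <- suppressWarnings(wilcox.test(levels_tumor, levels_normal,
                                     paired = TRUE))
  nz <- sum(d != 0)
  tibble(statistic = unname(wt$statistic) - nz * (nz + 1) / 4,
         p = wt$p.value, n = n)
}
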