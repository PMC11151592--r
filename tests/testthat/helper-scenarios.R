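# Shared scenario builders. The association and DML scenarios space CpGs
# 1000 bp apart so the 500-bp smoother treats every locus independently;
# per-locus planted effects then stay attributable to their locus.

assoc_config <- function(seed, n_assoc = 20L) {
  sim_config(spacing_bp = 1000L, n_assoc = n_assoc, seed = seed)
}

# Run the full screen on one synthetic cohort; returns recovery metrics
# against the planted truth.
assoc_recovery <- function(seed, n_assoc = 20L, ...) {
  cfg <- assoc_config(seed, n_assoc)
  truth <- planted_truth(cfg)
  taxa <- filter_taxa(simulate_taxa_table(cfg))
  meth <- simulate_methylome(cfg, taxa, truth)
  scr <- suppressMessages(run_association_screen(meth, taxa, seed = seed, ...))
  ret <- retained_associations(scr)
  keys <- function(l, p) paste(l, p)
  planted <- keys(truth$assoc_pairs$locus_id, truth$assoc_pairs$taxon_id)
  found <- keys(ret$locus_id, ret$predictor_id)
  list(sens = if (length(planted)) mean(planted %in% found) else NA_real_,
       fdr = if (length(found)) mean(!found %in% planted) else 0,
       n_retained = nrow(ret), screen = scr, truth = truth)
}

dml_scenario <- function(seed, n_samples = 13L, n_loci = 1000L,
                         n_dml = 50L, delta = 0.3) {
  cfg <- sim_config(n_samples = n_samples, n_loci = n_loci, n_assoc = 0L,
                    spacing_bp = 1000L, seed = seed)
  truth <- planted_truth(cfg, n_dml = n_dml, dml_delta = delta)
  sim <- simulate_group_methylome(cfg, truth)
  list(cfg = cfg, truth = truth, tumor = sim$tumor, normal = sim$normal)
}

# Independent single-locus recomputation of the beta-binomial Wald test,
# written from the model formulas (not via the package internals).
oracle_dml_stat <- function(pa, na, pb, nb) {
  one_group <- function(prop, N) {
    mu <- sum(N * prop) / sum(N)
    s2 <- sum((prop - mu)^2) / (length(prop) - 1)
    pq <- mu * (1 - mu)
    phi <- if (pq > 0) {
      (s2 / pq - mean(1 / N)) / mean((N - 1) / N)
    } else 0
    phi <- min(max(phi, 0), 1 - 1e-8)
    vc <- pq * (1 + (N - 1) * phi) / N
    list(mu = mu, var_mu = sum(N^2 * vc) / sum(N)^2)
  }
  ga <- one_group(pa, na)
  gb <- one_group(pb, nb)
  se <- max(sqrt(ga$var_mu + gb$var_mu), 1e-8)
  z <- (ga$mu - gb$mu) / se
  list(mu1 = ga$mu, mu2 = gb$mu, se = se, z = z, p = 2 * pnorm(-abs(z)))
}

# Exhaustive enumeration of the one-sided enrichment tail for small
# backgrounds: over all subsets of the given size, the fraction whose
# category count reaches the observed one.
oracle_enrichment_p <- function(bg_in_cat, bg_total, n_hits, k_obs) {
  sets <- utils::combn(bg_total, n_hits)
  in_cat <- seq_len(bg_in_cat)  # w.l.o.g. the first loci are in-category
  mean(apply(sets, 2, function(s) sum(s %in% in_cat) >= k_obs))
}

make_taxa <- function(abund, is_relative = FALSE) {
  if (is.null(rownames(abund))) {
    rownames(abund) <- sprintf("S%02d", seq_len(nrow(abund)))
  }
  if (is.null(colnames(abund))) {
    colnames(abund) <- sprintf("T%03d", seq_len(ncol(abund)))
  }
  taxa_table(abund, is_relative = is_relative)
}
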