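#' Simulate a bisulfite methylome linked to a taxa table
#'
#' For locus `l` and sample `s` the mean methylation is
#' `p_ls = plogis(alpha_l + sum_k beta_lk * clr(taxa)_sk + covariate terms)`,
#' with the planted coefficients taken from `truth`. Coverage is
#' gamma-Poisson (negative binomial) with mean `cfg$coverage_mean` and shape
#' `cfg$coverage_shape`, floored at one read; methylated counts are
#' beta-binomial with over-dispersion `cfg$dispersion_phi`. Loci sit on one
#' synthetic chromosome `chrSim` at `cfg$spacing_bp` intervals.
#'
#' CLR values of the *true* compositions (carried by
#' [simulate_taxa_table()]) drive the signal, so the observed counts add
#' realistic measurement noise on the predictor side as well.
#'
#' @param cfg A [sim_config()].
#' @param taxa A [taxa_table()] from [simulate_taxa_table()].
#' @param truth A [planted_truth()].
#' @param seed_component Internal: which RNG substream to draw from.
#' @return A [meth_calls()].
#' @export
simulate_methylome <- function(cfg, taxa, truth,
                               seed_component = "methylome") {
  validate_sim_config(cfg)
  stopifnot(inherits(taxa, "taxa_table"), inherits(truth, "planted_truth"))
  if (!all(truth$assoc_pairs$taxon_id %in% colnames(taxa$abundance))) {
    abort_config("planted pair references a taxon absent from the taxa table")
  }
  if (nrow(taxa$abundance) != cfg$n_samples) {
    abort_config("taxa table sample count does not match cfg$n_samples")
  }
  comp <- taxa$true_composition
  clr <- if (!is.null(comp)) clr_transform(comp) else clr_transform(taxa)
  eta <- linear_predictor(cfg, truth, clr, taxa$sample_meta)
  draw_calls(cfg, plogis(eta), colnames(eta), seed_component)
}

linear_predictor <- function(cfg, truth, clr, meta) {
  n_loci <- cfg$n_loci
  samples <- rownames(clr)
  eta <- matrix(truth$baseline_logit, n_loci, length(samples),
                dimnames = list(names(truth$baseline_logit), samples))
  if (nrow(truth$assoc_pairs)) {
    for (i in seq_len(nrow(truth$assoc_pairs))) {
      pr <- truth$assoc_pairs[i, ]
      eta[pr$locus_id, ] <- eta[pr$locus_id, ] + pr$beta * clr[, pr$taxon_id]
    }
  }
  covs <- truth$covariate_betas
  shift <- covs[["gender"]] * meta$gender +
    covs[["age"]] * (meta$age - 60) +
    covs[["subtype"]] * meta$subtype
  sweep(eta, 2, shift, `+`)
}

draw_calls <- function(cfg, p, sample_ids, seed_component) {
  n_loci <- nrow(p)
  n_s <- ncol(p)
  loci <- tibble(locus_id = rownames(p), chrom = "chrSim",
                 pos = cfg$spacing_bp * seq_len(n_loci))
  with_component_seed(cfg$seed, seed_component, {
    lambda <- rgamma(n_loci * n_s, shape = cfg$coverage_shape,
                     rate = cfg$coverage_shape / cfg$coverage_mean)
    N <- matrix(pmax(1L, rpois(n_loci * n_s, lambda)), n_loci, n_s)
    phi <- cfg$dispersion_phi
    pv <- as.vector(p)
    if (phi > 0) {
      pv <- rbeta(length(pv), pv * (1 - phi) / phi, (1 - pv) * (1 - phi) / phi)
      # rbeta returns NaN when a shape is 0 (p exactly 0 or 1): degenerate draw
      pv[as.vector(p) %in% c(0, 1)] <- as.vector(p)[as.vector(p) %in% c(0, 1)]
    }
    X <- matrix(rbinom(length(pv), as.vector(N), pv), n_loci, n_s)
    dimnames(N) <- dimnames(X) <- list(loci$locus_id, sample_ids)
    meth_calls(loci, N, X)
  })
}

#' Simulate a paired two-group methylome with planted DML
#'
#' Both groups share the per-locus baseline methylation of `truth`; at the
#' planted DML the tumor-like group's mean is shifted by the planted delta
#' on the proportion scale. No taxa or covariate effects enter, so the two
#' groups are exchangeable at every non-planted locus.
#'
#' @param cfg A [sim_config()]; `n_samples` is the size of each group.
#' @param truth A [planted_truth()] with `dml` planted (see `n_dml`).
#' @return A list with `meth_calls` elements `tumor` and `normal`.
#' @export
#' @examples
#' cfg <- sim_config(n_samples = 4, n_loci = 30, seed = 3)
#' sim <- simulate_group_methylome(cfg, planted_truth(cfg, n_dml = 5))
#' dim(sim$tumor)
simulate_group_methylome <- function(cfg, truth) {
  validate_sim_config(cfg)
  stopifnot(inherits(truth, "planted_truth"))
  p0 <- plogis(truth$baseline_logit)
  p_tumor <- p0
  if (nrow(truth$dml)) {
    idx <- match(truth$dml$locus_id, names(p0))
    if (anyNA(idx)) abort_config("planted DML references a missing locus")
    p_tumor[idx] <- p0[idx] + truth$dml$delta
    if (any(p_tumor[idx] <= 0) || any(p_tumor[idx] >= 1)) {
      abort_config("planted delta pushes a group mean outside (0, 1)")
    }
  }
  ids_t <- sprintf("T%03d", seq_len(cfg$n_samples))
  ids_n <- sprintf("N%03d", seq_len(cfg$n_samples))
  pm_t <- matrix(p_tumor, cfg$n_loci, cfg$n_samples,
                 dimnames = list(names(p0), ids_t))
  pm_n <- matrix(p0, cfg$n_loci, cfg$n_samples,
                 dimnames = list(names(p0), ids_n))
  list(tumor = draw_calls(cfg, pm_t, ids_t, "methylome"),
       normal = draw_calls(cfg, pm_n, ids_n, "methylome_b"))
}
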