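#' Planted ground truth for a synthetic cohort
#'
#' Draws and records every non-null effect the generators will plant:
#' taxon-locus association pairs with their logit-scale coefficients, the
#' covariate coefficients, per-locus baseline methylation, the set of
#' differentially methylated loci with their group difference, and the true
#' pooled effect / heterogeneity of the meta-analysis component. Downstream
#' oracle comparisons read this record; nothing is ever re-derived.
#'
#' @param cfg A [sim_config()].
#' @param n_dml Number of loci with a planted tumor-vs-normal difference.
#' @param dml_delta Absolute methylation difference at planted DML
#'   (tumor minus normal on the proportion scale); signs alternate.
#' @param meta_true_effect,meta_tau2 True pooled standardized effect and
#'   between-study variance for [simulate_meta_cohorts()].
#' @return An object of class `planted_truth` with fields `assoc_pairs`
#'   (tibble: `locus_id`, `taxon_id`, `beta`), `covariate_betas`,
#'   `baseline_logit`, `dml` (tibble: `locus_id`, `delta`, `p_normal`),
#'   `meta_true_effect`, `meta_tau2`.
#' @export
#' @examples
#' truth <- planted_truth(sim_config(n_loci = 50, n_assoc = 5, seed = 7))
#' truth$assoc_pairs
planted_truth <- function(cfg, n_dml = 0L, dml_delta = 0.3,
                          meta_true_effect = 0.5, meta_tau2 = 0) {
  validate_sim_config(cfg)
  if (abs(dml_delta) > 1) abort_config("dml_delta must lie in [-1, 1]")
  if (meta_tau2 < 0) abort_config("meta_tau2 must be >= 0")
  n_dml <- as.integer(n_dml)
  if (n_dml < 0L || n_dml > cfg$n_loci) {
    abort_config("n_dml must lie in [0, n_loci]")
  }
  locus_ids <- sprintf("L%04d", seq_len(cfg$n_loci))
  taxon_ids <- sprintf("T%03d", seq_len(cfg$n_taxa))
  with_component_seed(cfg$seed, "truth", {
    baseline <- rnorm(cfg$n_loci, cfg$baseline_logit_mean, cfg$baseline_logit_sd)
    pair_idx <- sample.int(cfg$n_loci * cfg$n_taxa, cfg$n_assoc)
    assoc <- tibble(
      locus_id = locus_ids[(pair_idx - 1L) %% cfg$n_loci + 1L],
      taxon_id = taxon_ids[(pair_idx - 1L) %/% cfg$n_loci + 1L],
      beta = cfg$effect_size * rep_len(c(1, -1), cfg$n_assoc)
    )
    dml_idx <- sample.int(cfg$n_loci, n_dml)
    deltas <- abs(dml_delta) * rep_len(c(1, -1), n_dml)
    # baseline for planted DML redrawn so both group means stay inside (0, 1)
    p_normal <- runif(n_dml,
                      pmax(0.02, 0.02 - pmin(deltas, 0)),
                      pmin(0.98, 0.98 - pmax(deltas, 0)))
    if (n_dml > 0 && (any(p_normal + deltas >= 1) || any(p_normal + deltas <= 0))) {
      abort_config("planted DML delta pushes a group mean outside (0, 1)")
    }
    baseline[dml_idx] <- qlogis(p_normal)
    covb <- setNames(numeric(3), c("gender", "age", "subtype"))
    covb[names(cfg$covariate_effects)] <- cfg$covariate_effects
    structure(
      list(assoc_pairs = assoc,
           covariate_betas = covb,
           baseline_logit = setNames(baseline, locus_ids),
           dml = tibble(locus_id = locus_ids[dml_idx], delta = deltas,
                        p_normal = p_normal),
           meta_true_effect = meta_true_effect,
           meta_tau2 = meta_tau2),
      class = "planted_truth"
    )
  })
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("<planted_truth> %d assoc pairs, %d DML, meta effect %.2f (tau2 %.3f)\n",
              nrow(x$assoc_pairs), nrow(x$dml), x$meta_true_effect, x$meta_tau2))
  invisible(x)
}
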