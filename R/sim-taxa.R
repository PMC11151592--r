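#' Simulate a taxa count table
#'
#' Per-sample community compositions follow a log-normal model around a
#' fixed community mean (softmax of i.i.d. normal log-abundances), with
#' counts drawn by multinomial sampling at `cfg$total_reads` reads per
#' sample; `dirichlet = TRUE` in the configuration switches to a
#' Dirichlet-multinomial with matched mean composition. The true underlying
#' compositions are attached as field `true_composition` for oracle use.
#'
#' @param cfg A [sim_config()].
#' @return A [taxa_table()] of counts with synthetic lineage strings and the
#'   covariate table of [simulate_covariates()] as sample metadata.
#' @export
#' @examples
#' tt <- simulate_taxa_table(sim_config(n_samples = 6, n_taxa = 10))
#' rowSums(relative_abundance(tt)$abundance)
simulate_taxa_table <- function(cfg) {
  validate_sim_config(cfg)
  meta <- simulate_covariates(cfg)
  with_component_seed(cfg$seed, "taxa", {
    base_log <- rnorm(cfg$n_taxa, 0, 1)
    comp <- matrix(0, cfg$n_samples, cfg$n_taxa)
    if (cfg$dirichlet) {
      conc <- cfg$n_taxa / max(cfg$taxa_lognormal_sd, 1e-8)^2
      alpha <- softmax(base_log) * conc
      g <- matrix(rgamma(cfg$n_samples * cfg$n_taxa,
                         shape = rep(alpha, each = cfg$n_samples)),
                  cfg$n_samples, cfg$n_taxa)
      comp <- g / rowSums(g)
    } else {
      for (i in seq_len(cfg$n_samples)) {
        comp[i, ] <- softmax(base_log + rnorm(cfg$n_taxa, 0, cfg$taxa_lognormal_sd))
      }
    }
    counts <- t(apply(comp, 1, function(p) {
      rmultinom(1, size = cfg$total_reads, prob = p)[, 1]
    }))
    taxon_ids <- sprintf("T%03d", seq_len(cfg$n_taxa))
    dimnames(counts) <- dimnames(comp) <- list(meta$sample_id, taxon_ids)
    tt <- taxa_table(counts,
                     taxonomy = synthetic_lineage(taxon_ids),
                     sample_meta = meta)
    tt$true_composition <- comp
    tt
  })
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

synthetic_lineage <- function(taxon_ids) {
  k <- seq_along(taxon_ids)
  tibble(
    taxon_id = taxon_ids,
    lineage = sprintf(
      "k__Bacteria|p__Phylum%02d|c__Class%02d|o__Order%02d|f__Family%02d|g__Genus%03d|s__Species%03d",
      (k - 1L) %% 6L + 1L, (k - 1L) %% 10L + 1L, (k - 1L) %% 14L + 1L,
      (k - 1L) %% 20L + 1L, k, k)
  )
}
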