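#' Simulation configuration for synthetic microbiome-methylome cohorts
#'
#' Bundles every knob of the synthetic-data generator. The defaults describe
#' the reference study design used throughout the package's tests: 40 tissue
#' samples, 50 taxa, 200 CpG loci, 20 planted taxon-locus associations with a
#' logit-scale effect of 0.8 per CLR unit, beta-binomial over-dispersion 0.05
#' and a mean bisulfite coverage of 30x.
#'
#' @param n_samples Number of samples (for two-group designs, per group).
#' @param n_taxa Number of taxa in the community.
#' @param n_loci Number of CpG loci on the single synthetic chromosome.
#' @param n_assoc Number of planted non-null taxon-locus pairs.
#' @param effect_size Absolute logit-scale shift in methylation per CLR unit
#'   of a planted taxon; signs alternate across planted pairs.
#' @param baseline_logit_mean,baseline_logit_sd Normal distribution of the
#'   per-locus baseline methylation on the logit scale.
#' @param dispersion_phi Beta-binomial over-dispersion in `[0, 1)`; 0 recovers
#'   pure binomial sampling.
#' @param coverage_mean Mean sequencing depth per CpG per sample.
#' @param coverage_shape Gamma shape of the gamma-Poisson (negative binomial)
#'   coverage model; smaller values give more over-dispersed depth.
#' @param taxa_lognormal_sd Log-scale standard deviation of per-sample taxon
#'   abundances around the community mean composition.
#' @param total_reads Sequencing depth of each taxa profile (multinomial size).
#' @param covariate_effects Named numeric vector of logit-scale covariate
#'   effects; names must be a subset of `c("gender", "age", "subtype")`. Age
#'   is centred at 60 years before its effect is applied.
#' @param spacing_bp Distance between consecutive CpG positions, in bp.
#' @param dirichlet Use a Dirichlet-multinomial instead of the default
#'   log-normal-multinomial taxa model.
#' @param seed Integer master seed; every component derives its own stream
#'   from it, so e.g. adding taxa does not perturb the methylome draws.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_samples = 10, n_taxa = 8, n_loci = 20, n_assoc = 3)
#' cfg$n_taxa
sim_config <- function(n_samples = 40,
                       n_taxa = 50,
                       n_loci = 200,
                       n_assoc = 20,
                       effect_size = 0.8,
                       baseline_logit_mean = 0,
                       baseline_logit_sd = 1.2,
                       dispersion_phi = 0.05,
                       coverage_mean = 30,
                       coverage_shape = 10,
                       taxa_lognormal_sd = 1,
                       total_reads = 1e5,
                       covariate_effects = c(gender = 0.3, age = 0.01, subtype = 0.3),
                       spacing_bp = 100,
                       dirichlet = FALSE,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_taxa = as.integer(n_taxa),
    n_loci = as.integer(n_loci), n_assoc = as.integer(n_assoc),
    effect_size = effect_size,
    baseline_logit_mean = baseline_logit_mean,
    baseline_logit_sd = baseline_logit_sd,
    dispersion_phi = dispersion_phi,
    coverage_mean = coverage_mean, coverage_shape = coverage_shape,
    taxa_lognormal_sd = taxa_lognormal_sd, total_reads = total_reads,
    covariate_effects = covariate_effects,
    spacing_bp = as.integer(spacing_bp),
    dirichlet = isTRUE(dirichlet),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_samples < 1L || cfg$n_taxa < 1L || cfg$n_loci < 1L) {
    abort_config("n_samples, n_taxa and n_loci must all be >= 1")
  }
  if (cfg$n_assoc < 0L || cfg$n_assoc > cfg$n_taxa * cfg$n_loci) {
    abort_config("n_assoc must lie in [0, n_taxa * n_loci]")
  }
  if (cfg$dispersion_phi < 0 || cfg$dispersion_phi >= 1) {
    abort_config("dispersion_phi must lie in [0, 1)")
  }
  if (cfg$coverage_mean <= 0 || cfg$coverage_shape <= 0) {
    abort_config("coverage_mean and coverage_shape must be positive")
  }
  if (cfg$taxa_lognormal_sd < 0) abort_config("taxa_lognormal_sd must be >= 0")
  if (cfg$total_reads < 1) abort_config("total_reads must be >= 1")
  if (cfg$spacing_bp < 1L) abort_config("spacing_bp must be >= 1")
  extra <- setdiff(names(cfg$covariate_effects), c("gender", "age", "subtype"))
  if (length(extra)) {
    abort_config(paste0("unknown covariate effects: ", paste(extra, collapse = ", ")))
  }
  invisible(cfg)
}

abort_config <- function(msg) {
  rlang::abort(msg, class = "mbmeth_config_error")
}

# Hierarchical RNG: one substream per named component so that changing the
# draw count of one component never shifts another component's stream.
component_seed <- function(seed, component) {
  offsets <- c(taxa = 11L, covariates = 23L, truth = 37L, methylome = 53L,
               methylome_b = 59L, coverage = 71L, meta = 83L, folds = 97L,
               stability = 113L)
  if (!component %in% names(offsets)) {
    stop("unknown RNG component: ", component)
  }
  # double arithmetic: exact up to 2^53, avoids 32-bit overflow
  as.integer((as.numeric(seed) * 1009 + offsets[[component]]) %% 2147483477)
}

with_component_seed <- function(seed, component, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(component_seed(seed, component))
  force(code)
}

#' Simulate sample covariates
#'
#' Gender and disease subtype are Bernoulli(0.5); age is uniform on 40-80
#' years, the range typical of surgical colorectal-cancer cohorts.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with columns `sample_id`, `gender`, `age`, `subtype`.
#' @export
simulate_covariates <- function(cfg) {
  validate_sim_config(cfg)
  with_component_seed(cfg$seed, "covariates", {
    tibble(
      sample_id = sprintf("S%03d", seq_len(cfg$n_samples)),
      gender = rbinom(cfg$n_samples, 1L, 0.5),
      age = runif(cfg$n_samples, 40, 80),
      subtype = rbinom(cfg$n_samples, 1L, 0.5)
    )
  })
}
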