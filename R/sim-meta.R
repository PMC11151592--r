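#' Simulate multi-study two-group pathway abundance cohorts
#'
#' Each study draws its true standardized effect `theta_i ~ N(true_effect,
#' tau2)` and generates case/control pathway relative abundances on `[0, 1]`
#' so that the arcsine-square-root transformed values realise `theta_i`:
#' transformed values are normal with unit-free spread `sd_t` and the case
#' mean shifted by `theta_i * sd_t`. Additional exchangeable null pathways
#' can be appended for screen calibration studies.
#'
#' @param n_studies Number of studies (>= 2).
#' @param true_effect True pooled standardized mean difference.
#' @param tau2 Between-study variance of the standardized effect (>= 0).
#' @param per_study_n Integer vector (recycled to `n_studies`) of per-group
#'   sample sizes.
#' @param seed Integer seed.
#' @param n_null Number of extra pathways with zero effect and no
#'   heterogeneity.
#' @param mean_t,sd_t Mean and SD of the transformed abundances in the
#'   control group (defaults keep draws well inside `[0, pi/2]`).
#' @return A list of per-study tibbles with columns `study_id`, `sample_id`,
#'   `group` (`"case"`/`"control"`) and one column per pathway (`PWY_...`).
#' @export
#' @examples
#' tabs <- simulate_meta_cohorts(3, 0.5, 0, per_study_n = 20, seed = 1)
#' tabs[[1]][1:3, 1:4]
simulate_meta_cohorts <- function(n_studies, true_effect, tau2,
                                  per_study_n, seed, n_null = 0L,
                                  mean_t = 0.7, sd_t = 0.12) {
  if (n_studies < 2) abort_config("n_studies must be >= 2")
  if (tau2 < 0) abort_config("tau2 must be >= 0")
  per_study_n <- rep_len(as.integer(per_study_n), n_studies)
  if (any(per_study_n < 2)) abort_config("per_study_n must be >= 2")
  pathways <- c("PWY_effect",
                if (n_null > 0) sprintf("PWY_null%03d", seq_len(n_null)))
  with_component_seed(seed, "meta", {
    theta <- rnorm(n_studies, true_effect, sqrt(tau2))
    lapply(seq_len(n_studies), function(i) {
      n <- per_study_n[i]
      grp <- rep(c("case", "control"), each = n)
      vals <- vapply(pathways, function(pw) {
        th <- if (pw == "PWY_effect") theta[i] else 0
        t_case <- rnorm(n, mean_t + th * sd_t, sd_t)
        t_ctrl <- rnorm(n, mean_t, sd_t)
        tt <- pmin(pmax(c(t_case, t_ctrl), 0), pi / 2)
        sin(tt)^2
      }, numeric(2L * n))
      bind_cols(
        tibble(study_id = sprintf("study%02d", i),
               sample_id = sprintf("study%02d_%03d", i, seq_len(2L * n)),
               group = grp),
        as_tibble(vals)
      )
    })
  })
}
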