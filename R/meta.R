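#' Arcsine-square-root transform of a relative abundance
#'
#' The variance-stabilising transform for proportions used before
#' standardized-mean-difference computation: `asin(sqrt(p))`, mapping
#' `[0, 1]` onto `[0, pi/2]`.
#'
#' @param p Numeric vector of proportions in `[0, 1]`.
#' @return Numeric vector in `[0, pi/2]`.
#' @export
#' @examples
#' arcsine_sqrt(c(0, 0.25, 1))
arcsine_sqrt <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p must lie in [0, 1]")
  }
  asin(sqrt(p))
}

#' Standardized mean difference (Hedges' g) from group summaries
#'
#' Cohen's d with the small-sample (Hedges) correction
#' `J = 1 - 3 / (4 * (n1 + n2 - 2) - 1)` and the usual large-sample
#' sampling variance `v = (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2))`.
#' Group 1 is the case group: positive `g` means higher in cases.
#'
#' @param s Data frame with columns `n1`, `n2`, `m1`, `m2`, `s1`, `s2`
#'   (group sizes, means and SDs of the transformed abundances).
#' @return The input as a tibble with columns `g` and `v` appended.
#' @export
#' @examples
#' smd_effect(data.frame(n1 = 10, n2 = 10, m1 = 1, m2 = 0, s1 = 1, s2 = 1))
smd_effect <- function(s) {
  s <- as_tibble(s)
  stopifnot(all(c("n1", "n2", "m1", "m2", "s1", "s2") %in% names(s)))
  if (any(s$n1 < 2 | s$n2 < 2)) stop("group sizes must be >= 2")
  if (any(s$s1 < 0 | s$s2 < 0)) stop("group SDs must be >= 0")
  df <- s$n1 + s$n2 - 2
  sp <- sqrt(((s$n1 - 1) * s$s1^2 + (s$n2 - 1) * s$s2^2) / df)
  if (any(sp == 0)) stop("pooled SD is zero: SMD undefined")
  J <- 1 - 3 / (4 * df - 1)
  g <- J * (s$m1 - s$m2) / sp
  s |> mutate(g = g, v = (s$n1 + s$n2) / (s$n1 * s$n2) + g^2 / (2 * (s$n1 + s$n2)))
}

#' Random-effects pooling of standardized effects
#'
#' Pools per-study effects `(g_i, v_i)` under the random-effects model.
#' `Q = sum w_i (g_i - gbar_w)^2` with fixed-effect weights `w_i = 1/v_i`;
#' the DerSimonian-Laird estimator is
#' `tau2 = max(0, (Q - df) / (sum w_i - sum w_i^2 / sum w_i))`, with REML
#' available as an iterative alternative. The pooled mean uses weights
#' `1 / (v_i + tau2)`; the p-value and 95% CI are Wald-normal.
#'
#' @param effects Data frame with columns `g` and `v` (one row per study).
#' @param method `"DL"` (default) or `"REML"`.
#' @return An object of class `meta_effect`: a list with the per-study
#'   tibble and fields `pooled_mu`, `pooled_se`, `ci_low`, `ci_high`, `Q`,
#'   `df`, `tau2`, `I2`, `p`, `method`.
#' @export
#' @examples
#' pool_random_effects(data.frame(g = c(0.4, 0.6, 0.5), v = c(0.1, 0.1, 0.2)))
pool_random_effects <- function(effects, method = c("DL", "REML")) {
  method <- match.arg(method)
  effects <- as_tibble(effects)
  stopifnot(all(c("g", "v") %in% names(effects)))
  g <- effects$g
  v <- effects$v
  k <- length(g)
  if (k < 2) stop("need at least two studies")
  if (any(v <= 0)) stop("all sampling variances must be positive")
  w <- 1 / v
  gbar <- sum(w * g) / sum(w)
  Q <- sum(w * (g - gbar)^2)
  df <- k - 1
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  if (method == "REML") tau2 <- reml_tau2(g, v, start = tau2)
  wr <- 1 / (v + tau2)
  mu <- sum(wr * g) / sum(wr)
  se <- sqrt(1 / sum(wr))
  structure(
    list(studies = effects, pooled_mu = mu, pooled_se = se,
         ci_low = mu - qnorm(0.975) * se, ci_high = mu + qnorm(0.975) * se,
         Q = Q, df = df, tau2 = tau2, I2 = heterogeneity_i2(Q, df),
         p = 2 * pnorm(-abs(mu / se)), method = method),
    class = "meta_effect"
  )
}

reml_tau2 <- function(g, v, start = 0, upper = NULL) {
  if (is.null(upper)) upper <- max(start, var(g), 1e-3) * 10
  nll <- function(tau2) {
    wr <- 1 / (v + tau2)
    mu <- sum(wr * g) / sum(wr)
    0.5 * (sum(log(v + tau2)) + log(sum(wr)) + sum(wr * (g - mu)^2))
  }
  opt <- stats::optimize(nll, c(0, upper))
  # re-expand the bracket if the optimum sits on the upper edge
  while (opt$minimum > 0.99 * upper && upper < 1e6) {
    upper <- upper * 10
    opt <- stats::optimize(nll, c(0, upper))
  }
  opt$minimum
}

#' Higgins' I-squared heterogeneity statistic
#'
#' @param Q Cochran's Q (>= 0).
#' @param df Degrees of freedom (number of studies minus one).
#' @return Percentage in `[0, 100]`: `max(0, (Q - df) / Q) * 100`.
#' @export
#' @examples
#' heterogeneity_i2(20, 10)
heterogeneity_i2 <- function(Q, df) {
  if (Q < 0) stop("Q must be >= 0")
  if (df < 1) stop("df must be >= 1")
  if (Q == 0) return(0)
  max(0, (Q - df) / Q) * 100
}

#' @export
print.meta_effect <- function(x, ...) {
  cat(sprintf(
    "<meta_effect> %d studies (%s): mu = %.3f [%.3f, %.3f], tau2 = %.4f, I2 = %.1f%%, p = %.3g\n",
    nrow(x$studies), x$method, x$pooled_mu, x$ci_low, x$ci_high,
    x$tau2, x$I2, x$p))
  invisible(x)
}

#' @export
tidy.meta_effect <- function(x, ...) forest_data(x)

#' @export
glance.meta_effect <- function(x, ...) {
  tibble(pooled_mu = x$pooled_mu, pooled_se = x$pooled_se,
         ci_low = x$ci_low, ci_high = x$ci_high, Q = x$Q, df = x$df,
         tau2 = x$tau2, I2 = x$I2, p = x$p, method = x$method,
         n_studies = nrow(x$studies))
}

#' Forest-plot data for a pooled meta-analytic effect
#'
#' @param me A `meta_effect` from [pool_random_effects()].
#' @return A tibble of per-study rows (`g`, 95% `ci_low`/`ci_high`,
#'   `weight`) followed by the pooled summary row.
#' @export
forest_data <- function(me) {
  stopifnot(inherits(me, "meta_effect"))
  st <- me$studies
  lab <- if ("study_id" %in% names(st)) as.character(st$study_id) else
    sprintf("study%02d", seq_len(nrow(st)))
  wr <- 1 / (st$v + me$tau2)
  bind_rows(
    tibble(label = lab, type = "study", g = st$g,
           ci_low = st$g - qnorm(0.975) * sqrt(st$v),
           ci_high = st$g + qnorm(0.975) * sqrt(st$v),
           weight = wr / sum(wr)),
    tibble(label = "pooled", type = "pooled", g = me$pooled_mu,
           ci_low = me$ci_low, ci_high = me$ci_high, weight = 1)
  )
}

#' Meta-analytic screen of microbial pathways across cohorts
#'
#' For every pathway shared by at least two studies: arcsine-square-root
#' transform the relative abundances, summarise each study's case and
#' control groups, compute Hedges' g per study, pool under the
#' random-effects model, then adjust the pooled p-values across pathways
#' with Benjamini-Hochberg. A pathway is flagged significant when both the
#' heterogeneity and FDR gates pass (`I2 < i2_max`, `q < fdr_max`).
#'
#' @param tables List of per-study data frames with a `group` column
#'   (values `"case"`/`"control"`) and one numeric column in `[0, 1]` per
#'   pathway; non-pathway columns `study_id`/`sample_id` are ignored.
#' @param i2_max Heterogeneity gate in percent.
#' @param fdr_max FDR gate.
#' @param method Pooling method, see [pool_random_effects()].
#' @return A tibble ranked by `|pooled_mu|`, one row per pathway, with the
#'   pooled fields, `p`, `q` and `significant`; the per-pathway
#'   `meta_effect` objects are attached as a list-column `fit`.
#' @export
meta_screen <- function(tables, i2_max = 50, fdr_max = 0.05,
                        method = c("DL", "REML")) {
  method <- match.arg(method)
  stopifnot(is.list(tables), length(tables) >= 2)
  id_cols <- c("study_id", "sample_id", "group")
  summaries <- imap(tables, function(tab, i) {
    tab <- as_tibble(tab)
    stopifnot("group" %in% names(tab))
    pw_cols <- setdiff(names(tab), id_cols)
    study <- if ("study_id" %in% names(tab)) as.character(tab$study_id[1]) else
      sprintf("study%02d", i)
    case <- tab$group == "case"
    list_rbind(map(pw_cols, function(pw) {
      a <- arcsine_sqrt(tab[[pw]])
      tibble(study_id = study, pathway_id = pw,
             n1 = sum(case), n2 = sum(!case),
             m1 = mean(a[case]), m2 = mean(a[!case]),
             s1 = sd(a[case]), s2 = sd(a[!case]))
    }))
  }) |> list_rbind()
  fits <- summaries |>
    group_by(.data$pathway_id) |>
    dplyr::group_map(function(d, key) {
      if (nrow(d) < 2) {
        message("pathway ", key$pathway_id, " present in < 2 studies: skipped")
        return(NULL)
      }
      eff <- smd_effect(d)
      me <- pool_random_effects(eff[c("study_id", "g", "v")], method = method)
      tibble(pathway_id = key$pathway_id, n_studies = nrow(d),
             pooled_mu = me$pooled_mu, pooled_se = me$pooled_se,
             ci_low = me$ci_low, ci_high = me$ci_high, Q = me$Q,
             tau2 = me$tau2, I2 = me$I2, p = me$p, fit = list(me))
    }) |> list_rbind()
  if (is.null(fits) || nrow(fits) == 0) stop("no pathway present in >= 2 studies")
  fits |>
    mutate(q = bh_adjust(.data$p),
           significant = .data$I2 < i2_max & .data$q < fdr_max) |>
    arrange(desc(abs(.data$pooled_mu))) |>
    relocate("fit", .after = dplyr::last_col())
}
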