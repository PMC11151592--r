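#' Locus-wise microbiome-methylation association screen
#'
#' The package's core inference. For every CpG locus the (smoothed)
#' methylation level is regressed on the CLR-transformed taxa plus the
#' clinical covariates: a scaled-lasso fit provides the sparse estimate and
#' noise level, de-sparsified (nodewise-projection) inference provides a
#' p-value per predictor, all locus-by-predictor p-values are
#' BH-adjusted in one family (per-locus families optional), and
#' complementary-pairs stability selection provides per-predictor
#' selection frequencies. An association is retained when it passes the
#' FDR gate *and* the stability gate *and* the predictor is a taxon --
#' covariate associations are filtered out by design.
#'
#' @param meth A [meth_calls()] (smoothed internally) or a numeric
#'   loci-by-samples matrix of methylation levels with sample columns
#'   matching the taxa table.
#' @param taxa A [taxa_table()], already through [filter_taxa()].
#' @param covariates Covariate tibble for [build_design()]; defaults to
#'   the taxa table's sample metadata.
#' @param fdr_cut FDR threshold on the debiased q-values (default 0.1).
#' @param cutoff,B,q_sel Stability-selection parameters, see
#'   [stability_selection()].
#' @param family `"global"` pools all locus-by-predictor tests into one BH
#'   family; `"per_locus"` adjusts within each locus.
#' @param window_bp Smoothing window when `meth` is a call set.
#' @param min_var Loci with response variance below this are skipped.
#' @param seed Seed driving CV folds and subsampling.
#' @return An `assoc_screen` object: tibble with one row per (locus,
#'   predictor) holding `beta_lasso`, `beta_debiased`, `se`, `p`, `q`,
#'   `stab_freq`, `passed_fdr`, `passed_stability`, `retained`, plus
#'   attributes `pfer_bound` and `skipped` (locus ids).
#' @export
run_association_screen <- function(meth, taxa, covariates = NULL,
                                   fdr_cut = 0.10, cutoff = 0.75, B = 50L,
                                   q_sel = NULL,
                                   family = c("global", "per_locus"),
                                   window_bp = 500L, min_var = 1e-8,
                                   seed = 1L) {
  family <- match.arg(family)
  stopifnot(inherits(taxa, "taxa_table"))
  Ymat <- if (inherits(meth, "meth_calls")) {
    m <- smooth_methylation(meth, window_bp)
    rownames(m) <- meth$loci$locus_id
    m
  } else as.matrix(meth)
  samples <- rownames(taxa$abundance)
  if (!all(samples %in% colnames(Ymat))) {
    stop("methylation matrix lacks columns for some taxa-table samples")
  }
  Ymat <- Ymat[, samples, drop = FALSE]
  if (anyNA(Ymat)) stop("methylation levels contain missing values")
  design <- build_design(taxa, covariates)
  X <- design$X
  keep <- apply(Ymat, 1, var) >= min_var
  skipped <- rownames(Ymat)[!keep]
  if (length(skipped)) {
    message(length(skipped), " degenerate locus/loci skipped")
  }
  Ymat <- Ymat[keep, , drop = FALSE]
  if (nrow(Ymat) == 0) stop("no testable locus")
  nw <- nodewise_projection(X, lambda = "cv", seed = seed)
  loci <- rownames(Ymat)
  per_locus <- map(loci, function(l) {
    res <- debiased_inference(Ymat[l, ], X, nodewise = nw, seed = seed)
    res$locus_id <- l
    res
  })
  results <- list_rbind(per_locus) |>
    left_join(design$col_info, by = "predictor_id") |>
    relocate("locus_id")
  results$q <- if (family == "global") bh_adjust(results$p) else {
    stats::ave(results$p, results$locus_id, FUN = bh_adjust)
  }
  stab <- stability_frequencies(X, t(Ymat), B = B, q_sel = q_sel,
                                cutoff = cutoff, seed = seed)
  freq_tbl <- tibble(
    locus_id = rep(loci, each = ncol(X)),
    predictor_id = rep(colnames(X), length(loci)),
    stab_freq = as.vector(stab$freq)
  )
  results <- results |>
    left_join(freq_tbl, by = c("locus_id", "predictor_id")) |>
    mutate(passed_fdr = .data$q < fdr_cut,
           passed_stability = .data$stab_freq >= cutoff,
           retained = .data$passed_fdr & .data$passed_stability) |>
    filter_covariate_associations()
  structure(results,
            class = c("assoc_screen", class(results)),
            pfer_bound = stab$pfer_bound, q_sel = stab$q_sel,
            fdr_cut = fdr_cut, cutoff = cutoff, family = family,
            skipped = skipped)
}

#' Drop covariate associations from a screen result
#'
#' Gender, age and disease-subtype associations are never reported as
#' findings: any covariate row has `retained` forced to `FALSE`, taxa rows
#' are untouched. Idempotent.
#'
#' @param results An `assoc_screen` tibble (or any tibble with
#'   `predictor_class` and `retained` columns).
#' @return The input with covariate rows un-retained.
#' @export
filter_covariate_associations <- function(results) {
  stopifnot(all(c("predictor_class", "retained") %in% names(results)))
  results$retained <- results$retained & results$predictor_class == "taxon"
  results
}

#' @export
tidy.assoc_screen <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.assoc_screen <- function(x, ...) {
  tibble(n_loci = length(unique(x$locus_id)),
         n_predictors = length(unique(x$predictor_id)),
         n_retained = sum(x$retained),
         n_passed_fdr = sum(x$passed_fdr),
         n_passed_stability = sum(x$passed_stability),
         fdr_cut = attr(x, "fdr_cut"), cutoff = attr(x, "cutoff"),
         pfer_bound = attr(x, "pfer_bound"), family = attr(x, "family"))
}

#' Retained taxon-locus associations
#'
#' @param x An `assoc_screen` result.
#' @return The retained rows as a plain tibble.
#' @export
retained_associations <- function(x) {
  as_tibble(x)[x$retained, , drop = FALSE]
}

#' Correlate taxon abundances with global methylation levels
#'
#' Per taxon, the Spearman correlation between relative abundance and the
#' per-sample global methylation level, BH-adjusted across taxa. Constant
#' abundance vectors are skipped with a message. Run separately per tissue
#' group when groups are present.
#'
#' @param taxa A [taxa_table()].
#' @param global_levels Named vector from [global_methylation_level()];
#'   names must match the taxa-table samples (>= 5 required).
#' @return Tibble with `taxon_id`, `rho`, `p`, `q`.
#' @export
global_methylation_taxa_correlation <- function(taxa, global_levels) {
  stopifnot(inherits(taxa, "taxa_table"))
  rel <- relative_abundance(taxa)$abundance
  common <- intersect(rownames(rel), names(global_levels))
  if (length(common) < 5) stop("need at least 5 samples with both profiles")
  rel <- rel[common, , drop = FALSE]
  lev <- global_levels[common]
  res <- list_rbind(map(colnames(rel), function(tx) {
    a <- rel[, tx]
    if (sd(a) == 0) {
      message("taxon ", tx, " constant: skipped")
      return(NULL)
    }
    ct <- suppressWarnings(cor.test(a, lev, method = "spearman"))
    tibble(taxon_id = tx, rho = unname(ct$estimate), p = ct$p.value)
  }))
  if (is.null(res) || nrow(res) == 0) stop("no non-constant taxon")
  res |> mutate(q = bh_adjust(.data$p))
}
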