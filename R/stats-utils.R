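#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, validating wrapper around `stats::p.adjust(method = "BH")`:
#' `q_(i) = min_{j >= i} p_(j) * m / j` over the sorted p-values, with ties
#' handled stably.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Rank correlation between paired feature profiles
#'
#' Per shared feature (column), the Spearman correlation across subjects
#' between two aligned matrices -- e.g. fecal vs tissue taxon or pathway
#' abundances of the same patients -- with BH q-values across features.
#' Features with fewer than `min_pairs` complete pairs are skipped with a
#' message.
#'
#' @param fecal,tissue Numeric matrices or data frames (subjects x
#'   features) with matching row order and shared column names.
#' @param min_pairs Minimum number of complete pairs per feature.
#' @return A tibble with columns `feature`, `n`, `rho`, `p`, `q`.
#' @export
paired_feature_correlation <- function(fecal, tissue, min_pairs = 5L) {
  fecal <- as.matrix(fecal)
  tissue <- as.matrix(tissue)
  feats <- intersect(colnames(fecal), colnames(tissue))
  if (length(feats) == 0) stop("no shared features")
  if (nrow(fecal) != nrow(tissue)) stop("subject counts differ")
  res <- list_rbind(map(feats, function(f) {
    ok <- complete.cases(fecal[, f], tissue[, f])
    if (sum(ok) < min_pairs) {
      message("feature ", f, ": fewer than ", min_pairs,
              " complete pairs, skipped")
      return(NULL)
    }
    ct <- suppressWarnings(
      cor.test(fecal[ok, f], tissue[ok, f], method = "spearman"))
    tibble(feature = f, n = sum(ok),
           rho = unname(ct$estimate), p = ct$p.value)
  }))
  if (is.null(res) || nrow(res) == 0) stop("no feature with enough pairs")
  res |> mutate(q = bh_adjust(.data$p))
}
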