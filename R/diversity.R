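#' Alpha-diversity indices
#'
#' Standard community indices from one sample's abundance vector. Shannon
#' and Simpson are delegated to `vegan::diversity`; richness, Pielou
#' evenness, Chao1 and ACE use the classical formulas: Chao1 is
#' `S_obs + F1^2 / (2 F2)` (bias-corrected `S_obs + F1 (F1 - 1) / 2` when
#' no doubletons exist) and ACE the abundance-based coverage estimator with
#' the usual rare-species threshold of 10. Chao1 and ACE require integer
#' counts. A single-taxon sample has zero Shannon entropy and, by the
#' package's convention, Pielou evenness 0 (with a warning), since
#' `H / log(S)` is undefined at `S = 1`.
#'
#' @param counts Non-negative abundance vector for one sample.
#' @param metric One of `"richness"`, `"shannon"`, `"simpson"`, `"pielou"`,
#'   `"chao1"`, `"ace"`.
#' @return A single numeric value.
#' @export
#' @examples
#' alpha_diversity(c(10, 10, 10, 10), "shannon")  # log(4)
#' alpha_diversity(c(rep(1, 4), rep(2, 2), rep(5, 4)), "chao1")
alpha_diversity <- function(counts,
                            metric = c("richness", "shannon", "simpson",
                                       "pielou", "chao1", "ace")) {
  metric <- match.arg(metric)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative")
  }
  if (sum(counts) == 0) stop("all-zero abundance vector")
  x <- counts[counts > 0]
  S <- length(x)
  if (metric %in% c("chao1", "ace") && any(x != round(x))) {
    stop(metric, " requires integer counts")
  }
  switch(metric,
    richness = S,
    shannon = unname(vegan::diversity(counts, index = "shannon")),
    simpson = unname(vegan::diversity(counts, index = "simpson")),
    pielou = {
      if (S == 1) {
        warning("single taxon: Pielou evenness undefined, returning 0")
        0
      } else {
        unname(vegan::diversity(counts, index = "shannon")) / log(S)
      }
    },
    chao1 = {
      F1 <- sum(x == 1)
      F2 <- sum(x == 2)
      if (F2 > 0) S + F1^2 / (2 * F2) else S + F1 * (F1 - 1) / 2
    },
    ace = ace_index(x)
  )
}

# Chao & Lee abundance-based coverage estimator, rare threshold 10
ace_index <- function(x, rare_max = 10L) {
  rare <- x[x <= rare_max]
  S_abund <- sum(x > rare_max)
  S_rare <- length(rare)
  if (S_rare == 0) return(S_abund)
  N_rare <- sum(rare)
  F1 <- sum(rare == 1)
  if (N_rare == F1) {
    # no coverage information; fall back to Chao1-style correction
    return(S_abund + S_rare + F1 * (F1 - 1) / 2)
  }
  C_ace <- 1 - F1 / N_rare
  Fi <- vapply(seq_len(rare_max), function(i) sum(rare == i), numeric(1))
  gamma2 <- max(
    S_rare / C_ace * sum(seq_len(rare_max) * (seq_len(rare_max) - 1) * Fi) /
      (N_rare * (N_rare - 1)) - 1,
    0)
  S_abund + S_rare / C_ace + F1 / C_ace * gamma2
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(i, j) = 1 - 2 sum_k min(x_ik, x_jk) / sum_k (x_ik + x_jk)`, computed
#' with `vegan::vegdist`. Values lie in `[0, 1]` with a zero diagonal.
#'
#' @param t A [taxa_table()] or samples-by-taxa matrix with >= 2 samples.
#' @return A symmetric matrix with sample labels.
#' @export
#' @examples
#' bray_curtis(matrix(c(2, 0, 2, 2, 0, 2), 2, 3,
#'             dimnames = list(c("a", "b"), NULL)))
bray_curtis <- function(t) {
  x <- if (inherits(t, "taxa_table")) t$abundance else as.matrix(t)
  if (nrow(x) < 2) stop("need at least two samples")
  if (any(rowSums(x) == 0)) stop("all-zero sample: Bray-Curtis undefined")
  as.matrix(vegan::vegdist(x, method = "bray"))
}

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and returns the top-`k`
#' coordinates scaled by the square roots of the (non-negative)
#' eigenvalues, sorted by eigenvalue. The sign of each axis is fixed so
#' that its largest-magnitude loading is positive.
#'
#' @param d Distance matrix (symmetric, zero diagonal) or `dist` object.
#' @param k Number of axes (`0 < k < n`).
#' @return A list with `coordinates` (samples x k, named `PCo1..PCok`),
#'   `eigenvalues` (all `n - 1`) and `var_explained` (fractions over the
#'   positive eigenvalues).
#' @export
pcoa_ordination <- function(d, k = 2L) {
  dm <- as.matrix(d)
  if (k <= 0) stop("k must be positive")
  if (k >= nrow(dm)) stop("k must be smaller than the number of samples")
  if (max(abs(dm - base::t(dm))) > 1e-12 || any(diag(dm) != 0)) {
    stop("d must be symmetric with a zero diagonal")
  }
  fit <- cmdscale(stats::as.dist(dm), k = k, eig = TRUE)
  coords <- fit$points
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  pos <- fit$eig[fit$eig > 0]
  list(coordinates = coords,
       eigenvalues = fit$eig[seq_len(nrow(dm) - 1L)],
       var_explained = fit$eig[seq_len(ncol(coords))] / sum(pos))
}
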