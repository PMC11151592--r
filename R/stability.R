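#' Complementary-pairs stability selection
#'
#' Draws `B` random splits of the samples into complementary halves of
#' size `floor(n / 2)`; on each of the `2B` half-samples the lasso path is
#' followed until `q_sel` predictors have entered, and those first
#' `q_sel` entrants are the subsample's selected set. A predictor's
#' stability frequency is the fraction of half-samples selecting it; it is
#' selected when the frequency reaches `cutoff`. The reported
#' per-family expected false positives (PFER) bound is
#' `q_sel^2 / ((2 cutoff - 1) p)`.
#'
#' @param y Numeric response.
#' @param X A `design_matrix` or numeric matrix; `n >= 20` samples.
#' @param B Number of complementary pairs (so `2B` subsamples).
#' @param q_sel Per-subsample selection bound; default `ceiling(sqrt(p))`.
#' @param cutoff Selection-frequency threshold, must exceed 0.5.
#' @param seed Integer seed for the subsample draws.
#' @return Tibble with `predictor_id`, `stab_freq`, `selected`; the PFER
#'   bound is attached as attribute `pfer_bound`.
#' @export
stability_selection <- function(y, X, B = 50L, q_sel = NULL, cutoff = 0.75,
                                seed = 1L) {
  Xm <- if (inherits(X, "design_matrix")) X$X else as.matrix(X)
  if (length(y) != nrow(Xm)) stop("length(y) does not match nrow(X)")
  if (nrow(Xm) < 20) stop("stability selection needs n >= 20")
  freq <- stability_frequencies(Xm, matrix(y, ncol = 1), B = B,
                                q_sel = q_sel, cutoff = cutoff, seed = seed)
  tibble(predictor_id = colnames(Xm), stab_freq = freq$freq[, 1],
         selected = freq$freq[, 1] >= cutoff) |>
    structure(pfer_bound = freq$pfer_bound, q_sel = freq$q_sel)
}

# Workhorse shared by stability_selection() and run_association_screen():
# the same 2B half-samples are reused for every response column of Y.
stability_frequencies <- function(X, Y, B = 50L, q_sel = NULL,
                                  cutoff = 0.75, seed = 1L) {
  n <- nrow(X)
  p <- ncol(X)
  if (cutoff <= 0.5 || cutoff > 1) {
    stop("cutoff must lie in (0.5, 1]: the error bound is undefined otherwise")
  }
  if (is.null(q_sel)) q_sel <- ceiling(sqrt(p))
  q_sel <- as.integer(q_sel)
  if (q_sel < 1 || q_sel > p) stop("q_sel must lie in [1, p]")
  half <- n %/% 2L
  counts <- matrix(0L, p, ncol(Y))
  with_component_seed(seed, "stability", {
    for (b in seq_len(B)) {
      perm <- sample.int(n)
      for (rows in list(perm[seq_len(half)], perm[half + seq_len(half)])) {
        sel <- lasso_first_q(X[rows, , drop = FALSE],
                             Y[rows, , drop = FALSE], q_sel)
        counts <- counts + sel
      }
    }
  })
  list(freq = counts / (2 * B),
       pfer_bound = q_sel^2 / ((2 * cutoff - 1) * p),
       q_sel = q_sel)
}
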