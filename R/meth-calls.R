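#' Methylation call set
#'
#' Per-sample CpG bisulfite counts: for every locus and sample, the total
#' coverage `N` and the methylated read count `X`. Loci are kept sorted by
#' `(chrom, pos)` (1-based positions, unique within a chromosome).
#'
#' @param loci Tibble with columns `locus_id`, `chrom`, `pos`.
#' @param N,X Integer matrices (loci x samples) with identical dimnames;
#'   `0 <= X <= N` cell-wise.
#' @return An object of class `meth_calls`.
#' @export
meth_calls <- function(loci, N, X) {
  loci <- as_tibble(loci)
  stopifnot(all(c("locus_id", "chrom", "pos") %in% names(loci)),
            is.matrix(N), is.matrix(X),
            all(dim(N) == dim(X)), nrow(N) == nrow(loci))
  if (any(X < 0) || any(N < 0) || any(X > N)) {
    stop("invalid counts: need 0 <= X <= N at every cell")
  }
  if (is.null(colnames(N))) stop("N and X need sample column names")
  if (is.null(colnames(X))) colnames(X) <- colnames(N)
  if (!identical(colnames(N), colnames(X))) stop("N/X sample names differ")
  ord <- order(loci$chrom, loci$pos)
  loci <- loci[ord, ]
  N <- N[ord, , drop = FALSE]
  X <- X[ord, , drop = FALSE]
  if (any(duplicated(loci[c("chrom", "pos")]))) {
    stop("duplicate (chrom, pos) locus")
  }
  rownames(N) <- rownames(X) <- loci$locus_id
  structure(list(loci = loci, N = N, X = X), class = "meth_calls")
}

#' @export
print.meth_calls <- function(x, ...) {
  cat(sprintf("<meth_calls> %d loci x %d samples, %d chromosome(s)\n",
              nrow(x$N), ncol(x$N), length(unique(x$loci$chrom))))
  invisible(x)
}

#' @export
dim.meth_calls <- function(x) dim(x$N)

#' @export
tidy.meth_calls <- function(x, ...) {
  bind_cols(
    x$loci[rep(seq_len(nrow(x$loci)), ncol(x$N)), ],
    tibble(sample_id = rep(colnames(x$N), each = nrow(x$N)),
           N = as.vector(x$N), X = as.vector(x$X))
  ) |>
    mutate(level = ifelse(.data$N > 0, .data$X / .data$N, NA_real_))
}

n_samples <- function(calls) ncol(calls$N)

#' Retain CpG loci with adequate coverage in every sample
#'
#' @param calls A [meth_calls()].
#' @param min_depth Minimum coverage; a locus is retained when `N >=
#'   min_depth` for every sample of the set (see Details).
#' @details The depth rule is applied per sample across all samples of the
#'   comparison: one shallow sample drops the locus for everyone, so that
#'   group means are always computed over a common locus set.
#' @return A filtered `meth_calls`.
#' @export
depth_filter <- function(calls, min_depth = 10L) {
  stopifnot(inherits(calls, "meth_calls"))
  keep <- rowSums(calls$N >= min_depth) == ncol(calls$N)
  if (!any(keep)) {
    stop(sprintf("depth_filter(min_depth = %d) removed all %d loci",
                 min_depth, nrow(calls$N)))
  }
  meth_calls(calls$loci[keep, ], calls$N[keep, , drop = FALSE],
             calls$X[keep, , drop = FALSE])
}

#' Coverage-weighted smoothing of methylation levels
#'
#' For each locus the smoothed level is the ratio of summed methylated to
#' summed total counts over all loci of the same chromosome within
#' `window_bp / 2` on either side -- a coverage-weighted moving average.
#' Loci with no neighbour inside the window are returned unchanged (X/N).
#'
#' @param calls A [meth_calls()].
#' @param window_bp Full window width in bp; `0` disables smoothing.
#' @return A loci-by-samples matrix of smoothed proportions.
#' @export
smooth_methylation <- function(calls, window_bp = 500L) {
  stopifnot(inherits(calls, "meth_calls"))
  if (window_bp < 0) stop("window_bp must be >= 0")
  half <- window_bp / 2
  Xs <- calls$X * 0
  Ns <- calls$N * 0
  for (ch in unique(calls$loci$chrom)) {
    idx <- which(calls$loci$chrom == ch)
    pos <- calls$loci$pos[idx]
    # loci are sorted, so the window is a contiguous run
    lo <- findInterval(pos - half, pos, left.open = TRUE) + 1L
    hi <- findInterval(pos + half, pos)
    cx <- rbind(0, apply(calls$X[idx, , drop = FALSE], 2, cumsum))
    cn <- rbind(0, apply(calls$N[idx, , drop = FALSE], 2, cumsum))
    Xs[idx, ] <- cx[hi + 1L, , drop = FALSE] - cx[lo, , drop = FALSE]
    Ns[idx, ] <- cn[hi + 1L, , drop = FALSE] - cn[lo, , drop = FALSE]
  }
  out <- ifelse(Ns > 0, Xs / Ns, NA_real_)
  dimnames(out) <- dimnames(calls$N)
  out
}

#' Per-sample global methylation level
#'
#' Unweighted mean of X/N over all (depth-filtered) loci of each sample.
#'
#' @param calls A [meth_calls()], ideally already through [depth_filter()].
#' @return A named numeric vector, one value in `[0, 1]` per sample.
#' @export
global_methylation_level <- function(calls) {
  stopifnot(inherits(calls, "meth_calls"))
  if (nrow(calls$N) == 0) stop("no retained loci")
  if (any(colSums(calls$N > 0) == 0)) stop("sample with no covered locus")
  lev <- colMeans(ifelse(calls$N > 0, calls$X / calls$N, NA), na.rm = TRUE)
  setNames(lev, colnames(calls$N))
}
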