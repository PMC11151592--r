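#' Taxa abundance table
#'
#' Container for a samples-by-taxa abundance matrix together with taxonomy
#' lineage strings and per-sample metadata. Rows are samples, columns taxa.
#'
#' @param abundance Numeric matrix (samples x taxa) with unique row and
#'   column names, or a data frame with a `sample_id` column followed by
#'   numeric taxon columns.
#' @param taxonomy Optional tibble with columns `taxon_id`, `lineage`.
#' @param sample_meta Optional tibble with a `sample_id` column.
#' @param is_relative Logical; `TRUE` if rows are proportions summing to 1.
#'
#' @return An object of class `taxa_table`.
#' @export
#' @examples
#' m <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(paste0("S", 1:3), paste0("t", 1:4)))
#' tt <- taxa_table(m)
#' dim(tt$abundance)
taxa_table <- function(abundance, taxonomy = NULL, sample_meta = NULL,
                       is_relative = FALSE) {
  if (is.data.frame(abundance)) {
    stopifnot("sample_id" %in% names(abundance))
    ids <- as.character(abundance$sample_id)
    abundance <- as.matrix(abundance[setdiff(names(abundance), "sample_id")])
    rownames(abundance) <- ids
  }
  stopifnot(is.matrix(abundance), is.numeric(abundance))
  if (is.null(rownames(abundance)) ||
      (ncol(abundance) > 0 && is.null(colnames(abundance)))) {
    stop("abundance matrix needs sample rownames and taxon colnames")
  }
  if (anyDuplicated(colnames(abundance))) stop("taxon identifiers must be unique")
  if (anyDuplicated(rownames(abundance))) stop("sample identifiers must be unique")
  if (any(abundance < 0)) stop("abundance matrix has negative entries")
  if (isTRUE(is_relative)) {
    rs <- rowSums(abundance)
    if (any(abs(rs - 1) > 1e-8)) {
      stop("is_relative = TRUE but some sample rows do not sum to 1")
    }
  }
  if (is.null(taxonomy)) {
    cn <- colnames(abundance)
    if (is.null(cn)) cn <- character(0)
    taxonomy <- tibble(taxon_id = cn, lineage = cn)
  }
  stopifnot(all(c("taxon_id", "lineage") %in% names(taxonomy)))
  if (!setequal(taxonomy$taxon_id, colnames(abundance))) {
    stop("taxonomy does not match abundance columns")
  }
  if (is.null(sample_meta)) {
    sample_meta <- tibble(sample_id = rownames(abundance))
  }
  stopifnot("sample_id" %in% names(sample_meta))
  structure(
    list(abundance = abundance,
         taxonomy = as_tibble(taxonomy)[match(colnames(abundance), taxonomy$taxon_id), ],
         sample_meta = as_tibble(sample_meta)[match(rownames(abundance), sample_meta$sample_id), ],
         is_relative = isTRUE(is_relative)),
    class = "taxa_table"
  )
}

#' @export
print.taxa_table <- function(x, ...) {
  cat(sprintf("<taxa_table> %d samples x %d taxa (%s)\n",
              nrow(x$abundance), ncol(x$abundance),
              if (x$is_relative) "relative" else "counts"))
  invisible(x)
}

#' @export
dim.taxa_table <- function(x) dim(x$abundance)

#' Convert a taxa table to relative abundances
#'
#' @param t A [taxa_table()].
#' @return A `taxa_table` whose rows sum to 1.
#' @export
relative_abundance <- function(t) {
  stopifnot(inherits(t, "taxa_table"))
  if (t$is_relative) return(t)
  rs <- rowSums(t$abundance)
  if (any(rs <= 0)) stop("cannot normalise: sample(s) with zero total abundance")
  taxa_table(t$abundance / rs, t$taxonomy, t$sample_meta, is_relative = TRUE)
}

#' @export
tidy.taxa_table <- function(x, ...) {
  as_tibble(x$abundance, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "taxon_id",
                        values_to = "abundance") |>
    left_join(x$taxonomy, by = "taxon_id")
}

#' Prevalence-abundance filtering of taxa
#'
#' Retains taxa whose relative abundance strictly exceeds `min_abund` in
#' strictly more than `min_prev` of the samples -- the standard retention
#' rule for amplicon and metagenomic profiles (defaults: relative abundance
#' > 1e-4 in more than 10% of samples). Column order is preserved.
#'
#' @param t A [taxa_table()].
#' @param min_abund Relative-abundance threshold (strict).
#' @param min_prev Prevalence threshold as a fraction of samples (strict).
#' @return A filtered `taxa_table` on the original (count or relative) scale.
#' @export
#' @examples
#' m <- matrix(c(5000, 5000, 1, 9999), 2, 2,
#'             dimnames = list(c("a", "b"), c("t1", "t2")))
#' dim(filter_taxa(taxa_table(m)))
filter_taxa <- function(t, min_abund = 1e-4, min_prev = 0.10) {
  stopifnot(inherits(t, "taxa_table"))
  rel <- relative_abundance(t)$abundance
  n <- nrow(rel)
  keep <- colSums(rel > min_abund) > min_prev * n
  if (!any(keep)) {
    warning("filter_taxa removed every taxon")
  }
  # dropping columns of a relative table leaves a subcomposition whose
  # rows no longer close to 1, so the flag only survives a no-op filter
  taxa_table(t$abundance[, keep, drop = FALSE],
             t$taxonomy[keep, , drop = FALSE],
             t$sample_meta, is_relative = t$is_relative && all(keep))
}

#' Centered log-ratio transform
#'
#' Per sample, `clr_i = log((x_i + c) / g)` where `g` is the geometric mean
#' of the shifted composition; rows of the result sum to zero. The default
#' pseudocount is half the smallest non-zero relative abundance in the
#' table, the usual compositional-data convention; it is only applied when
#' zeros are present.
#'
#' @param t A [taxa_table()] or a non-negative samples-by-taxa matrix.
#' @param pseudocount Positive shift added before taking logs, or `NULL`
#'   for the default.
#' @return A samples-by-taxa numeric matrix.
#' @export
#' @examples
#' clr_transform(matrix(c(1, 1, 2), 1, 3,
#'               dimnames = list("s1", c("a", "b", "c"))))
clr_transform <- function(t, pseudocount = NULL) {
  x <- if (inherits(t, "taxa_table")) relative_abundance(t)$abundance else {
    stopifnot(is.matrix(t), all(t >= 0))
    rs <- rowSums(t)
    if (any(rs <= 0)) stop("all-zero sample: CLR undefined")
    t / rs
  }
  if (any(rowSums(x) <= 0)) stop("all-zero sample: CLR undefined")
  if (is.null(pseudocount)) {
    pseudocount <- if (any(x == 0)) min(x[x > 0]) / 2 else 0
  }
  if (any(x == 0) && pseudocount <= 0) {
    stop("zeros present: pseudocount must be > 0")
  }
  lx <- log(x + pseudocount)
  sweep(lx, 1, rowMeans(lx))
}
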