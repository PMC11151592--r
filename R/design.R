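#' Build the standardized predictor matrix for the association screen
#'
#' CLR-transforms the (filtered) taxa table, appends the covariate columns
#' (gender 0/1, age in years, subtype 0/1) untransformed, and standardizes
#' every column to mean 0 / unit variance. Zero-variance columns are
#' dropped with a message. The standardization constants are retained so
#' the transform can be inverted.
#'
#' @param taxa A [taxa_table()], already through [filter_taxa()].
#' @param covariates Tibble with a `sample_id` column plus any of
#'   `gender`, `age`, `subtype`; defaults to the table's own sample
#'   metadata. `NULL` columns are simply absent from the design.
#' @param pseudocount Passed to [clr_transform()].
#' @return An object of class `design_matrix`: list with `X` (n x (K + C)
#'   standardized matrix), `col_info` (tibble: `predictor_id`,
#'   `predictor_class`), `center`, `scale`.
#' @export
build_design <- function(taxa, covariates = NULL, pseudocount = NULL) {
  stopifnot(inherits(taxa, "taxa_table"))
  if (is.null(covariates)) covariates <- taxa$sample_meta
  covariates <- as_tibble(covariates)
  stopifnot("sample_id" %in% names(covariates))
  idx <- match(rownames(taxa$abundance), covariates$sample_id)
  if (anyNA(idx)) stop("sample mismatch between taxa table and covariates")
  covariates <- covariates[idx, ]
  clr <- clr_transform(taxa, pseudocount)
  cov_cols <- intersect(c("gender", "age", "subtype"), names(covariates))
  C <- as.matrix(covariates[cov_cols])
  if (length(cov_cols)) {
    storage.mode(C) <- "double"
    rownames(C) <- covariates$sample_id
  }
  X <- cbind(clr, if (length(cov_cols)) C)
  if (anyNA(X)) stop("design matrix has missing entries")
  col_class <- c(rep("taxon", ncol(clr)), rep("covariate", length(cov_cols)))
  sds <- apply(X, 2, sd)
  drop <- sds < 1e-12
  if (any(drop)) {
    message("dropping zero-variance column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, !drop, drop = FALSE]
    col_class <- col_class[!drop]
    sds <- sds[!drop]
  }
  if (ncol(X) == 0) stop("no usable predictor columns")
  ctr <- colMeans(X)
  Xs <- scale(X, center = ctr, scale = sds)
  attr(Xs, "scaled:center") <- NULL
  attr(Xs, "scaled:scale") <- NULL
  structure(
    list(X = Xs,
         col_info = tibble(predictor_id = colnames(X),
                           predictor_class = col_class),
         center = ctr, scale = sds),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d samples x %d predictors (%d taxa, %d covariates)\n",
              nrow(x$X), ncol(x$X),
              sum(x$col_info$predictor_class == "taxon"),
              sum(x$col_info$predictor_class == "covariate")))
  invisible(x)
}

#' Undo the standardization of a design matrix
#'
#' @param design A `design_matrix`.
#' @return The unstandardized matrix (CLR values and raw covariates).
#' @export
destandardize_design <- function(design) {
  stopifnot(inherits(design, "design_matrix"))
  sweep(sweep(design$X, 2, design$scale, `*`), 2, design$center, `+`)
}
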