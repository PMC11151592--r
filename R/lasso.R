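#' Cross-validated lasso fit for one locus
#'
#' Coordinate-descent lasso (via glmnet) with the penalty chosen by 10-fold
#' cross-validation and the 1-SE rule by default; the intercept is
#' unpenalized and the folds are seeded, so the fit is deterministic.
#'
#' @param y Numeric response (methylation levels of one locus).
#' @param X A `design_matrix` from [build_design()] or a numeric matrix.
#' @param lambda_rule `"1se"` (default) or `"min"`; alternatively a single
#'   numeric penalty to skip cross-validation (`0` gives the least-squares
#'   fit).
#' @param nfolds Number of CV folds.
#' @param seed Seed for the fold assignment.
#' @return Named numeric vector of penalized coefficients, with attributes
#'   `intercept` and `lambda`.
#' @export
fit_locus_lasso <- function(y, X, lambda_rule = "1se", nfolds = 10L,
                            seed = 1L) {
  Xm <- if (inherits(X, "design_matrix")) X$X else as.matrix(X)
  if (!all(is.finite(y))) stop("y must be finite")
  if (length(y) != nrow(Xm)) stop("length(y) does not match nrow(X)")
  if (is.numeric(lambda_rule)) {
    fit <- glmnet_at(Xm, y, lambda_rule)
    return(fit$beta_attr)
  }
  lambda_rule <- match.arg(lambda_rule, c("1se", "min"))
  nfolds <- min(nfolds, max(3L, length(y) %/% 3L))
  foldid <- with_component_seed(seed, "folds",
                                sample(rep_len(seq_len(nfolds), length(y))))
  cv <- glmnet::cv.glmnet(Xm, y, foldid = foldid, standardize = FALSE)
  lam <- if (lambda_rule == "1se") cv$lambda.1se else cv$lambda.min
  cf <- suppressWarnings(as.numeric(coef(cv, s = lam)))
  structure(setNames(cf[-1], colnames(Xm)), intercept = cf[1], lambda = lam)
}

# Fit glmnet along a path ending at `lambda` and extract that solution;
# warm-starting down the path is both faster and more accurate than a
# single-lambda call, and lambda = 0 then reproduces least squares.
glmnet_at <- function(X, y, lambda, thresh = 1e-12) {
  sdy <- sd(y)
  if (sdy == 0) {
    beta <- structure(setNames(numeric(ncol(X)), colnames(X)),
                      intercept = mean(y), lambda = lambda)
    return(list(beta_attr = beta, beta = beta, a0 = mean(y)))
  }
  lam_max <- max(abs(crossprod(X - rep(1, nrow(X)) %o% colMeans(X),
                               y - mean(y)))) / nrow(X)
  lam_max <- max(lam_max, lambda * 1.001, 1e-12)
  path <- exp(seq(log(lam_max), log(max(lambda, lam_max * 1e-5)), length.out = 30))
  if (lambda < min(path)) path <- c(path, lambda)
  fit <- glmnet::glmnet(X, y, lambda = path, standardize = FALSE,
                        thresh = thresh)
  cf <- suppressWarnings(as.numeric(coef(fit, s = lambda, exact = FALSE)))
  beta <- cf[-1]
  a0 <- cf[1]
  b <- structure(setNames(beta, colnames(X)), intercept = a0, lambda = lambda)
  list(beta_attr = b, beta = beta, a0 = a0)
}

#' Scaled-lasso estimate of coefficients and noise level
#'
#' Joint estimation of the lasso coefficients and the noise standard
#' deviation by alternating `sigma_hat = ||y - X beta||_2 / sqrt(n)` with a
#' lasso fit at `lambda = sigma_hat * lambda0`, where
#' `lambda0 = sqrt(2 log(p) / n)` is the universal penalty level.
#'
#' @param X Numeric matrix (standardized columns).
#' @param y Numeric response.
#' @param lambda0 Penalty level; default `sqrt(2 * log(p) / n)`.
#' @param max_iter,tol Convergence controls on `sigma_hat`.
#' @return List with `beta` (named), `intercept`, `sigma`, `lambda`.
#' @export
scaled_lasso <- function(X, y, lambda0 = NULL, max_iter = 25L, tol = 1e-4) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(lambda0)) lambda0 <- sqrt(2 * log(max(p, 2)) / n)
  sigma <- max(sd(y), 1e-8)
  fit <- NULL
  for (it in seq_len(max_iter)) {
    fit <- glmnet_at(X, y, sigma * lambda0)
    res <- y - fit$a0 - drop(X %*% fit$beta)
    sigma_new <- max(sqrt(sum(res^2) / n), 1e-8)
    if (abs(sigma_new - sigma) < tol * sigma) {
      sigma <- sigma_new
      break
    }
    sigma <- sigma_new
  }
  list(beta = fit$beta_attr, intercept = fit$a0, sigma = sigma,
       lambda = sigma * lambda0)
}

#' Nodewise-lasso projection scores for de-sparsified inference
#'
#' For each column `j`, regresses `X_j` on the remaining columns with the
#' lasso and stores the residual `Z_j`. These projections depend only on
#' the design, so they are computed once and reused across loci.
#'
#' @param X Numeric matrix (standardized columns).
#' @param lambda Either `"cv"` (per-column 10-fold CV, 1-SE rule) or a
#'   single numeric penalty used for every column.
#' @param seed Seed for the CV folds.
#' @return An object of class `nodewise_projection`: list with `Z`
#'   (n x p), `zx = diag(Z^T X)`, `znorm2 = colSums(Z^2)` and
#'   `identifiable` (logical per column).
#' @export
nodewise_projection <- function(X, lambda = "cv", seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  Z <- matrix(0, n, p, dimnames = dimnames(X))
  nfolds <- min(10L, max(3L, n %/% 3L))
  foldid <- with_component_seed(seed, "folds",
                                sample(rep_len(seq_len(nfolds), n)))
  for (j in seq_len(p)) {
    Xj <- X[, j]
    Xmj <- X[, -j, drop = FALSE]
    if (identical(lambda, "cv")) {
      cv <- glmnet::cv.glmnet(Xmj, Xj, foldid = foldid, standardize = FALSE)
      gam <- suppressWarnings(as.numeric(coef(cv, s = cv$lambda.1se)))
    } else {
      f <- glmnet_at(Xmj, Xj, lambda)
      gam <- c(f$a0, f$beta)
    }
    Z[, j] <- Xj - gam[1] - drop(Xmj %*% gam[-1])
  }
  zx <- colSums(Z * X)
  znorm2 <- colSums(Z^2)
  xnorm2 <- colSums(X^2)
  # Z_j is a residual, so Z_j' X_j = ||Z_j||^2 up to the intercept; a
  # projection that explains X_j (almost) perfectly - e.g. a duplicated
  # column - leaves nothing to identify the coefficient with
  identifiable <- zx > 1e-4 * pmax(xnorm2, .Machine$double.eps)
  structure(list(Z = Z, zx = zx, znorm2 = znorm2, identifiable = identifiable),
            class = "nodewise_projection")
}

#' De-sparsified (debiased) lasso inference
#'
#' Corrects the lasso estimate by projecting the residual onto the
#' nodewise scores: `b_j = beta_j + Z_j^T (y - X beta) / (Z_j^T X_j)`, with
#' standard error `sigma_hat * ||Z_j||_2 / |Z_j^T X_j|` and two-sided
#' p-values from a t reference with `n - df_hat - 1` degrees of freedom
#' (`df_hat` = size of the active set). The residual degrees of freedom
#' also enter the noise estimate, so in the low-dimensional small-penalty
#' limit the procedure reproduces the classical t-test exactly; at
#' moderate n the t tail keeps the extreme quantiles honest where a normal
#' reference would be anti-conservative. The initial fit and noise level
#' come from the scaled lasso unless `lambda` is given. Columns whose
#' projection is numerically degenerate (e.g. duplicated predictors) are
#' flagged unidentifiable and assigned `p = 1`.
#'
#' @param y Numeric response.
#' @param X A `design_matrix` or numeric matrix with standardized columns.
#' @param lambda Optional numeric penalty for both the initial fit and the
#'   nodewise regressions (e.g. ~0 to reproduce least squares when
#'   `p < n`); default uses the scaled lasso and CV nodewise penalties.
#' @param nodewise Optional precomputed [nodewise_projection()].
#' @param seed Seed for CV folds.
#' @return Tibble with one row per column: `predictor_id`,
#'   `beta_lasso`, `beta_debiased`, `se`, `p`, `identifiable`.
#' @export
debiased_inference <- function(y, X, lambda = NULL, nodewise = NULL,
                               seed = 1L) {
  Xm <- if (inherits(X, "design_matrix")) X$X else as.matrix(X)
  if (length(y) != nrow(Xm)) stop("length(y) does not match nrow(X)")
  n <- nrow(Xm)
  if (is.null(nodewise)) {
    nodewise <- nodewise_projection(Xm, lambda = if (is.null(lambda)) "cv" else lambda,
                                    seed = seed)
  }
  if (is.null(lambda)) {
    # softer than the universal level: the full sqrt(2 log p / n)
    # over-shrinks at these sample sizes, inflating sigma_hat and costing
    # power; the residual-df t reference keeps the softer fit honest
    # under the null
    sl <- scaled_lasso(Xm, y, lambda0 = 0.7 * sqrt(2 * log(max(ncol(Xm), 2)) /
                                                     nrow(Xm)))
    beta <- as.numeric(sl$beta)
    a0 <- sl$intercept
    df_resid <- max(n - sum(beta != 0) - 1, 1)
    # scaled-lasso sigma uses RSS / n; rescale to residual df
    sigma <- sl$sigma * sqrt(n / df_resid)
  } else {
    f <- glmnet_at(Xm, y, lambda)
    beta <- f$beta
    a0 <- f$a0
    res0 <- y - a0 - drop(Xm %*% beta)
    df_resid <- max(n - sum(beta != 0) - 1, 1)
    sigma <- sqrt(sum(res0^2) / df_resid)
  }
  r <- y - a0 - drop(Xm %*% beta)
  ok <- nodewise$identifiable
  b <- beta + ifelse(ok, colSums(nodewise$Z * r) / nodewise$zx, 0)
  se <- ifelse(ok, sigma * sqrt(nodewise$znorm2) / abs(nodewise$zx), NA_real_)
  p <- ifelse(ok, 2 * stats::pt(-abs(b / se), df = df_resid), 1)
  tibble(predictor_id = colnames(Xm), beta_lasso = beta,
         beta_debiased = ifelse(ok, b, NA_real_), se = se, p = p,
         identifiable = ok)
}
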