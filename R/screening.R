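#' Regress covariates out of every feature column
#'
#' Replaces each feature column by the residuals of a least-squares fit on an
#' intercept plus the covariate columns (gender, education level, ...).
#' Constant covariate columns are dropped (leaving centering only if all are
#' constant); a rank-deficient design among the non-constant covariates is an
#' error naming the collinear columns.
#'
#' When `newdata` is supplied, the fit estimated on `covariates` is applied
#' to it (train-estimated residualization of held-out subjects, required for
#' leakage-free hold-out evaluation).
#'
#' @param x subjects x features numeric matrix (or a `feature_matrix`).
#' @param covariates data.frame or matrix of per-subject covariates, complete
#'   (no NA), one row per row of `x`.
#' @param newdata optional list(x=, covariates=) to residualize with the
#'   training fit.
#' @return residualized matrix (or list(train=, test=) when `newdata` given).
#' @export
regress_covariates <- function(x, covariates, newdata = NULL) {
  if (inherits(x, "feature_matrix")) x <- x$x
  x <- as.matrix(x)
  Z <- as.matrix(covariates)
  storage.mode(Z) <- "double"
  if (anyNA(Z)) stop("covariates must be complete (no NA)")
  if (nrow(Z) != nrow(x)) stop("covariates and features disagree on subjects")
  keep <- apply(Z, 2L, function(v) stats::sd(v) > 0)
  Z <- Z[, keep, drop = FALSE]
  D <- cbind(`(intercept)` = 1, Z)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    dropped <- colnames(D)[qrD$pivot[(qrD$rank + 1L):ncol(D)]]
    stop(sprintf("rank-deficient covariate design; collinear column(s): %s",
                 paste(dropped, collapse = ", ")))
  }
  beta <- qr.coef(qrD, x)
  res <- x - D %*% beta
  if (is.null(newdata)) return(res)
  xt <- as.matrix(newdata$x)
  Zt <- as.matrix(newdata$covariates)[, keep, drop = FALSE]
  storage.mode(Zt) <- "double"
  Dt <- cbind(1, Zt)
  list(train = res, test = xt - Dt %*% beta)
}

#' Two-sample t-test screening of feature columns
#'
#' Computes a two-sample t statistic and two-sided p value per feature column
#' (patients +1 vs controls -1) and retains the columns with p below `alpha`
#' (uncorrected, the screening convention this pipeline replicates).
#' Pooled-variance (Student) t by default; Welch by flag. Degenerate columns
#' with zero variance in both groups get p = 1 and are never retained.
#'
#' @param x subjects x features matrix (typically covariate-residualized).
#' @param labels integer vector in {+1, -1}.
#' @param alpha significance threshold in (0,1); default 0.001.
#' @param welch use Welch's unequal-variance t instead of pooled.
#' @return a `screen_result`: list with `retained` (column indices),
#'   `statistic`, `p_value`, `alpha`, `welch`.
#' @export
ttest_screen <- function(x, labels, alpha = 0.001, welch = FALSE) {
  if (inherits(x, "feature_matrix")) x <- x$x
  x <- as.matrix(x)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)")
  g1 <- labels == 1L; g0 <- labels == -1L
  n1 <- sum(g1); n0 <- sum(g0)
  if (n1 < 2L || n0 < 2L) stop("both groups must have at least two subjects")
  x1 <- x[g1, , drop = FALSE]; x0 <- x[g0, , drop = FALSE]
  m1 <- colMeans(x1); m0 <- colMeans(x0)
  v1 <- colMeans(x1 * x1) - m1^2; v1 <- v1 * n1 / (n1 - 1)
  v0 <- colMeans(x0 * x0) - m0^2; v0 <- v0 * n0 / (n0 - 1)
  if (welch) {
    se2 <- v1 / n1 + v0 / n0
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n0)
    df <- rep.int(n1 + n0 - 2, ncol(x))
  }
  degen <- se2 <= 0 | !is.finite(se2)
  tstat <- (m1 - m0) / sqrt(se2)
  tstat[degen] <- 0
  p <- 2 * stats::pt(-abs(tstat), df)
  p[degen] <- 1
  structure(list(retained = which(p < alpha), statistic = tstat,
                 p_value = p, alpha = alpha, welch = welch),
            class = "screen_result")
}
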