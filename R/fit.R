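# Assemble the model matrix (intercept + covariates) and fail loudly on
# missing values or rank deficiency, naming the offending columns.
.design_matrix <- function(design) {
  if (is.data.frame(design)) design <- as.matrix(design)
  if (is.null(dim(design))) design <- matrix(design, ncol = 1,
                                             dimnames = list(NULL, "x"))
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  if (anyNA(design)) stop("design contains missing values", call. = FALSE)
  cbind("(Intercept)" = 1, design)
}

.check_rank <- function(X) {
  qd <- qr(X)
  if (qd$rank < ncol(X)) {
    bad <- colnames(X)[qd$pivot[(qd$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(qd)
}

.effect_table <- function(terms, est, se, n_used) {
  structure(
    data.frame(term = terms, estimate = est, se = se,
               ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
               n_used = n_used, row.names = NULL),
    class = c("effect_estimate", "data.frame"))
}

#' Ordinary (or weighted) least squares with Wald confidence intervals
#'
#' Closed-form normal-equations fit with model-based standard errors and
#' fixed-z 95% Wald intervals (`estimate +/- 1.96 * se`). Kept deliberately
#' lean: it is called twice per replicate across thousands of Monte-Carlo
#' replicates. Weights, when given, define a weighted least-squares fit.
#'
#' @param outcome numeric response vector (no missing values).
#' @param design covariate data.frame/matrix/vector; an intercept is always
#'   added. Must be full column rank.
#' @param weights optional positive case weights.
#' @param robust use heteroskedasticity-robust (HC0 sandwich) standard
#'   errors instead of model-based ones.
#' @return an `effect_estimate` data.frame with one row per covariate
#'   (intercept included) and columns `term`, `estimate`, `se`, `ci_low`,
#'   `ci_high`, `n_used`.
#' @examples
#' x <- 1:10
#' fit_linear(2 * x, x)  # exact fit: slope 2, se 0
#' @export
fit_linear <- function(outcome, design, weights = NULL, robust = FALSE) {
  X <- .design_matrix(design)
  if (anyNA(outcome)) stop("outcome contains missing values", call. = FALSE)
  n <- length(outcome); p <- ncol(X)
  if (nrow(X) != n) stop("outcome and design sizes differ", call. = FALSE)
  if (n <= p) stop("need more observations than parameters", call. = FALSE)
  .check_rank(X)
  if (!is.null(weights)) {
    if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
    sw <- sqrt(weights)
    Xw <- X * sw; yw <- outcome * sw
  } else {
    Xw <- X; yw <- outcome
  }
  XtX <- crossprod(Xw)
  beta <- drop(solve(XtX, crossprod(Xw, yw)))
  res <- yw - drop(Xw %*% beta)
  XtXi <- solve(XtX)
  se <- if (robust) {
    sqrt(pmax(diag(XtXi %*% crossprod(Xw * res) %*% XtXi), 0))
  } else {
    sqrt(pmax(diag(XtXi) * sum(res^2) / (n - p), 0))
  }
  .effect_table(colnames(X), beta, se, n)
}

#' Maximum-likelihood logistic regression with Wald confidence intervals
#'
#' A thin wrapper around [stats::glm.fit()] (binomial family) that returns
#' the same `effect_estimate` layout as [fit_linear()] and turns
#' non-convergence or separation into explicit errors.
#'
#' @param outcome binary 0/1 response.
#' @param design covariates as in [fit_linear()].
#' @return an `effect_estimate` on the log-odds scale.
#' @export
fit_logistic <- function(outcome, design) {
  X <- .design_matrix(design)
  if (anyNA(outcome)) stop("outcome contains missing values", call. = FALSE)
  if (!all(outcome %in% c(0, 1)))
    stop("outcome must be binary 0/1", call. = FALSE)
  .check_rank(X)
  fit <- suppressWarnings(
    stats::glm.fit(X, outcome, family = stats::binomial()))
  if (!fit$converged)
    stop("logistic fit did not converge", call. = FALSE)
  eps <- 1e-8
  if (any(abs(fit$coefficients) > 15) &&
      all(fit$fitted.values < eps | fit$fitted.values > 1 - eps))
    stop("logistic fit is separated: fitted probabilities are all 0 or 1",
         call. = FALSE)
  se <- sqrt(diag(chol2inv(fit$qr$qr[seq_len(fit$qr$rank),
                                     seq_len(fit$qr$rank), drop = FALSE])))
  .effect_table(colnames(X), unname(fit$coefficients), se, length(outcome))
}

#' @export
print.effect_estimate <- function(x, digits = 4, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
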