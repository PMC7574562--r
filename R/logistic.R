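#' Ridge-penalized logistic regression via IRLS
#'
#' Fits a logistic regression with a quadratic (Gaussian) penalty on the
#' slope coefficients, expressed on standardized predictors. The penalty
#' keeps the fit finite and well-defined under complete separation, which
#' is the expected regime for chromosome-ratio Z-scores of trisomic
#' samples: an unpenalized fit would diverge exactly where the assay works
#' best. A small `lambda` (default `1e-4`) leaves the ranking of predicted
#' probabilities indistinguishable from the unpenalized fit; a `lambda` of
#' `1 / (2 * scale^2)` corresponds to a normal prior with standard
#' deviation `scale` on each standardized slope, which is how the
#' weakly-informative per-window classifier ([per_dmr_cv_auc()]) uses it.
#'
#' @param x numeric matrix of predictors (rows = observations), or a vector.
#' @param y binary response: logical, 0/1 numeric, or a two-level factor
#'   whose second level is treated as the positive class.
#' @param lambda ridge penalty applied to each standardized slope. The
#'   intercept is never penalized.
#' @param maxit,tol IRLS iteration cap and relative convergence tolerance
#'   on the penalized log-likelihood.
#' @return object of class `penalized_logit`: list with `coefficients`
#'   (intercept first, original predictor scale), `converged`,
#'   `loglik` (unpenalized, at the penalized optimum), `iterations`.
#' @seealso [predict.penalized_logit()]
#' @export
penalized_logistic <- function(x, y, lambda = 1e-4, maxit = 100L, tol = 1e-8) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("`y` must be binary", call. = FALSE)
  if (nrow(x) != length(y)) stop("nrow(x) != length(y)", call. = FALSE)
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)

  # standardize so the penalty is scale-free; constant columns get slope 0
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- Inf
  xs <- sweep(sweep(x, 2L, ctr, "-"), 2L, scl, "/")
  X <- cbind(1, xs)
  p <- ncol(X)
  D <- diag(c(0, rep(1, p - 1L)), p)

  beta <- numeric(p)
  beta[1] <- stats::qlogis(min(max(mean(y), 0.01), 0.99))
  obj_old <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(X, w * X) + 2 * lambda * D
    b <- crossprod(X, w * z)
    beta_new <- tryCatch(drop(solve(A, b)), error = function(e) beta)
    eta_new <- drop(X %*% beta_new)
    ll <- sum(y * eta_new - log1p(exp(eta_new)))
    obj <- ll - lambda * sum(beta_new[-1]^2)
    if (is.finite(obj) && obj >= obj_old) {
      beta <- beta_new
    } else {
      # step-halve toward the previous iterate
      for (h in 1:20) {
        beta_try <- (beta + beta_new) / 2
        eta_try <- drop(X %*% beta_try)
        obj_try <- sum(y * eta_try - log1p(exp(eta_try))) -
          lambda * sum(beta_try[-1]^2)
        if (is.finite(obj_try) && obj_try >= obj_old) {
          beta <- beta_try
          obj <- obj_try
          break
        }
        beta_new <- beta_try
      }
    }
    if (is.finite(obj) && abs(obj - obj_old) < tol * (abs(obj_old) + 1)) {
      converged <- TRUE
      obj_old <- obj
      break
    }
    obj_old <- obj
  }

  # back-transform to the original predictor scale
  slopes <- beta[-1] / scl
  slopes[!is.finite(slopes)] <- 0
  intercept <- beta[1] - sum(ctr * slopes)
  eta <- intercept + drop(x %*% slopes)
  structure(
    list(
      coefficients = c(`(Intercept)` = intercept, slopes),
      std_coefficients = beta,
      center = ctr, scale = scl,
      lambda = lambda,
      loglik = sum(y * eta - log1p(exp(eta))),
      converged = converged,
      iterations = it
    ),
    class = "penalized_logit"
  )
}

#' Predicted probabilities from a penalized logistic fit
#'
#' @param object a `penalized_logit` fit.
#' @param newdata matrix (or vector) of predictors on the original scale.
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.penalized_logit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  cf <- object$coefficients
  if (ncol(newdata) != length(cf) - 1L) {
    stop("newdata has wrong number of columns", call. = FALSE)
  }
  stats::plogis(cf[1] + drop(newdata %*% cf[-1]))
}

#' Area under the ROC curve by the rank (Mann-Whitney) formula
#'
#' Midranks are used so that tied scores contribute 1/2, making
#' `auc(rep(0, n), y)` exactly 0.5. Invariant to any strictly monotone
#' transform of `scores`.
#'
#' @param scores numeric classifier scores (higher = more positive-like).
#' @param labels binary labels; the positive class is `TRUE`, `1`, or the
#'   second factor level.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("NA in scores or labels", call. = FALSE)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
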