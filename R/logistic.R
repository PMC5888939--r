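#' Maximum-likelihood logistic regression on a prebuilt design matrix
#'
#' Newton–Raphson (IRLS) fit of a Bernoulli logit model. The matrix
#' interface (no formula parsing) keeps the Monte Carlo harness fast: a
#' single replication fits dozens of candidate models on shared design
#' columns. Supports prior weights (inverse-probability weighting), an
#' offset (the TMLE fluctuation submodel), and aliased-column handling via
#' pivoted QR, matching `stats::glm`'s NA-coefficient convention.
#'
#' Perfect separation is not penalised away: the fit stops at `max_iter`
#' with `converged = FALSE` and a warning, as a plain GLM would.
#'
#' @param x Numeric design matrix, intercept column included if wanted.
#' @param y Binary response vector (0/1).
#' @param weights Optional non-negative prior weights.
#' @param offset Optional offset added to the linear predictor.
#' @param max_iter Maximum Newton iterations (default 100).
#' @param tol Convergence tolerance on the largest absolute coefficient
#'   change (default 1e-8).
#' @param start Optional starting coefficients (warm start; aliased
#'   columns are handled after the restart).
#' @return An object of class `drate_logit` with elements `coefficients`
#'   (named, `NA` for aliased columns), `fitted`, `linear_predictor`,
#'   `log_likelihood`, `k` (estimable parameter count), `n`, `aic`, `bic`,
#'   `converged`, `iterations`.
#' @examples
#' x <- cbind(1, rnorm(200))
#' y <- rbinom(200, 1, plogis(x %*% c(-0.5, 1)))
#' fit <- fit_logistic(x, y)
#' coef(fit)
#' @export
fit_logistic <- function(x, y, weights = NULL, offset = NULL,
                         max_iter = 100L, tol = 1e-8, start = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  y <- check_binary(y, "y")
  if (length(y) != n) abort("`x` and `y` have different lengths.")
  if (n == 0L) abort("Empty data.")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || anyNA(w)) {
    abort("`weights` must be non-negative and of length nrow(x).")
  }
  off <- if (is.null(offset)) rep(0, n) else as.numeric(offset)
  ybar <- sum(w * y) / sum(w)
  if (ybar <= 0 || ybar >= 1) {
    abort("Response is constant (all 0 or all 1); logistic fit is undefined.")
  }

  init <- function(cols) {
    b <- numeric(length(cols))
    # intercept-ish start when the first kept column is constant
    if (all(x[, cols[1]] == x[1, cols[1]]) && x[1, cols[1]] != 0) {
      b[1] <- logit(ybar) / x[1, cols[1]]
    }
    b
  }

  keep <- seq_len(ncol(x))
  b0 <- if (is.null(start)) init(keep) else as.numeric(start)
  res <- .irls_fit(x, y, w, off, b0, as.integer(max_iter), tol)
  if (res$singular) {
    # aliased columns (or a degenerate information matrix): drop to a
    # full-rank column basis via pivoted QR and refit
    qx <- qr(x * sqrt(pmax(w, 1e-12)))
    keep <- sort(qx$pivot[seq_len(qx$rank)])
    xk <- x[, keep, drop = FALSE]
    res <- .irls_fit(xk, y, w, off, init(keep), as.integer(max_iter), tol)
  }
  converged <- res$converged && !res$singular

  if (!converged) {
    warn("Logistic fit did not converge (possible separation); estimate returned with converged = FALSE.")
  }

  coefs <- rep(NA_real_, ncol(x))
  coefs[keep] <- drop(res$beta)
  names(coefs) <- colnames(x) %||% paste0("x", seq_len(ncol(x)))
  k <- length(keep)
  ll <- res$loglik
  structure(
    list(coefficients = coefs, keep = keep, fitted = drop(res$fitted),
         linear_predictor = drop(res$eta), log_likelihood = ll, k = k,
         n = n, aic = -2 * ll + 2 * k, bic = -2 * ll + k * log(n),
         converged = converged, iterations = res$iterations),
    class = "drate_logit"
  )
}

#' @export
coef.drate_logit <- function(object, ...) object$coefficients

#' Predict probabilities from a `drate_logit` fit
#'
#' @param object A fit from [fit_logistic()].
#' @param newx New design matrix with the same columns as the training one.
#' @param offset Optional offset for the new data.
#' @param ... Unused.
#' @return Probability vector.
#' @export
predict.drate_logit <- function(object, newx, offset = NULL, ...) {
  newx <- as.matrix(newx)
  if (ncol(newx) != length(object$coefficients)) {
    abort("`newx` has a different number of columns than the training design.")
  }
  off <- if (is.null(offset)) 0 else as.numeric(offset)
  expit(drop(newx[, object$keep, drop = FALSE] %*%
               object$coefficients[object$keep]) + off)
}

#' @export
print.drate_logit <- function(x, ...) {
  cat(sprintf("<drate_logit> n = %d, k = %d, logLik = %.3f, AIC = %.2f, BIC = %.2f%s\n",
              x$n, x$k, x$log_likelihood, x$aic, x$bic,
              if (x$converged) "" else " (NOT converged)"))
  print(x$coefficients)
  invisible(x)
}

#' Fit a nuisance logistic regression from a cohort and a model spec
#'
#' Convenience wrapper: builds the design matrix via [build_design_matrix()]
#' and dispatches to [fit_logistic()] with the response named by the spec
#' (`a` for treatment models, `y` for outcome models).
#'
#' @inheritParams build_design_matrix
#' @param weights,max_iter,tol Passed to [fit_logistic()].
#' @return A `drate_logit` with the `spec` attached.
#' @export
fit_spec <- function(data, spec, weights = NULL, max_iter = 100L, tol = 1e-8) {
  if (is.character(spec)) spec <- model_spec(spec, response = "treatment")
  x <- build_design_matrix(data, spec)
  yname <- if (spec$response == "outcome") "y" else "a"
  if (!yname %in% names(data)) {
    abort(sprintf("Column `%s` missing from the cohort.", yname))
  }
  fit <- fit_logistic(x, data[[yname]], weights = weights,
                      max_iter = max_iter, tol = tol)
  fit$spec <- spec
  fit
}

#' @method tidy drate_logit
#' @export
tidy.drate_logit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @method glance drate_logit
#' @export
glance.drate_logit <- function(x, ...) {
  tibble::tibble(logLik = x$log_likelihood, AIC = x$aic, BIC = x$bic,
                 k = x$k, nobs = x$n, converged = x$converged)
}
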