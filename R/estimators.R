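#' Influence-curve standard error
#'
#' `sqrt(var(ic) / n)` with the usual n-1 sample variance.
#'
#' @param ic Influence-curve values, length >= 2.
#' @return Standard error (scalar, >= 0).
#' @export
influence_se <- function(ic) {
  if (length(ic) < 2L) abort("Need at least 2 observations.")
  sqrt(var(ic) / length(ic))
}

new_ate_estimate <- function(method, psi, se, n, diagnostics = list()) {
  structure(
    list(method = method, psi = psi, se = se,
         ci95 = c(lower = psi - 1.96 * se, upper = psi + 1.96 * se),
         n = n, diagnostics = diagnostics),
    class = "ate_estimate"
  )
}

#' @export
print.ate_estimate <- function(x, ...) {
  cat(sprintf("<ate_estimate> %s: ATE = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], n = %d\n",
              x$method, x$psi, x$se, x$ci95[1], x$ci95[2], x$n))
  invisible(x)
}

#' @method tidy ate_estimate
#' @export
tidy.ate_estimate <- function(x, ...) {
  tibble::tibble(method = x$method, estimate = x$psi, std.error = x$se,
                 conf.low = unname(x$ci95[1]), conf.high = unname(x$ci95[2]))
}

#' @method glance ate_estimate
#' @export
glance.ate_estimate <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(method = x$method, nobs = x$n,
                 converged = d$converged %||% TRUE,
                 near_positivity = d$near_positivity %||% NA)
}

check_both_arms <- function(a) {
  if (!any(a == 1) || !any(a == 0)) {
    abort("Both treatment arms must be non-empty.", class = "drate_arm_error")
  }
}

check_ps_tol <- function(g, ps_tol) {
  bad <- sum(g <= ps_tol | g >= 1 - ps_tol)
  if (bad > 0) {
    abort(sprintf(
      "Positivity violation: %d fitted propensity score(s) outside (%g, %g).",
      bad, ps_tol, 1 - ps_tol), class = "drate_positivity_error")
  }
}

#' Naive regression-adjusted ATE
#'
#' Classical multivariate regression adjustment: a linear-probability (OLS)
#' regression of `y` on `a` and the covariate terms, with the coefficient on
#' `a` as the effect estimate and a heteroskedasticity-robust (HC1) standard
#' error. The coefficient is a conditional-variance-weighted average of
#' conditional risk differences, so it is biased for the ATE under effect
#' heterogeneity and poor overlap — which is exactly the behaviour the
#' Monte Carlo benchmark quantifies.
#'
#' @param data Cohort with columns `a`, `y` and the spec's covariates.
#' @param outcome_spec A [model_spec()] naming the covariate terms, or
#'   `NULL` for the unadjusted difference in means.
#' @return An `ate_estimate`.
#' @examples
#' cohort <- generate_cohort(dgp_scenario1(), 2000, seed = 1)
#' ate_naive(cohort, model_spec(c("w1", "w2", "w3", "w4")))
#' @export
ate_naive <- function(data, outcome_spec = spec_preset(1, "outcome",
                                                       "misspecified")) {
  a <- check_binary(data$a, "a")
  y <- check_binary(data$y, "y")
  check_both_arms(a)
  x <- if (is.null(outcome_spec)) {
    cbind("(Intercept)" = 1, a = a)
  } else {
    sp <- model_spec(outcome_spec$terms %||% outcome_spec,
                     response = "outcome", include_treatment_main = TRUE)
    build_design_matrix(data, sp)
  }
  fit <- lm(y ~ x - 1)
  vc <- sandwich::vcovHC(fit, type = "HC1")
  ai <- which(colnames(x) == "a")
  psi <- unname(coef(fit)[ai])
  se <- sqrt(vc[ai, ai])
  new_ate_estimate("naive", psi, se, length(y))
}

#' Inverse-probability-of-treatment-weighted regression adjustment
#'
#' Two steps: (1) a logistic propensity model `g(W)`; (2) outcome
#' regressions fitted separately in each arm, weighted by the unnormalised
#' inverse probability of the observed treatment (`1/g` among treated,
#' `1/(1-g)` among controls; stabilised weights behind the flag). The
#' estimate standardises the arm-specific predictions over the whole
#' sample: `psi = mean(m1(W) - m0(W))`. Standard errors come from the
#' sandwich variance of the stacked estimating equations (propensity
#' scores, two weighted outcome scores, two means), so they account for
#' nuisance estimation; `se_method = "fixed"` treats the nuisances as known
#' and uses the efficient-influence-curve approximation instead.
#'
#' Fitted propensities at or beyond `ps_tol` raise a positivity error
#' naming the offending count; no silent truncation.
#'
#' @param data Cohort data frame.
#' @param treatment_spec,outcome_spec [model_spec()]s for the two nuisance
#'   models.
#' @param ps_tol Weight tolerance on the fitted propensity (default 1e-5).
#' @param stabilized Multiply weights by the marginal arm probabilities.
#' @param se_method `"stacked"` (default) or `"fixed"`.
#' @param g Optional known propensity vector (e.g. a randomised design);
#'   skips the propensity fit, and SEs fall back to the influence-curve
#'   form.
#' @return An `ate_estimate`.
#' @export
ate_iptw_ra <- function(data,
                        treatment_spec = spec_preset(1, "treatment"),
                        outcome_spec = spec_preset(1, "outcome"),
                        ps_tol = 1e-5, stabilized = FALSE,
                        se_method = c("stacked", "fixed"), g = NULL) {
  se_method <- match.arg(se_method)
  a <- check_binary(data$a, "a")
  y <- check_binary(data$y, "y")
  check_both_arms(a)
  n <- length(y)

  if (is.null(g)) {
    gfit <- fit_spec(data, treatment_spec)
    g <- gfit$fitted
  } else {
    if (length(g) == 1L) g <- rep(g, n)
    check_prob(g, "g", open = TRUE)
    gfit <- NULL
    se_method <- "fixed"
  }
  check_ps_tol(g, ps_tol)
  w <- ifelse(a == 1, 1 / g, 1 / (1 - g))
  if (stabilized) w <- w * ifelse(a == 1, mean(a), 1 - mean(a))

  # per-arm regressions: treatment main effect is absorbed by the intercept
  arm_spec <- model_spec(outcome_spec$terms, response = "outcome",
                         include_treatment_main = FALSE)
  xq <- build_design_matrix(data, arm_spec)
  f1 <- fit_logistic(xq[a == 1, , drop = FALSE], y[a == 1],
                     weights = w[a == 1])
  f0 <- fit_logistic(xq[a == 0, , drop = FALSE], y[a == 0],
                     weights = w[a == 0])
  m1 <- predict(f1, xq)
  m0 <- predict(f0, xq)
  psi <- mean(m1 - m0)

  se <- if (se_method == "stacked") {
    iptw_ra_stacked_se(a, y, g, m1, m0,
                       xg = build_design_matrix(data, treatment_spec),
                       xq = xq, psi = psi)
  } else {
    ic <- m1 - m0 - psi + (a / g) * (y - m1) - ((1 - a) / (1 - g)) * (y - m0)
    influence_se(ic)
  }
  new_ate_estimate("iptw_ra", psi, se, n, diagnostics = list(
    converged = (is.null(gfit) || gfit$converged) && f1$converged &&
      f0$converged,
    g_summary = quantile(g, c(0, 0.01, 0.5, 0.99, 1)),
    se_method = se_method
  ))
}

# sandwich variance of the stacked IPTW-RA estimating equations
iptw_ra_stacked_se <- function(a, y, g, m1, m0, xg, xq, psi) {
  n <- length(y)
  pg <- ncol(xg); pq <- ncol(xq)
  w1 <- a / g; w0 <- (1 - a) / (1 - g)
  mu1 <- mean(m1); mu0 <- mean(m0)
  # per-subject scores, in theta = (alpha, beta1, beta0, mu1, mu0, psi) order
  s <- cbind(
    xg * (a - g),
    xq * (w1 * (y - m1)),
    xq * (w0 * (y - m0)),
    m1 - mu1,
    m0 - mu0,
    rep((mu1 - mu0) - psi, n)
  )
  p <- ncol(s)
  A <- matrix(0, p, p)
  ig <- seq_len(pg); i1 <- pg + seq_len(pq); i0 <- pg + pq + seq_len(pq)
  im1 <- pg + 2 * pq + 1; im0 <- im1 + 1; ip <- im0 + 1
  A[ig, ig] <- crossprod(xg * (g * (1 - g)), xg) / n
  A[i1, i1] <- crossprod(xq * (w1 * m1 * (1 - m1)), xq) / n
  A[i0, i0] <- crossprod(xq * (w0 * m0 * (1 - m0)), xq) / n
  A[i1, ig] <- crossprod(xq * (a * ((1 - g) / g) * (y - m1)), xg) / n
  A[i0, ig] <- -crossprod(xq * ((1 - a) * (g / (1 - g)) * (y - m0)), xg) / n
  A[im1, i1] <- -colMeans(xq * (m1 * (1 - m1)))
  A[im0, i0] <- -colMeans(xq * (m0 * (1 - m0)))
  A[im1, im1] <- 1; A[im0, im0] <- 1
  A[ip, im1] <- -1; A[ip, im0] <- 1; A[ip, ip] <- 1
  B <- crossprod(s) / n
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ainv)) {
    ic <- m1 - m0 - psi + w1 * (y - m1) - w0 * (y - m0)
    return(influence_se(ic))
  }
  V <- Ainv %*% B %*% t(Ainv) / n
  sqrt(V[ip, ip])
}

#' Augmented inverse-probability-of-treatment weighting
#'
#' The one-step estimating-equation estimator:
#' `psi = mean(q1 - q0 + a (y - q1) / g - (1 - a)(y - q0) / (1 - g))`,
#' with the standard error equal to the sample standard deviation of the
#' summand divided by `sqrt(n)`. Being a non-substitution estimator it can
#' leave the `[-1, 1]` range of a risk difference under near-positivity
#' violations; it does so by design here, and the diagnostics record when
#' it happens.
#'
#' @inheritParams ate_iptw_ra
#' @param ps_tol Fitted propensities at or beyond this tolerance raise a
#'   positivity error (default 1e-5; relax to 1e-8 to push through severe
#'   near-violations, mirroring the weight-tolerance escape hatch of the
#'   reference implementation).
#' @param g,q1,q0 Optional known nuisance values (scalars are recycled);
#'   when all three are given no nuisance model is fitted.
#' @return An `ate_estimate`.
#' @export
ate_aiptw <- function(data,
                      treatment_spec = spec_preset(1, "treatment"),
                      outcome_spec = spec_preset(1, "outcome"),
                      ps_tol = 1e-5, g = NULL, q1 = NULL, q0 = NULL) {
  a <- check_binary(data$a, "a")
  y <- check_binary(data$y, "y")
  check_both_arms(a)
  n <- length(y)
  if (is.null(g) || is.null(q1) || is.null(q0)) {
    nuis <- fit_nuisance_parametric(data, treatment_spec, outcome_spec)
    converged <- nuis$gfit$converged && nuis$qfit$converged
    g <- nuis$g; q1 <- nuis$q1; q0 <- nuis$q0
  } else {
    if (length(g) == 1L) g <- rep(g, n)
    if (length(q1) == 1L) q1 <- rep(q1, n)
    if (length(q0) == 1L) q0 <- rep(q0, n)
    check_prob(g, "g", open = TRUE)
    converged <- TRUE
  }
  check_ps_tol(g, ps_tol)
  summand <- q1 - q0 +
    a * (y - q1) / g - (1 - a) * (y - q0) / (1 - g)
  psi <- mean(summand)
  se <- sd(summand) / sqrt(n)
  new_ate_estimate("aiptw", psi, se, n, diagnostics = list(
    converged = converged,
    g_summary = quantile(g, c(0, 0.01, 0.5, 0.99, 1)),
    out_of_range = abs(psi) > 1
  ))
}

# logistic fluctuation of the initial outcome fit along the clever
# covariate(s); returns epsilon and the updated counterfactual predictions
tmle_fluctuate <- function(a, y, g, q1, q0, single_epsilon = FALSE,
                           max_iter = 50L, tol = 1e-10) {
  q1 <- trunc_prob(q1); q0 <- trunc_prob(q0); g <- trunc_prob(g)
  q_obs <- ifelse(a == 1, q1, q0)
  h1 <- a / g
  h0 <- -(1 - a) / (1 - g)
  xf <- if (single_epsilon) cbind(h = h1 + h0) else cbind(h1 = h1, h0 = h0)
  fit <- fit_logistic(xf, y, offset = logit(q_obs),
                      max_iter = max_iter, tol = tol)
  if (!fit$converged) {
    abort("TMLE fluctuation did not converge.", class = "drate_tmle_error")
  }
  eps <- coef(fit)
  if (single_epsilon) {
    q1s <- expit(logit(q1) + eps[["h"]] / g)
    q0s <- expit(logit(q0) - eps[["h"]] / (1 - g))
  } else {
    q1s <- expit(logit(q1) + eps[["h1"]] / g)
    q0s <- expit(logit(q0) - eps[["h0"]] / (1 - g))
  }
  list(epsilon = eps, h1 = h1, h0 = h0, q1_star = q1s, q0_star = q0s)
}

#' Targeted maximum likelihood estimation of the ATE
#'
#' The substitution estimator: (1) initial outcome predictions `Q(a, W)`
#' from a cross-validated super learner on `(a, W)` (or a parametric spec);
#' (2) propensity `g(W)` from a super learner on `W` (or a spec), bounded
#' to `g_bounds`; (3) clever covariates `h1 = a/g`, `h0 = -(1-a)/(1-g)`;
#' (4) an intercept-free logistic fluctuation of `y` on `(h1, h0)` with
#' offset `logit(Q(A, W))`; (5) updated counterfactual predictions
#' `q1* = expit(logit(q1) + eps1/g)`, `q0* = expit(logit(q0) - eps0/(1-g))`;
#' (6) `psi = mean(q1* - q0*)`; (7) the influence curve
#' `IC = (a/g)(y - q1*) - ((1-a)/(1-g))(y - q0*) + q1* - q0* - psi`
#' gives the standard error. As a substitution estimator the estimate
#' always lies in `[-1, 1]`.
#'
#' @param data Cohort data frame.
#' @param nuisance `"superlearner"` (default), `"parametric"`, or
#'   `"fixed"` (supply `g`, `q1`, `q0` directly).
#' @param sl_library A [learner_library()] for the super learner.
#' @param sl_v Number of CV folds (default 10).
#' @param seed Seed for the CV fold shuffle.
#' @param treatment_spec,outcome_spec Specs used when
#'   `nuisance = "parametric"`.
#' @param g_bounds Propensity bounds (default `c(0.025, 0.975)`).
#' @param single_epsilon Use a one-parameter fluctuation instead of the
#'   two-parameter `(h1, h0)` targeting.
#' @param g,q1,q0 Known nuisance values for `nuisance = "fixed"` (scalars
#'   are recycled).
#' @return An `ate_estimate`; the fluctuation details (epsilon, clever
#'   covariates, updated predictions) are in `$diagnostics$fluctuation`.
#' @examples
#' cohort <- generate_cohort(dgp_scenario1(), 500, seed = 3)
#' ate_tmle(cohort, nuisance = "parametric", seed = 3)
#' @export
ate_tmle <- function(data,
                     nuisance = c("superlearner", "parametric", "fixed"),
                     sl_library = NULL, sl_v = 10L, seed = 1L,
                     treatment_spec = spec_preset(1, "treatment"),
                     outcome_spec = spec_preset(1, "outcome"),
                     g_bounds = c(0.025, 0.975),
                     single_epsilon = FALSE,
                     g = NULL, q1 = NULL, q0 = NULL) {
  nuisance <- match.arg(nuisance)
  a <- check_binary(data$a, "a")
  y <- check_binary(data$y, "y")
  check_both_arms(a)
  n <- length(y)
  wcols <- setdiff(names(data), c("a", "y"))

  if (nuisance == "superlearner") {
    seeds <- derive_seeds(seed, 2L)
    xq <- data[c("a", wcols)]
    slq <- superlearner_fit(xq, y, library = sl_library, v = sl_v,
                            seed = seeds[1])
    d1 <- xq; d1$a <- 1
    d0 <- xq; d0$a <- 0
    q1 <- superlearner_predict(slq, d1)
    q0 <- superlearner_predict(slq, d0)
    slg <- superlearner_fit(data[wcols], a, library = sl_library, v = sl_v,
                            seed = seeds[2])
    g_raw <- superlearner_predict(slg, data[wcols])
    sl_info <- list(q_weights = slq$weights, g_weights = slg$weights)
  } else if (nuisance == "parametric") {
    nuis <- fit_nuisance_parametric(data, treatment_spec, outcome_spec)
    q1 <- nuis$q1; q0 <- nuis$q0; g_raw <- nuis$g
    sl_info <- NULL
  } else {
    if (is.null(g) || is.null(q1) || is.null(q0)) {
      abort("nuisance = \"fixed\" requires `g`, `q1` and `q0`.")
    }
    if (length(g) == 1L) g <- rep(g, n)
    if (length(q1) == 1L) q1 <- rep(q1, n)
    if (length(q0) == 1L) q0 <- rep(q0, n)
    g_raw <- check_prob(g, "g")
    sl_info <- NULL
  }
  g <- bound_propensity(g_raw, g_bounds[1], g_bounds[2])

  fl <- tmle_fluctuate(a, y, g, q1, q0, single_epsilon = single_epsilon)
  psi <- mean(fl$q1_star - fl$q0_star)
  ic <- (a / g) * (y - fl$q1_star) - ((1 - a) / (1 - g)) * (y - fl$q0_star) +
    fl$q1_star - fl$q0_star - psi
  se <- influence_se(ic)
  new_ate_estimate("tmle", psi, se, n, diagnostics = list(
    converged = TRUE,
    fluctuation = fl,
    mean_ic = mean(ic),
    g_summary = quantile(g_raw, c(0, 0.01, 0.5, 0.99, 1)),
    g_bounds = g_bounds,
    superlearner = sl_info
  ))
}

#' Estimate the ATE by a named method
#'
#' Thin dispatcher over [ate_naive()], [ate_iptw_ra()], [ate_aiptw()] and
#' [ate_tmle()], convenient in pipelines and for the command line.
#'
#' @param data Cohort data frame.
#' @param method One of `"naive"`, `"iptw_ra"`, `"aiptw"`, `"tmle"`.
#' @param ... Passed to the method's function.
#' @return An `ate_estimate`.
#' @export
estimate_ate <- function(data, method = c("tmle", "naive", "iptw_ra",
                                          "aiptw"), ...) {
  method <- match.arg(method)
  switch(method,
    naive = ate_naive(data, ...),
    iptw_ra = ate_iptw_ra(data, ...),
    aiptw = ate_aiptw(data, ...),
    tmle = ate_tmle(data, ...)
  )
}
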