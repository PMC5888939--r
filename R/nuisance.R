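#' Clamp propensity scores to a bounded interval
#'
#' Elementwise, order-preserving clamp. TMLE bounds its fitted propensities
#' to `[0.025, 0.975]` by default; the weighting estimators instead refuse
#' scores below a small tolerance (see [ate_aiptw()]).
#'
#' @param g Propensity vector.
#' @param lower,upper Bounds with `0 <= lower < upper <= 1`.
#' @return Bounded vector.
#' @examples
#' bound_propensity(c(0.001, 0.5, 0.99))
#' @export
bound_propensity <- function(g, lower = 0.025, upper = 0.975) {
  if (!(length(lower) == 1 && length(upper) == 1 &&
        lower >= 0 && upper <= 1 && lower < upper)) {
    abort("Need 0 <= lower < upper <= 1.")
  }
  check_prob(g, "g")
  pmin(pmax(g, lower), upper)
}

#' Summarise propensity-score overlap between treatment arms
#'
#' Computes min, the 1/5/25/50/75/95/99 percentiles, and max of the
#' propensity score overall and within each arm, and flags near-positivity
#' when the overall 1st percentile falls below `threshold`. The summary is
#' the tabular counterpart of a visual overlap check of the two arm-wise
#' propensity distributions; `autoplot()` draws it.
#'
#' @param g Propensity vector.
#' @param a Binary treatment vector of the same length.
#' @param threshold Near-positivity flag threshold on the 1st percentile
#'   (default 0.01).
#' @return An object of class `overlap_summary`: a tibble with one row per
#'   group (`overall`, `treated`, `control`) and attributes
#'   `near_positivity` (logical), `threshold`, and `data` (g, a) for
#'   plotting. Empty arms yield an all-`NA` row and a flag, not an error.
#' @export
overlap_summary <- function(g, a, threshold = 0.01) {
  check_prob(g, "g")
  check_binary(a, "a")
  if (length(g) != length(a)) abort("`g` and `a` lengths differ.")
  probs <- c(0.01, 0.05, 0.25, 0.50, 0.75, 0.95, 0.99)
  row <- function(gi, label) {
    if (length(gi) == 0L) {
      qs <- rep(NA_real_, length(probs))
      mn <- mx <- NA_real_
    } else {
      qs <- unname(quantile(gi, probs))
      mn <- min(gi); mx <- max(gi)
    }
    tibble::tibble(group = label, n = length(gi), min = mn,
                   p1 = qs[1], p5 = qs[2], p25 = qs[3], p50 = qs[4],
                   p75 = qs[5], p95 = qs[6], p99 = qs[7], max = mx)
  }
  out <- dplyr::bind_rows(
    row(g, "overall"),
    row(g[a == 1], "treated"),
    row(g[a == 0], "control")
  )
  empty_arm <- any(out$n[-1] == 0L)
  flag <- isTRUE(out$p1[1] < threshold)
  structure(out,
            class = c("overlap_summary", class(out)),
            near_positivity = flag, empty_arm = empty_arm,
            threshold = threshold,
            data = tibble::tibble(g = as.numeric(g), a = as.numeric(a)))
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("Propensity-score overlap summary\n")
  NextMethod()
  if (isTRUE(attr(x, "near_positivity"))) {
    cat(sprintf("Near-positivity flag: 1st percentile < %g\n",
                attr(x, "threshold")))
  }
  if (isTRUE(attr(x, "empty_arm"))) cat("Warning: an arm is empty.\n")
  invisible(x)
}

#' @describeIn overlap_summary Mirrored arm-wise propensity histogram, the
#'   usual visual overlap diagnostic.
#' @param object An `overlap_summary`.
#' @param ... Unused.
#' @method autoplot overlap_summary
#' @export
autoplot.overlap_summary <- function(object, ...) {
  d <- attr(object, "data")
  d$arm <- factor(ifelse(d$a == 1, "treated (A = 1)", "control (A = 0)"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$g, fill = .data$arm)) +
    ggplot2::geom_histogram(
      data = function(z) z[z$a == 1, ],
      ggplot2::aes(y = ggplot2::after_stat(density)),
      bins = 50, alpha = 0.85, boundary = 0
    ) +
    ggplot2::geom_histogram(
      data = function(z) z[z$a == 0, ],
      ggplot2::aes(y = -ggplot2::after_stat(density)),
      bins = 50, alpha = 0.85, boundary = 0
    ) +
    ggplot2::labs(x = "propensity score P(A = 1 | W)",
                  y = "density (treated up / control down)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Fitted nuisance estimates for one cohort
#'
#' Bundles the fitted propensity `g(W)` and the outcome predictions at the
#' observed exposure and under both counterfactual exposures, as used by the
#' AIPTW and TMLE estimators.
#'
#' @param g Propensity vector P(A=1|W).
#' @param q1,q0 Outcome predictions under A=1 and A=0.
#' @param a Observed exposure (defines `q_obs`).
#' @param g_bounds Bounds applied to `g` (recorded, not re-applied).
#' @return Object of class `nuisance_estimates`.
#' @export
nuisance_estimates <- function(g, q1, q0, a, g_bounds = c(0, 1)) {
  check_prob(g, "g"); check_prob(q1, "q1"); check_prob(q0, "q0")
  check_binary(a, "a")
  n <- length(a)
  stopifnot(length(g) == n, length(q1) == n, length(q0) == n)
  structure(
    list(g = as.numeric(g), q1 = as.numeric(q1), q0 = as.numeric(q0),
         q_obs = ifelse(a == 1, q1, q0), a = as.numeric(a),
         g_bounds = g_bounds),
    class = "nuisance_estimates"
  )
}

# Fit both nuisances parametrically from model specs.
fit_nuisance_parametric <- function(data, treatment_spec, outcome_spec) {
  gfit <- fit_spec(data, treatment_spec)
  qfit <- fit_spec(data, outcome_spec)
  xq <- build_design_matrix(data, outcome_spec)
  d1 <- data; d1$a <- 1
  d0 <- data; d0$a <- 0
  list(
    g = gfit$fitted,
    q1 = predict(qfit, build_design_matrix(d1, outcome_spec)),
    q0 = predict(qfit, build_design_matrix(d0, outcome_spec)),
    gfit = gfit, qfit = qfit
  )
}
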