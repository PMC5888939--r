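#' Enumerate nested candidate model specifications
#'
#' Builds the best-fit candidate ladder: starting from a single main
#' effect, each subsequent candidate adds one term, in the fixed order
#' mains, then squares, then pairwise products (lexicographic), ending at
#' the fully interacted order-2 polynomial. With 4 covariates and
#' `order = 2` the final candidate has 14 non-intercept terms
#' (4 mains + 4 squares + 6 pairs).
#'
#' @param covariates Character vector of covariate column names.
#' @param order 1 (mains only) or 2.
#' @param response Passed to [model_spec()]; outcome candidates carry the
#'   treatment main term in every candidate.
#' @return List of [model_spec()]s with strictly increasing term counts.
#' @export
enumerate_candidates <- function(covariates, order = 2,
                                 response = c("treatment", "outcome")) {
  response <- match.arg(response)
  if (length(covariates) < 1L) abort("Need at least one covariate.")
  if (!order %in% c(1, 2)) {
    abort("Only polynomial orders 1 and 2 are implemented.")
  }
  terms <- covariates
  if (order == 2) {
    terms <- c(terms, paste0(covariates, "^2"))
    if (length(covariates) > 1) {
      pairs <- utils::combn(covariates, 2)
      terms <- c(terms, apply(pairs, 2, paste, collapse = ":"))
    }
  }
  lapply(seq_along(terms), function(k) {
    model_spec(terms[seq_len(k)], response = response)
  })
}

#' Rank candidate models by AIC or BIC ("best fit" selection)
#'
#' Fits every candidate by maximum-likelihood logistic regression and
#' returns the ranking table. The chosen candidate minimises the configured
#' criterion; ties break towards fewer parameters, then earlier enumeration
#' order. Candidates that fail to converge are kept in the table but
#' flagged and never chosen unless all fail to converge cleanly, in which
#' case selection errors.
#'
#' @param data Cohort data frame.
#' @param response `"a"` (treatment model) or `"y"` (outcome model).
#' @param candidates List of [model_spec()]s, e.g. from
#'   [enumerate_candidates()]; defaults to the order-2 ladder over
#'   `w1..w4`.
#' @param criterion `"aic"` (default) or `"bic"`.
#' @return Object of class `bfit_ranking`: a tibble with one row per
#'   candidate (`rank`, `terms`, `k`, `aic`, `bic`, `converged`, `chosen`),
#'   with the winning [model_spec()] in `attr(, "chosen_spec")`.
#' @examples
#' cohort <- generate_cohort(dgp_scenario2(), 1000, seed = 1)
#' bfit_select(cohort, response = "y")
#' @export
bfit_select <- function(data, response = c("a", "y"), candidates = NULL,
                        criterion = c("aic", "bic")) {
  response <- match.arg(response)
  criterion <- match.arg(criterion)
  if (is.null(candidates)) {
    candidates <- enumerate_candidates(
      intersect(c("w1", "w2", "w3", "w4"), names(data)), order = 2,
      response = if (response == "y") "outcome" else "treatment")
  }
  if (length(candidates) == 0L) abort("`candidates` is empty.")

  rows <- purrr::map_dfr(seq_along(candidates), function(i) {
    sp <- candidates[[i]]
    fit <- tryCatch(suppressWarnings(fit_spec(data, sp)),
                    error = function(e) NULL)
    if (is.null(fit)) {
      tibble::tibble(candidate = i, terms = paste(sp$terms, collapse = "+"),
                     k = NA_integer_, aic = Inf, bic = Inf,
                     converged = FALSE)
    } else {
      tibble::tibble(candidate = i, terms = paste(sp$terms, collapse = "+"),
                     k = fit$k, aic = fit$aic, bic = fit$bic,
                     converged = fit$converged)
    }
  })
  ok <- rows$converged
  if (!any(ok)) abort("No candidate model converged.", class = "drate_selection_error")
  crit <- if (criterion == "aic") rows$aic else rows$bic
  crit[!ok] <- Inf
  # minimise criterion; ties -> smaller k, then earlier enumeration
  chosen <- order(crit, rows$k, rows$candidate)[1]
  out <- rows[order(crit, rows$k, rows$candidate), ]
  out$rank <- seq_len(nrow(out))
  out$chosen <- out$candidate == chosen
  out <- out[, c("rank", "candidate", "terms", "k", "aic", "bic",
                 "converged", "chosen")]
  structure(out,
            class = c("bfit_ranking", class(out)),
            chosen_spec = candidates[[chosen]],
            criterion = criterion)
}

#' @export
print.bfit_ranking <- function(x, ...) {
  cat(sprintf("Best-fit candidate ranking (criterion: %s)\n",
              toupper(attr(x, "criterion"))))
  NextMethod()
  invisible(x)
}

#' @method tidy bfit_ranking
#' @export
tidy.bfit_ranking <- function(x, ...) tibble::as_tibble(x)

#' Extract the selected model spec from a `bfit_ranking`
#' @param ranking A [bfit_select()] result.
#' @return The chosen [model_spec()].
#' @export
chosen_spec <- function(ranking) {
  stopifnot(inherits(ranking, "bfit_ranking"))
  attr(ranking, "chosen_spec")
}
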