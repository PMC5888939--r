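#' V-fold cross-validation fold assignment
#'
#' Folds are assigned by cycling fold labels over a seeded shuffle, so fold
#' sizes differ by at most one. With `strata` (default: the response, when
#' called from [superlearner_fit()]), the shuffle is grouped by stratum and
#' the label cycle continues across strata, keeping both the global and the
#' per-stratum fold sizes balanced — this avoids folds without events at
#' n = 1,000 with rare outcomes.
#'
#' @param n Number of observations.
#' @param v Number of folds, `2 <= v <= n`.
#' @param seed Integer seed.
#' @param strata Optional vector to balance folds over.
#' @return Integer vector in `1..v` of length `n`.
#' @export
make_folds <- function(n, v, seed = 1L, strata = NULL) {
  n <- as.integer(n); v <- as.integer(v)
  if (v < 2L || v > n) abort("Need 2 <= v <= n.")
  with_seed(seed, {
    idx <- sample.int(n)
    ord <- if (is.null(strata)) {
      idx
    } else {
      stopifnot(length(strata) == n)
      idx[order(strata[idx])]  # stable: shuffled within stratum
    }
    folds <- integer(n)
    folds[ord] <- rep_len(seq_len(v), n)
    folds
  })
}

#' Learner library for the super learner
#'
#' The default library mirrors the basic ensemble used with TMLE here:
#' `sl_step` (bidirectional stepwise logistic selection by AIC over main
#' terms), `sl_glm` (logistic GLM, main terms), and `sl_glm_interaction`
#' (logistic GLM with squares of the continuous predictors and all pairwise
#' products). `sl_step_interaction` (stepwise with the pairwise-interaction
#' scope) is available but not in the default library.
#'
#' @param names Character vector of learner names.
#' @return Object of class `learner_library`: named list of learners, each
#'   with `fit(x, y)` and `predict(model, x)` working on a predictor data
#'   frame `x`.
#' @export
learner_library <- function(names = c("sl_step", "sl_glm",
                                      "sl_glm_interaction")) {
  if (length(names) == 0L) abort("Need at least one learner.")
  if (anyDuplicated(names)) abort("Learner names must be unique.")
  all <- list(
    sl_glm = learner_glm(),
    sl_step = learner_step(interactions = FALSE),
    sl_step_interaction = learner_step(interactions = TRUE),
    sl_glm_interaction = learner_glm_interaction()
  )
  unknown <- setdiff(names, names(all))
  if (length(unknown)) {
    abort(sprintf("Unknown learner(s): %s.", paste(unknown, collapse = ", ")))
  }
  structure(all[names], class = "learner_library")
}

is_binary_col <- function(x) all(x %in% c(0, 1))

# design helpers: x is a predictor-only data frame
design_mains <- function(x) {
  m <- cbind(1, as.matrix(x))
  colnames(m) <- c("(Intercept)", names(x))
  m
}

design_order2 <- function(x) {
  nm <- names(x)
  cols <- list()
  for (v in nm) if (!is_binary_col(x[[v]])) {
    cols[[paste0(v, "^2")]] <- x[[v]]^2
  }
  if (length(nm) > 1) {
    for (i in seq_len(length(nm) - 1)) {
      for (j in seq((i + 1), length(nm))) {
        cols[[paste0(nm[i], ":", nm[j])]] <- x[[nm[i]]] * x[[nm[j]]]
      }
    }
  }
  m <- cbind(design_mains(x), do.call(cbind, cols))
  colnames(m) <- c("(Intercept)", nm, names(cols))
  m
}

learner_glm <- function() {
  list(
    name = "sl_glm",
    fit = function(x, y) fit_logistic(design_mains(x), y),
    predict = function(model, x) predict(model, design_mains(x))
  )
}

learner_glm_interaction <- function() {
  list(
    name = "sl_glm_interaction",
    fit = function(x, y) {
      fit <- fit_logistic(design_order2(x), y)
      fit$design_fn <- "order2"
      fit
    },
    predict = function(model, x) predict(model, design_order2(x))
  )
}

# greedy bidirectional stepwise by AIC over a fixed candidate-column design;
# deterministic scan order (column order of the design), ties to the
# earlier candidate
step_logistic <- function(xfull, y, k_penalty = 2) {
  p <- ncol(xfull)  # column 1 is the intercept
  in_model <- rep(FALSE, p); in_model[1] <- TRUE
  fit <- fit_logistic(xfull[, in_model, drop = FALSE], y)
  crit <- -2 * fit$log_likelihood + k_penalty * fit$k
  repeat {
    best <- NULL; best_crit <- crit
    cur_beta <- numeric(p)
    cb <- fit$coefficients
    cb[is.na(cb)] <- 0
    cur_beta[in_model] <- cb
    for (j in seq(2, p)) {
      cand <- in_model
      cand[j] <- !cand[j]  # toggle: add if out, drop if in
      # warm start from the current model (0 for an entering column);
      # the scan runs at a looser tolerance, the winner is refit below
      start <- cur_beta[cand]
      f <- suppressWarnings(
        fit_logistic(xfull[, cand, drop = FALSE], y,
                     start = start, tol = 1e-6))
      cc <- -2 * f$log_likelihood + k_penalty * f$k
      if (cc < best_crit - 1e-8) {
        best <- list(sel = cand, fit = f); best_crit <- cc
      }
    }
    if (is.null(best)) break
    in_model <- best$sel; fit <- best$fit; crit <- best_crit
  }
  fit <- fit_logistic(xfull[, in_model, drop = FALSE], y)
  fit$selected <- in_model
  fit
}

learner_step <- function(interactions = FALSE) {
  name <- if (interactions) "sl_step_interaction" else "sl_step"
  mk_design <- function(x) if (interactions) design_order2(x) else design_mains(x)
  list(
    name = name,
    fit = function(x, y) {
      fit <- step_logistic(mk_design(x), y)
      fit
    },
    predict = function(model, x) {
      xm <- mk_design(x)
      predict(model, xm[, model$selected, drop = FALSE])
    }
  )
}

#' Cross-validated risk of each learner in a library
#'
#' Risk is the mean over folds of the held-out mean squared error. Each
#' learner is trained only on the out-of-fold data. A learner that fails on
#' any fold is assigned infinite risk (and is thereby excluded from the
#' ensemble), with a warning.
#'
#' @param x Predictor data frame.
#' @param y Binary response.
#' @param library A [learner_library()].
#' @param folds Fold assignment from [make_folds()].
#' @return List with `risks` (named numeric) and `level_one` (n x L matrix
#'   of held-out predictions).
#' @export
cv_risk <- function(x, y, library, folds) {
  stopifnot(inherits(library, "learner_library"))
  n <- nrow(x)
  if (length(folds) != n || length(y) != n) abort("Length mismatch.")
  L <- length(library)
  z <- matrix(NA_real_, n, L, dimnames = list(NULL, names(library)))
  fold_ids <- sort(unique(folds))
  risks <- numeric(L); names(risks) <- names(library)
  for (l in seq_len(L)) {
    lrn <- library[[l]]
    fold_mse <- numeric(length(fold_ids))
    failed <- FALSE
    for (fi in seq_along(fold_ids)) {
      test <- folds == fold_ids[fi]
      pred <- tryCatch({
        m <- suppressWarnings(lrn$fit(x[!test, , drop = FALSE], y[!test]))
        lrn$predict(m, x[test, , drop = FALSE])
      }, error = function(e) NULL)
      if (is.null(pred)) { failed <- TRUE; break }
      z[test, l] <- pred
      fold_mse[fi] <- mean((y[test] - pred)^2)
    }
    if (failed) {
      warn(sprintf("Learner `%s` failed on a fold; assigned infinite risk.",
                   names(library)[l]))
      risks[l] <- Inf
      z[, l] <- NA_real_
    } else {
      risks[l] <- mean(fold_mse)
    }
  }
  list(risks = risks, level_one = z)
}

#' Convex ensemble weights by non-negative least squares
#'
#' Minimises the squared-error risk of the convex combination of the
#' level-one (held-out) predictions: non-negative least squares, then
#' normalisation to sum one. If the NNLS solution is identically zero, the
#' weight falls back to 1 on the learner with the smallest marginal risk,
#' with a warning.
#'
#' @param z n x L matrix of level-one predictions (columns = learners).
#' @param y Binary response.
#' @return Non-negative weight vector summing to 1.
#' @export
ensemble_weights <- function(z, y) {
  z <- as.matrix(z)
  L <- ncol(z)
  if (L == 1L) return(stats::setNames(1, colnames(z)))
  ok <- !apply(z, 2, anyNA) & apply(z, 2, function(c) all(is.finite(c)))
  w <- numeric(L)
  if (any(ok)) {
    sol <- tryCatch(pracma::lsqnonneg(z[, ok, drop = FALSE], y)$x,
                    error = function(e) NULL)
    if (!is.null(sol)) w[ok] <- sol
  }
  if (sum(w) <= 0) {
    warn("NNLS returned an all-zero solution; falling back to the single best learner.")
    risks <- apply(z, 2, function(c) if (anyNA(c)) Inf else mean((y - c)^2))
    w[which.min(risks)] <- 1
  }
  w <- w / sum(w)
  names(w) <- colnames(z)
  w
}

#' Fit a V-fold cross-validated super learner
#'
#' Computes level-one held-out predictions for every learner in the library,
#' chooses convex ensemble weights by NNLS on the level-one matrix, then
#' refits every learner on the full data. Predictions are the weighted
#' average of the full-data learner predictions, truncated to
#' `[1e-6, 1 - 1e-6]`.
#'
#' @param x Predictor data frame.
#' @param y Binary response.
#' @param library A [learner_library()] (default library if `NULL`).
#' @param v Number of folds (default 10).
#' @param seed Integer seed for the fold shuffle.
#' @param stratify Balance folds on the response (default `TRUE`).
#' @return Object of class `superlearner_fit` with `weights`, `cv_risks`,
#'   `folds`, and the refitted learners.
#' @examples
#' cohort <- generate_cohort(dgp_scenario1(), 300, seed = 1)
#' sl <- superlearner_fit(cohort[c("w1", "w2", "w3", "w4")], cohort$a,
#'                        v = 5, seed = 2)
#' sl$weights
#' @export
superlearner_fit <- function(x, y, library = NULL, v = 10L, seed = 1L,
                             stratify = TRUE) {
  library <- library %||% learner_library()
  y <- check_binary(y, "y")
  folds <- make_folds(nrow(x), v, seed = seed,
                      strata = if (stratify) y else NULL)
  cv <- cv_risk(x, y, library, folds)
  weights <- ensemble_weights(cv$level_one, y)
  full <- lapply(library, function(lrn) {
    tryCatch(suppressWarnings(lrn$fit(x, y)), error = function(e) NULL)
  })
  dead <- vapply(full, is.null, logical(1)) & weights > 0
  if (any(dead)) {
    weights[dead] <- 0
    if (sum(weights) <= 0) abort("All weighted learners failed on the full data.")
    weights <- weights / sum(weights)
  }
  structure(
    list(library = library, weights = weights, cv_risks = cv$risks,
         level_one = cv$level_one, folds = folds, fits = full,
         v = v, seed = seed),
    class = "superlearner_fit"
  )
}

#' @rdname superlearner_fit
#' @param object A `superlearner_fit`.
#' @param newx New predictor data frame.
#' @export
superlearner_predict <- function(object, newx) {
  stopifnot(inherits(object, "superlearner_fit"))
  pred <- rep(0, nrow(newx))
  for (l in seq_along(object$library)) {
    wl <- object$weights[l]
    if (wl > 0) {
      pred <- pred + wl * object$library[[l]]$predict(object$fits[[l]], newx)
    }
  }
  trunc_prob(pred, 1e-6)
}

#' @export
print.superlearner_fit <- function(x, ...) {
  cat(sprintf("<superlearner_fit> %d learners, %d-fold CV\n",
              length(x$library), x$v))
  print(tibble::tibble(learner = names(x$weights),
                       cv_risk = unname(x$cv_risks),
                       weight = unname(x$weights)))
  invisible(x)
}

#' @method tidy superlearner_fit
#' @export
tidy.superlearner_fit <- function(x, ...) {
  tibble::tibble(learner = names(x$weights),
                 cv_risk = unname(x$cv_risks),
                 weight = unname(x$weights))
}
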