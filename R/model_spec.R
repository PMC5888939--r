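#' Parametric model specifications for the nuisance regressions
#'
#' A `model_spec` names the linear-predictor terms of a logistic (or, for the
#' naive estimator, linear-probability) regression. Terms are plain strings
#' with deterministic parsing rules:
#'
#' * `"w1"` — a main effect (a column of the cohort);
#' * `"w2:w4"` — an elementwise product of two columns;
#' * `"w2^2"` — an elementwise square.
#'
#' Outcome-model specs carry the treatment indicator as a forced main term
#' (`include_treatment_main = TRUE`), mirroring regression adjustment where
#' the exposure always enters the linear predictor.
#'
#' @param terms Character vector of term strings (non-empty, no duplicates).
#' @param response `"outcome"` or `"treatment"` — which nuisance the spec is
#'   for.
#' @param include_treatment_main Add the exposure column `a` as a main term.
#'   Defaults to `TRUE` for outcome specs, `FALSE` for treatment specs.
#' @return An object of class `model_spec`.
#' @examples
#' model_spec(c("w1", "w2", "w3", "w4", "w2:w4"), response = "outcome")
#' @export
model_spec <- function(terms,
                       response = c("outcome", "treatment"),
                       include_treatment_main = NULL) {
  response <- match.arg(response)
  terms <- as.character(terms)
  if (length(terms) == 0L) abort("`terms` must be non-empty.")
  if (anyDuplicated(terms)) abort("`terms` contains duplicates.")
  if (is.null(include_treatment_main)) {
    include_treatment_main <- response == "outcome"
  }
  structure(
    list(terms = terms, response = response,
         include_treatment_main = isTRUE(include_treatment_main)),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  lhs <- if (x$response == "outcome") "y" else "a"
  rhs <- c(if (x$include_treatment_main) "a", x$terms)
  cat("<model_spec> ", lhs, " ~ ", paste(rhs, collapse = " + "), "\n", sep = "")
  invisible(x)
}

# parse one term string into its factors: a main effect, a square, or a
# product of two factors each of which may itself be a square
parse_term <- function(term) {
  split_pow <- function(s) {
    if (grepl("^", s, fixed = TRUE)) {
      parts <- strsplit(s, "^", fixed = TRUE)[[1]]
      if (length(parts) != 2L || parts[2] != "2") {
        abort(sprintf("Only squares are supported; cannot parse `%s`.", s))
      }
      list(var = parts[1], pow = 2L)
    } else {
      list(var = s, pow = 1L)
    }
  }
  if (grepl(":", term, fixed = TRUE)) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) abort(sprintf("Cannot parse term `%s`.", term))
    f <- lapply(parts, split_pow)
    list(kind = "product", vars = vapply(f, `[[`, "", "var"),
         pows = vapply(f, `[[`, 0L, "pow"))
  } else {
    f <- split_pow(term)
    list(kind = if (f$pow == 2L) "square" else "main", vars = f$var)
  }
}

# evaluate a parsed term on a data frame
eval_term <- function(p, data) {
  switch(p$kind,
    main = as.numeric(data[[p$vars]]),
    square = as.numeric(data[[p$vars]])^2,
    product = as.numeric(data[[p$vars[1]]])^p$pows[1] *
      as.numeric(data[[p$vars[2]]])^p$pows[2]
  )
}

#' Build a design matrix from a cohort and a model spec
#'
#' Deterministic column order: intercept first, then the forced treatment
#' main effect (outcome specs), then the spec's terms in the order given.
#'
#' @param data A cohort data frame.
#' @param spec A [model_spec()] (or a character vector of term strings, which
#'   is promoted to a spec with no forced treatment term).
#' @return Numeric matrix with named columns; first column `(Intercept)`.
#' @export
build_design_matrix <- function(data, spec) {
  if (is.character(spec)) {
    spec <- model_spec(spec, response = "treatment")
  }
  stopifnot(inherits(spec, "model_spec"))
  terms <- c(if (spec$include_treatment_main) "a", spec$terms)
  n <- nrow(data)
  cols <- lapply(terms, function(tm) {
    p <- parse_term(tm)
    missing <- setdiff(p$vars, names(data))
    if (length(missing)) {
      abort(sprintf("Column `%s` referenced by term `%s` is not in the data.",
                    missing[1], tm))
    }
    eval_term(p, data)
  })
  x <- cbind(1, do.call(cbind, cols))
  colnames(x) <- c("(Intercept)", terms)
  x
}

#' Named nuisance-model presets for the two simulation scenarios
#'
#' `"correct"` presets match the data-generating models (scenario 1: main
#' terms for the treatment; main terms plus the age-by-comorbidity product
#' `w2:w4` for the outcome; scenario 2: `w2:w4` in both). `"misspecified"`
#' presets are main-terms only, i.e. they omit the `w2:w4` interaction used
#' to generate the data.
#'
#' @param scenario 1 or 2.
#' @param response `"treatment"` or `"outcome"`.
#' @param form `"correct"` or `"misspecified"`.
#' @return A [model_spec()].
#' @export
spec_preset <- function(scenario = 1,
                        response = c("treatment", "outcome"),
                        form = c("correct", "misspecified")) {
  response <- match.arg(response)
  form <- match.arg(form)
  stopifnot(scenario %in% c(1, 2))
  mains <- c("w1", "w2", "w3", "w4")
  terms <- if (form == "misspecified") {
    mains
  } else if (scenario == 2) {
    # both scenario-2 generating models carry the full age-by-comorbidity
    # interaction, including its nonlinear component
    c(mains, "w2:w4", "w2^2:w4")
  } else if (response == "outcome") {
    c(mains, "w2:w4")
  } else {
    mains
  }
  model_spec(terms, response = response)
}
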