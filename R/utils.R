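expit <- function(x) plogis(x)

logit <- function(p) qlogis(p)

# clamp probabilities away from 0/1 before logit transforms
trunc_prob <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

#' Derive independent sub-seeds from one master seed
#'
#' Expands a single integer seed into `n` reproducible sub-seeds, one per
#' random stage (covariates, treatment, outcome, ...) or per Monte Carlo
#' replication, so that any stage or replication can be re-run in isolation.
#'
#' @param seed Master seed (single integer).
#' @param n Number of sub-seeds.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed), n >= 0)
  if (n == 0L) return(integer(0))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, code) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

check_binary <- function(x, name = deparse(substitute(x))) {
  if (anyNA(x) || !all(x %in% c(0, 1))) {
    abort(sprintf("`%s` must be a binary 0/1 vector without missing values.",
                  name))
  }
  invisible(as.numeric(x))
}

check_prob <- function(p, name = deparse(substitute(p)), open = FALSE) {
  if (anyNA(p)) abort(sprintf("`%s` contains missing values.", name))
  bad <- if (open) any(p <= 0 | p >= 1) else any(p < 0 | p > 1)
  if (bad) {
    abort(sprintf("`%s` must lie in %s.", name,
                  if (open) "(0, 1)" else "[0, 1]"))
  }
  invisible(as.numeric(p))
}
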