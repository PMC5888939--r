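# shared fixtures, all generated in code

# a cohort with a single binary covariate, fully saturated by w-only specs
toy_binary_cohort <- function(n = 400, seed = 42) {
  with_seed_local(seed, {
    w <- rbinom(n, 1, 0.5)
    g <- ifelse(w == 1, 0.7, 0.3)
    a <- rbinom(n, 1, g)
    py <- plogis(-0.5 + 0.8 * w - 0.9 * a)
    y <- rbinom(n, 1, py)
    tibble::tibble(w = w, a = a, y = y)
  })
}

# completely randomised cohort (A independent of W)
randomized_cohort <- function(n = 5000, seed = 7) {
  cfg <- dgp_scenario1()
  with_seed_local(seed, {
    w <- generate_covariates(cfg, n, seed = seed)
    a <- rbinom(n, 1, 0.5)
    y <- generate_outcome(cfg, w, a, seed = seed + 1)
    dplyr::mutate(w, a = a, y = as.numeric(y))
  })
}

with_seed_local <- function(seed, code) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# nonparametric standardised risk difference from a cohort with one binary
# covariate: sum_w P(w) [P(y|a=1,w) - P(y|a=0,w)]
standardized_rd_oracle <- function(cohort) {
  out <- 0
  for (wv in unique(cohort$w)) {
    sub <- cohort[cohort$w == wv, ]
    out <- out + nrow(sub) / nrow(cohort) *
      (mean(sub$y[sub$a == 1]) - mean(sub$y[sub$a == 0]))
  }
  out
}
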