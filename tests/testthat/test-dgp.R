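test_that("covariate generation follows the configured laws", {
  cfg <- dgp_scenario1()

  empty <- generate_covariates(cfg, 0, seed = 1)
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c("w1", "w2", "w3", "w4"))

  expect_error(generate_covariates(cfg, -1), "n")

  # binomial oracle: sample mean of w4 within 4 SE of p
  cfg$covariate_laws$w4$p <- 0.3
  n <- 100000
  w <- generate_covariates(cfg, n, seed = 3)
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(mean(w$w4) - 0.3), 4 * se)
  expect_true(all(w$w1 %in% 1:5))
  expect_true(all(w$w3 %in% 1:4))
  expect_true(all(w$w2 >= 0 & w$w2 <= 1))

  expect_identical(generate_covariates(cfg, 50, seed = 9),
                   generate_covariates(cfg, 50, seed = 9))
})

test_that("true propensity matches the logit closed form", {
  cfg <- dgp_scenario1()
  w <- generate_covariates(cfg, 200, seed = 1)

  cfg0 <- cfg
  cfg0$alpha[] <- 0
  expect_equal(true_propensity(cfg0, w), rep(0.5, 200))

  cfgc <- cfg
  cfgc$alpha[] <- 0
  cfgc$alpha[["(Intercept)"]] <- 1.3
  expect_equal(true_propensity(cfgc, w),
               rep(1 / (1 + exp(-1.3)), 200))

  expect_error(true_propensity(cfg, w[c("w1", "w2")]), "missing")

  # large severity forces part of the distribution towards zero
  cfg_sev <- dgp_scenario1(positivity_severity = 3)
  g <- true_propensity(cfg_sev, generate_covariates(cfg_sev, 10000, seed = 2))
  expect_lt(min(g), 0.01)
  expect_true(all(g > 0 & g < 1))
})

test_that("positivity severity knob behaves monotonically", {
  # severity 0: no near-violation with the default base coefficients
  cfg0 <- dgp_scenario1(positivity_severity = 0)
  g0 <- true_propensity(cfg0, generate_covariates(cfg0, 10000, seed = 5))
  expect_gt(min(g0), 0.05)

  p1 <- vapply(c(0, 0.5, 1, 2, 3), function(s) {
    cfg <- dgp_scenario1(positivity_severity = s)
    quantile(true_propensity(cfg, generate_covariates(cfg, 10000, seed = 5)),
             0.01)
  }, numeric(1))
  expect_true(all(diff(p1) < 0))
})

test_that("treatment draws are Bernoulli in the propensity", {
  expect_equal(generate_treatment(rep(1, 20), seed = 1), rep(1L, 20))
  expect_equal(generate_treatment(rep(0, 20), seed = 1), rep(0L, 20))
  expect_error(generate_treatment(c(0.5, 1.2)), "\\[0, 1\\]")

  n <- 100000
  a <- generate_treatment(rep(0.5, n), seed = 2)
  expect_lt(abs(mean(a) - 0.5), 4 * sqrt(0.25 / n))

  gfix <- with_seed_local(11, runif(100))
  expect_identical(generate_treatment(gfix, seed = 3),
                   generate_treatment(gfix, seed = 3))
})

test_that("outcome draws follow the structural logit model", {
  cfg <- dgp_scenario1()
  n <- 60000
  w <- generate_covariates(cfg, n, seed = 4)

  # null treatment coefficient: empirical risk difference near zero
  cfg_null <- cfg
  cfg_null$beta[["a"]] <- 0
  y1 <- generate_outcome(cfg_null, w, rep(1, n), seed = 5)
  y0 <- generate_outcome(cfg_null, w, rep(0, n), seed = 6)
  expect_lt(abs(mean(y1) - mean(y0)), 4 * sqrt(0.5 / n))

  # intercept-only: marginal mean is the inverse logit
  cfg_int <- cfg
  cfg_int$beta[] <- 0
  cfg_int$beta[["(Intercept)"]] <- -0.7
  cfg_int$beta[["w2:w4"]] <- 1e-12  # keep the invariant, negligible effect
  y <- generate_outcome(cfg_int, w, rep(0, n), seed = 7)
  expect_lt(abs(mean(y) - plogis(-0.7)), 4 * sqrt(0.25 / n))

  # flipping the sign of the treatment coefficient flips the effect sign
  cfg_flip <- cfg
  cfg_flip$beta[["a"]] <- -cfg$beta[["a"]]
  rd <- mean(generate_outcome(cfg, w, rep(1, n), seed = 8)) -
    mean(generate_outcome(cfg, w, rep(0, n), seed = 9))
  rd_flip <- mean(generate_outcome(cfg_flip, w, rep(1, n), seed = 8)) -
    mean(generate_outcome(cfg_flip, w, rep(0, n), seed = 9))
  expect_lt(rd, -0.1)
  expect_gt(rd_flip, 0.1)
})

test_that("plug-in true ATE matches its calibration and the counterfactual oracle", {
  cfg_null <- dgp_scenario1()
  cfg_null$beta[["a"]] <- 0
  expect_identical(compute_true_ate(cfg_null, 1000, seed = 1), 0)

  psi1 <- compute_true_ate(dgp_scenario1(), 1e6, seed = 2)
  expect_equal(psi1, -0.1813, tolerance = 0.005)
  psi2 <- compute_true_ate(dgp_scenario2(), 1e6, seed = 2)
  expect_equal(psi2, -0.1172, tolerance = 0.005)

  # counterfactual-sampling oracle: draw Y(1), Y(0) per subject and average
  cfg <- dgp_scenario1()
  n <- 200000
  w <- generate_covariates(cfg, n, seed = 3)
  y1 <- generate_outcome(cfg, w, rep(1, n), seed = 4)
  y0 <- generate_outcome(cfg, w, rep(0, n), seed = 5)
  psi_brute <- mean(y1) - mean(y0)
  mc_se <- sqrt(var(y1 - y0) / n)
  expect_lt(abs(psi_brute - psi1), 3 * mc_se)

  # seed invariance within Monte Carlo error
  psis <- vapply(1:4, function(s) compute_true_ate(cfg, 2e5, seed = s),
                 numeric(1))
  expect_lt(max(psis) - min(psis), 6 * sqrt(0.25 / 2e5))
})

test_that("cohort generation composes the stages reproducibly", {
  cfg <- dgp_scenario1()
  co <- generate_cohort(cfg, 1000, seed = 11)
  expect_equal(nrow(co), 1000L)
  expect_named(co, c("w1", "w2", "w3", "w4", "a", "y"))
  expect_true(all(co$a %in% 0:1) && all(co$y %in% 0:1))
  expect_false(anyNA(co))

  expect_identical(co, generate_cohort(cfg, 1000, seed = 11))
  co2 <- generate_cohort(cfg, 1000, seed = 12)
  expect_false(identical(co$a, co2$a))
  expect_false(identical(co$y, co2$y))

  # marginal P(Y=1) matches the plug-in mean of Q0(A, W)
  n <- 100000
  big <- generate_cohort(cfg, n, seed = 13)
  q_obs <- true_outcome_prob(cfg, big, big$a)
  expect_lt(abs(mean(big$y) - mean(q_obs)), 3 * sqrt(0.25 / n))
})

test_that("cohort CSV and DGP config round-trip through files", {
  co <- generate_cohort(dgp_scenario1(), 50, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- read_cohort(f)
  expect_equal(as.data.frame(back), as.data.frame(co), tolerance = 1e-12)
  expect_error(read_cohort({
    f2 <- tempfile(fileext = ".csv")
    write.csv(co[, -6], f2, row.names = FALSE)
    f2
  }), "lacks column")

  cfg <- dgp_scenario2()
  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(covariate_laws = cfg$covariate_laws, alpha = as.list(cfg$alpha),
         beta = as.list(cfg$beta), scenario_id = 2,
         positivity_severity = 1),
    fj, auto_unbox = TRUE, digits = NA)
  cfg2 <- read_dgp_config(fj)
  expect_equal(cfg2$beta, cfg$beta)
  expect_equal(cfg2$alpha, cfg$alpha)
})
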