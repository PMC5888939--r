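test_that("all estimators satisfy the 95% CI identity", {
  co <- generate_cohort(dgp_scenario1(), 800, seed = 1)
  ests <- list(
    ate_naive(co),
    ate_iptw_ra(co),
    ate_aiptw(co),
    ate_tmle(co, nuisance = "parametric")
  )
  for (e in ests) {
    expect_equal(unname(e$ci95),
                 c(e$psi - 1.96 * e$se, e$psi + 1.96 * e$se))
    expect_gte(e$se, 0)
  }
})

test_that("influence-curve SE follows its defining formula", {
  expect_equal(influence_se(rep(0.3, 50)), 0)
  expect_equal(influence_se(c(-1, 1)), sqrt(var(c(-1, 1)) / 2))
  expect_error(influence_se(1), "at least 2")
})

test_that("naive estimator is OLS with robust SEs", {
  # randomised, unadjusted: exactly the difference in means
  co <- randomized_cohort(2000, seed = 2)
  est <- ate_naive(co, outcome_spec = NULL)
  dm <- mean(co$y[co$a == 1]) - mean(co$y[co$a == 0])
  expect_equal(est$psi, dm, tolerance = 1e-12)

  # 6-row printed toy: hand-solved normal equations
  toy <- tibble::tibble(
    w = c(0, 1, 2, 0, 1, 2),
    a = c(1, 1, 1, 0, 0, 0),
    y = c(1, 0, 1, 0, 0, 1)
  )
  x <- cbind(1, toy$a, toy$w)
  beta_hand <- solve(crossprod(x), crossprod(x, toy$y))
  est_toy <- ate_naive(toy, outcome_spec = model_spec("w"))
  expect_equal(est_toy$psi, beta_hand[2], tolerance = 1e-10)

  expect_error(ate_naive(dplyr::mutate(toy, a = 1)), "arms")
})

test_that("IPTW-RA reduces to known closed forms", {
  # known constant g: equals the unweighted regression-adjustment estimate
  co <- randomized_cohort(3000, seed = 3)
  est <- ate_iptw_ra(co, outcome_spec = spec_preset(1, "outcome"), g = 0.5)
  xq <- build_design_matrix(co, model_spec(c("w1", "w2", "w3", "w4",
                                             "w2:w4"), "outcome",
                                           include_treatment_main = FALSE))
  f1 <- glm.fit(xq[co$a == 1, ], co$y[co$a == 1], family = binomial())
  f0 <- glm.fit(xq[co$a == 0, ], co$y[co$a == 0], family = binomial())
  ra <- mean(plogis(xq %*% coef(f1)) - plogis(xq %*% coef(f0)))
  expect_equal(est$psi, ra, tolerance = 1e-6)

  # saturated specs on one binary covariate: nonparametric standardisation
  tb <- toy_binary_cohort(500, seed = 4)
  est_sat <- ate_iptw_ra(tb,
                         treatment_spec = model_spec("w", "treatment"),
                         outcome_spec = model_spec("w", "outcome"))
  expect_equal(est_sat$psi, standardized_rd_oracle(tb), tolerance = 1e-6)
})

test_that("AIPTW matches its estimating-equation formula", {
  # zero-residual case: nuisances equal the saturated truth
  tb <- toy_binary_cohort(300, seed = 5)
  q1 <- ave(tb$y, tb$w, FUN = function(v) 0) # placeholder, filled below
  m1 <- tapply(tb$y[tb$a == 1], tb$w[tb$a == 1], mean)
  m0 <- tapply(tb$y[tb$a == 0], tb$w[tb$a == 0], mean)
  gq <- tapply(tb$a, tb$w, mean)
  q1 <- unname(m1[as.character(tb$w)])
  q0 <- unname(m0[as.character(tb$w)])
  g <- unname(gq[as.character(tb$w)])
  est <- ate_aiptw(tb, g = g, q1 = q1, q0 = q0)
  expect_equal(est$psi, mean(q1 - q0), tolerance = 1e-12)
  expect_equal(est$psi, standardized_rd_oracle(tb), tolerance = 1e-12)

  # 4-row worked example, hand formula
  toy <- tibble::tibble(w = c(1, 1, 0, 0), a = c(1, 0, 1, 0),
                        y = c(1, 0, 0, 1))
  g4 <- c(0.8, 0.8, 0.2, 0.2)
  hand <- mean(0.5 - 0.5 +
                 toy$a * (toy$y - 0.5) / g4 -
                 (1 - toy$a) * (toy$y - 0.5) / (1 - g4))
  est4 <- ate_aiptw(toy, g = g4, q1 = 0.5, q0 = 0.5)
  expect_equal(est4$psi, hand, tolerance = 1e-12)
  expect_equal(est4$se, sd(0.5 - 0.5 +
                             toy$a * (toy$y - 0.5) / g4 -
                             (1 - toy$a) * (toy$y - 0.5) / (1 - g4)) / 2,
               tolerance = 1e-12)
})

test_that("positivity violations raise informative errors", {
  co <- generate_cohort(dgp_scenario1(positivity_severity = 2), 2000,
                        seed = 6)
  expect_error(ate_aiptw(co, ps_tol = 0.05),
               class = "drate_positivity_error")
  err <- tryCatch(ate_aiptw(co, ps_tol = 0.05), error = identity)
  expect_match(conditionMessage(err), "[0-9]+ fitted propensity")
})

test_that("TMLE solves the efficient-score equation and stays bounded", {
  # fixed point: initial Q already solves the score -> epsilon ~ 0
  tb <- toy_binary_cohort(300, seed = 5)
  m1 <- tapply(tb$y[tb$a == 1], tb$w[tb$a == 1], mean)
  m0 <- tapply(tb$y[tb$a == 0], tb$w[tb$a == 0], mean)
  gq <- tapply(tb$a, tb$w, mean)
  q1 <- unname(m1[as.character(tb$w)])
  q0 <- unname(m0[as.character(tb$w)])
  g <- unname(gq[as.character(tb$w)])
  est <- ate_tmle(tb, nuisance = "fixed", g = g, q1 = q1, q0 = q0,
                  g_bounds = c(0, 1))
  eps <- est$diagnostics$fluctuation$epsilon
  expect_lt(max(abs(eps)), 1e-6)
  expect_equal(est$psi, mean(q1 - q0), tolerance = 1e-6)

  # empirical mean of the influence curve is zero after targeting
  co <- generate_cohort(dgp_scenario1(), 2000, seed = 7)
  fit <- ate_tmle(co, nuisance = "parametric")
  expect_lt(abs(fit$diagnostics$mean_ic), 1e-8)
  expect_true(fit$psi >= -1 && fit$psi <= 1)

  # adversarial near-positivity: AIPTW escapes [-1, 1], TMLE cannot
  adv <- tibble::tibble(w = c(5, 0, rep(0, 18)),
                        a = c(1, 1, rep(0, 18)),
                        y = c(1, 0, rep(c(0, 1), 9)))
  g_adv <- c(5e-4, 0.3, rep(0.5, 18))
  est_a <- ate_aiptw(adv, g = g_adv, q1 = 0.5, q0 = 0.5, ps_tol = 1e-8)
  est_t <- ate_tmle(adv, nuisance = "fixed", g = g_adv, q1 = 0.5, q0 = 0.5)
  expect_gt(est_a$psi, 1)
  expect_true(est_t$psi >= -1 && est_t$psi <= 1)
})

test_that("TMLE fluctuation matches a grid-search maximiser", {
  toy <- tibble::tibble(w = c(0, 1, 2, 1, 0), a = c(1, 1, 0, 0, 1),
                        y = c(1, 0, 1, 0, 1))
  g <- c(0.7, 0.6, 0.3, 0.4, 0.8)
  q1 <- c(0.6, 0.5, 0.55, 0.45, 0.7)
  q0 <- c(0.4, 0.35, 0.5, 0.3, 0.5)
  est <- ate_tmle(toy, nuisance = "fixed", g = g, q1 = q1, q0 = q0,
                  g_bounds = c(0, 1))
  eps <- est$diagnostics$fluctuation$epsilon

  # independent oracle: iteratively refined 2-d grid over the fluctuation
  # log-likelihood
  h1 <- toy$a / g
  h0 <- -(1 - toy$a) / (1 - g)
  q_obs <- ifelse(toy$a == 1, q1, q0)
  ll <- function(e1, e0) {
    p <- plogis(qlogis(q_obs) + e1 * h1 + e0 * h0)
    sum(toy$y * log(p) + (1 - toy$y) * log(1 - p))
  }
  centre <- c(0, 0); half <- 2
  for (round in 1:6) {
    e1s <- seq(centre[1] - half, centre[1] + half, length.out = 41)
    e0s <- seq(centre[2] - half, centre[2] + half, length.out = 41)
    vals <- outer(e1s, e0s, Vectorize(ll))
    ij <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    centre <- c(e1s[ij[1]], e0s[ij[2]])
    half <- half / 10
  }
  expect_equal(unname(eps), centre, tolerance = 1e-4)
  q1_star <- plogis(qlogis(q1) + centre[1] / g)
  q0_star <- plogis(qlogis(q0) - centre[2] / (1 - g))
  expect_equal(est$psi, mean(q1_star - q0_star), tolerance = 1e-4)
})

test_that("influence-curve SEs agree with the bootstrap", {
  co <- generate_cohort(dgp_scenario1(), 200, seed = 8)
  tspec <- spec_preset(1, "treatment")
  ospec <- spec_preset(1, "outcome")
  est <- ate_aiptw(co, tspec, ospec)
  boots <- with_seed_local(9, {
    vapply(seq_len(2000), function(b) {
      idx <- sample.int(nrow(co), replace = TRUE)
      tryCatch(suppressWarnings(ate_aiptw(co[idx, ], tspec, ospec)$psi),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  boot_se <- sd(boots, na.rm = TRUE)
  expect_lt(abs(est$se - boot_se) / boot_se, 0.15)
})

test_that("all estimators agree under randomisation", {
  co <- randomized_cohort(20000, seed = 10)
  dm <- mean(co$y[co$a == 1]) - mean(co$y[co$a == 0])
  se_dm <- sqrt(var(co$y[co$a == 1]) / sum(co$a) +
                  var(co$y[co$a == 0]) / sum(1 - co$a))
  ests <- c(
    ate_naive(co)$psi,
    ate_iptw_ra(co)$psi,
    ate_aiptw(co)$psi,
    ate_tmle(co, nuisance = "parametric")$psi
  )
  expect_true(all(abs(ests - dm) < 3 * se_dm))
})

test_that("estimates carry tidy and glance methods", {
  co <- generate_cohort(dgp_scenario1(), 500, seed = 11)
  est <- ate_aiptw(co)
  td <- tidy(est)
  expect_named(td, c("method", "estimate", "std.error", "conf.low",
                     "conf.high"))
  expect_equal(td$estimate, est$psi)
  gl <- glance(est)
  expect_equal(gl$nobs, 500L)
  expect_s3_class(estimate_ate(co, "naive"), "ate_estimate")
})
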