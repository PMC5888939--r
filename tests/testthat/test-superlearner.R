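test_that("fold assignment is a balanced seeded partition", {
  f <- make_folds(100, 10, seed = 1)
  expect_equal(as.integer(table(f)), rep(10L, 10))

  f2 <- make_folds(10, 3, seed = 2)
  expect_equal(sort(as.integer(table(f2)), decreasing = TRUE),
               c(4L, 3L, 3L))

  # partition: every index exactly once
  expect_equal(length(f), 100L)
  expect_true(all(f %in% 1:10))

  expect_identical(make_folds(57, 5, seed = 9), make_folds(57, 5, seed = 9))
  expect_error(make_folds(5, 10), "v <= n")

  # stratified folds stay globally balanced and balanced within stratum
  strata <- rep(c(0, 1), c(80, 20))
  fs <- make_folds(100, 5, seed = 3, strata = strata)
  expect_equal(as.integer(table(fs)), rep(20L, 5))
  expect_true(all(table(fs[strata == 1]) == 4L))
})

test_that("cross-validated risks match direct computation", {
  co <- generate_cohort(dgp_scenario1(), 200, seed = 1)
  x <- co[c("w1", "w2", "w3", "w4")]
  folds <- make_folds(200, 5, seed = 2)

  # duplicated learner gets identical risk
  lib2 <- learner_library(c("sl_glm", "sl_glm_interaction"))
  lib_dup <- structure(list(a = lib2$sl_glm, b = lib2$sl_glm),
                       class = "learner_library")
  r <- cv_risk(x, co$a, lib_dup, folds)
  expect_equal(r$risks[["a"]], r$risks[["b"]])

  # constant-predictor risk equals the closed form mean((y - p)^2)
  const_lrn <- structure(list(const = list(
    name = "const",
    fit = function(x, y) mean(y) * 0 + 0.3,
    predict = function(model, x) rep(model, nrow(x))
  )), class = "learner_library")
  rc <- cv_risk(x, co$y, const_lrn, folds)
  expect_equal(rc$risks[["const"]], mean((co$y - 0.3)^2), tolerance = 1e-12)

  # brute-force fold-by-fold oracle on a 30-row fixture
  co30 <- generate_cohort(dgp_scenario1(), 30, seed = 3)
  x30 <- co30[c("w1", "w2", "w3", "w4")]
  f30 <- make_folds(30, 3, seed = 4)
  lib1 <- learner_library("sl_glm")
  got <- cv_risk(x30, co30$y, lib1, f30)
  oracle <- mean(vapply(1:3, function(k) {
    test <- f30 == k
    xt <- cbind(1, as.matrix(x30[!test, ]))
    fit <- suppressWarnings(glm.fit(xt, co30$y[!test],
                                    family = binomial()))
    pr <- plogis(cbind(1, as.matrix(x30[test, ])) %*% coef(fit))
    mean((co30$y[test] - pr)^2)
  }, numeric(1)))
  expect_equal(got$risks[["sl_glm"]], oracle, tolerance = 1e-10)

  # failing learner is excluded with infinite risk
  bad <- structure(list(
    ok = lib2$sl_glm,
    boom = list(name = "boom", fit = function(x, y) stop("no"),
                predict = function(m, x) NULL)
  ), class = "learner_library")
  expect_warning(rb <- cv_risk(x, co$y, bad, folds), "infinite risk")
  expect_equal(rb$risks[["boom"]], Inf)
})

test_that("ensemble weights solve the simplex least-squares problem", {
  expect_equal(unname(ensemble_weights(matrix(0.4, 10, 1), rep(0:1, 5))), 1)

  with_seed_local(5, {
    y <- rbinom(60, 1, 0.5)
    z <- cbind(perfect = y, noise1 = runif(60), noise2 = runif(60))
    w <- ensemble_weights(z, y)
    expect_equal(unname(w["perfect"]), 1, tolerance = 1e-8)

    # grid-search oracle over the simplex, 3 learners
    z3 <- cbind(runif(60), plogis(y - 0.4 + rnorm(60, 0, 0.4)), runif(60))
    w3 <- ensemble_weights(z3, y)
    grid <- seq(0, 1, by = 0.01)
    best <- Inf; best_w <- NULL
    for (w1 in grid) for (w2 in grid[grid <= 1 - w1 + 1e-12]) {
      wv <- c(w1, w2, 1 - w1 - w2)
      r <- mean((y - drop(z3 %*% wv))^2)
      if (r < best) { best <- r; best_w <- wv }
    }
    expect_lt(mean((y - drop(z3 %*% w3))^2), best + 1e-6)
    expect_equal(unname(w3), best_w, tolerance = 0.02)
  })

  w2l <- with_seed_local(11,
                         ensemble_weights(matrix(runif(40), 20, 2),
                                          rep(0:1, 10)))
  expect_equal(sum(w2l), 1, tolerance = 1e-12)
  expect_true(all(w2l >= 0))
})

test_that("super learner ensembles behave as convex averages", {
  co <- generate_cohort(dgp_scenario1(), 500, seed = 6)
  x <- co[c("w1", "w2", "w3", "w4")]

  # degenerate library: predictions equal the single GLM's
  sl1 <- superlearner_fit(x, co$a, learner_library("sl_glm"), v = 5,
                          seed = 7)
  glm_fit <- fit_logistic(cbind(1, as.matrix(x)), co$a)
  expect_equal(superlearner_predict(sl1, x),
               pmin(pmax(glm_fit$fitted, 1e-6), 1 - 1e-6),
               tolerance = 1e-8)

  sl <- superlearner_fit(x, co$a, v = 5, seed = 8)
  p <- superlearner_predict(sl, x)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(abs(sum(sl$weights) - 1) < 1e-12)
  expect_true(all(sl$weights >= 0))

  # reproducible under the same seed
  sl_again <- superlearner_fit(x, co$a, v = 5, seed = 8)
  expect_equal(sl$weights, sl_again$weights)
  expect_equal(superlearner_predict(sl_again, x), p)

  # label equivariance: permuting the learner order leaves the ensemble
  # prediction unchanged (weights on learners with identical level-one
  # predictions are only identified up to their sum)
  lib_rev <- learner_library(rev(c("sl_step", "sl_glm",
                                   "sl_glm_interaction")))
  sl_rev <- superlearner_fit(x, co$a, lib_rev, v = 5, seed = 8)
  expect_equal(superlearner_predict(sl_rev, x), p, tolerance = 1e-6)
  expect_equal(sum(sl_rev$weights), sum(sl$weights))

  # convexity: ensemble level-one risk no worse than the best learner
  ens_risk <- mean((co$a - drop(sl$level_one %*% sl$weights))^2)
  expect_lte(ens_risk, min(sl$cv_risks) + 1e-8)
})

test_that("interaction learner wins on interaction-generated data", {
  co <- generate_cohort(dgp_scenario2(), 5000, seed = 9)
  x <- co[c("a", "w1", "w2", "w3", "w4")]
  folds <- make_folds(5000, 5, seed = 10, strata = co$y)
  r <- cv_risk(x, co$y, learner_library(c("sl_glm", "sl_glm_interaction")),
               folds)
  expect_lt(r$risks[["sl_glm_interaction"]], r$risks[["sl_glm"]])
})
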