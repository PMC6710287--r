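# Model specification, AICc, ranking, degeneracy to OLS, marginal R2 and
# prediction curves.

test_that("model specs enforce the longevity-variable and by-smooth rules", {
  expect_error(model_spec("bad", "distance",
                          linear_terms = c("fate", "remaining_lifespan")),
               "alternative longevity")
  expect_error(model_spec("bad", "movement",
                          smooth_terms = list(sm("hour", by = "fate"))),
               "main effect")
  ok <- model_spec("ok", "movement", linear_terms = "fate",
                   smooth_terms = list(sm("hour", by = "fate")))
  expect_true(ok$uses_fate)
  expect_false(ok$uses_lifespan)
})

test_that("candidate sets follow the hierarchical ladder", {
  mv <- build_candidate_set("movement")
  has_by_fate <- function(s, var) any(vapply(s$smooth_terms, function(x)
    x$var == var && identical(x$by, "fate"), TRUE))
  expect_true(has_by_fate(mv$fate_hour_jdate, "hour"))
  expect_true(has_by_fate(mv$fate_hour_jdate, "julian_date"))

  di <- build_candidate_set("distance")
  expect_true(all(vapply(di, function(s) length(s$smooth_terms) == 0, TRUE)))
  expect_true(any(vapply(di, function(s)
    "remaining_lifespan" %in% s$linear_terms, TRUE)))

  for (tr in c("movement", "activity", "distance")) {
    cs <- build_candidate_set(tr)
    expect_true("null" %in% names(cs))
    expect_true(all(vapply(cs, function(s) s$random && s$ar1, TRUE)))
  }
  expect_error(build_candidate_set("habitat"))
})

test_that("AICc follows its closed form and limits", {
  expect_equal(aicc(0, k = 2, n = 10), 4 + 12 / 7)
  expect_lt(abs(aicc(-100, k = 5, n = 1e9) - (200 + 10)), 1e-6)
  for (k in c(1, 3, 10)) {
    expect_gt(aicc(-50, k = k, n = 100), -2 * (-50) + 2 * k)  # AICc > AIC
  }
  expect_error(aicc(0, k = 9, n = 10), "undefined")
})

test_that("a spec without smooths, random terms or AR1 reduces to OLS", {
  set.seed(11)
  n <- 200
  d <- data.frame(log_dist = rnorm(n), age = runif(n, 3, 12),
                  julian_date = sample(-20:40, n, TRUE),
                  road_density = runif(n, 0.3, 1.5))
  spec <- model_spec("ols", "distance",
                     linear_terms = c("age", "julian_date", "road_density"),
                     random = FALSE, ar1 = FALSE)
  f <- fit_model(spec, d)
  X <- cbind(1, d$age, d$julian_date, d$road_density)
  beta_hat <- solve(t(X) %*% X, t(X) %*% d$log_dist)
  expect_equal(unname(f$coefficients$estimate), as.numeric(beta_hat),
               tolerance = 1e-8)
})

test_that("adding terms never decreases the maximized ML log-likelihood", {
  d <- simulate_lifespan_lmm(21)
  specs <- build_candidate_set("distance")
  lls <- vapply(c("null", "age", "controls", "roads", "lifespan"),
                function(nm) fit_model(specs[[nm]], d, method = "ML")$logLik, 0)
  expect_true(all(diff(lls) >= -1e-6))
})

test_that("ranking orders by AICc and breaks near-ties by parsimony", {
  fake <- function(name, ll, k, n = 1000) {
    structure(list(spec = list(name = name), converged = TRUE, logLik = ll,
                   k = k, n = n, aicc = aicc(ll, k, n)), class = "fit_result")
  }
  # singleton
  r1 <- rank_models(list(only = fake("only", -50, 3)))
  expect_equal(attr(r1, "best"), "only")
  expect_equal(r1$delta, 0)

  # clear separation: lower AICc wins
  r2 <- rank_models(list(a = fake("a", -50, 3), b = fake("b", -51.5, 3)))
  expect_equal(attr(r2, "best"), "a")

  # near-tie (delta < 2): fewer parameters wins despite higher AICc
  r3 <- rank_models(list(rich = fake("rich", -49.1, 6),
                         lean = fake("lean", -50, 4)))
  expect_lt(r3$delta[r3$model == "lean"], 2)
  expect_equal(attr(r3, "best"), "lean")

  # failed fits are dropped; all-failed errors
  bad <- structure(list(spec = list(name = "x"), converged = FALSE,
                        aicc = Inf, logLik = NA, k = NA, n = NA),
                   class = "fit_result")
  r4 <- rank_models(list(a = fake("a", -50, 3), x = bad))
  expect_equal(nrow(r4), 1)
  expect_error(rank_models(list(x = bad)), "no candidate")
})

test_that("marginal R2 spans its analytic extremes", {
  d <- simulate_lifespan_lmm(31, beta_rl = 0)
  specs <- build_candidate_set("distance")
  f0 <- fit_model(specs$null, d)
  expect_lt(marginal_r2(f0), 1e-6)     # intercept only: no fixed-effect variance

  set.seed(31)
  n <- 300
  d2 <- data.frame(log_dist = numeric(n), age = runif(n, 3, 12))
  d2$log_dist <- 2 + 0.5 * d2$age      # no noise at all
  f1 <- suppressWarnings(                # lm warns on a perfect fit
    fit_model(model_spec("det", "distance", linear_terms = "age",
                         random = FALSE, ar1 = FALSE), d2))
  expect_gt(marginal_r2(f1), 1 - 1e-6) # all variance from fixed effects
})

test_that("prediction curves are consistent and back-transform correctly", {
  set.seed(41)
  n <- 500
  d <- data.frame(age = runif(n, 3, 12))
  d$log_dist <- 6 + 0.05 * d$age + rnorm(n, 0, 0.3)
  spec <- model_spec("lin", "distance", linear_terms = "age",
                     random = FALSE, ar1 = FALSE)
  f <- fit_model(spec, d)
  cv <- predict_curve(f, "age", grid = c(5, 10), back_transform = FALSE)
  b <- f$coefficients$estimate
  expect_equal(cv$fit, b[1] + b[2] * c(5, 10), tolerance = 1e-8)

  # log responses are returned on the original scale: exp(0) = 1
  cvb <- predict_curve(f, "age", grid = c(5, 10))
  expect_equal(cvb$fit, exp(cv$fit), tolerance = 1e-8)

  expect_warning(predict_curve(f, "age", grid = c(0, 20)), "outside")

  # confidence bands shrink with sample size
  set.seed(42)
  big <- data.frame(age = runif(5000, 3, 12))
  big$log_dist <- 6 + 0.05 * big$age + rnorm(5000, 0, 0.3)
  fb <- fit_model(spec, big)
  w_small <- mean(predict_curve(f, "age", back_transform = FALSE)$upper -
                    predict_curve(f, "age", back_transform = FALSE)$lower)
  w_big <- mean(predict_curve(fb, "age", back_transform = FALSE)$upper -
                  predict_curve(fb, "age", back_transform = FALSE)$lower)
  expect_lt(w_big, w_small)
})

test_that("row order within AR1 groups does not change the fit", {
  d <- simulate_lifespan_lmm(51)
  spec <- build_candidate_set("distance")$lifespan
  f1 <- fit_model(spec, d)
  set.seed(1)
  f2 <- fit_model(spec, d[sample(nrow(d)), ])   # rows re-sorted internally
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-8)
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-8)
})
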