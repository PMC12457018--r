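test_that("profiled-REML fitter matches lme4 on a random-intercept LMM", {
  d <- make_grouped_data(n_id = 40, k = 3, seed = 2)
  sp <- model_spec("y", "x", "id", scale_continuous = FALSE)
  f1 <- fit_lmm(sp, d)
  f2 <- lme4::lmer(y ~ x + (1 | id), d, REML = TRUE)
  expect_equal(unname(f1$beta), unname(lme4::fixef(f2)), tolerance = 1e-6)
  expect_equal(unname(f1$varcomp),
               unname(c(unlist(lme4::VarCorr(f2)), sigma(f2)^2)),
               tolerance = 1e-6)
  expect_equal(f1$loglik, as.numeric(logLik(f2)), tolerance = 1e-8)
  expect_equal(unname(f1$se), unname(sqrt(diag(as.matrix(vcov(f2))))),
               tolerance = 1e-5)
})

test_that("balanced one-way variance components equal the ANOVA values", {
  set.seed(31)
  for (i in 1:5) {
    g <- rep(1:30, each = 4)
    y <- rnorm(30, 0, 1.3)[g] + rnorm(120, 0, 0.9)
    f <- fit_lmm(model_spec("y", random = "id", scale_continuous = FALSE),
                 data.frame(y = y, id = factor(g)))
    want <- anova_icc(y, g)
    expect_equal(unname(f$varcomp["id"]), want$sigma2_group, tolerance = 1e-6)
    expect_equal(unname(f$varcomp["residual"]), want$sigma2_resid,
                 tolerance = 1e-6)
  }
})

test_that("with no true group variance the LMM degenerates to OLS", {
  set.seed(4)
  n <- 400
  d <- data.frame(y = NA, x = rnorm(n), id = factor(rep(1:100, 4)))
  d$y <- 0.3 * d$x + rnorm(n)
  f <- fit_lmm(model_spec("y", "x", "id", scale_continuous = FALSE), d)
  ols <- lm(y ~ x, d)
  expect_lt(unname(f$varcomp["id"]), 0.02)
  expect_equal(unname(f$beta), unname(coef(ols)), tolerance = 1e-2)
  ## exact OLS agreement when the variance ratio is pinned at zero
  expect_equal(unname(paceline:::.reml_one_re(d$y, cbind(1, d$x), d$id)$beta),
               unname(coef(ols)), tolerance = 0.02)
})

test_that("slope recovery is unbiased at simulation scale", {
  est <- vapply(1:40, function(i) {
    d <- make_grouped_data(n_id = 167, k = 3, beta = 0.5, seed = 100 + i)
    unname(fit_lmm(model_spec("y", "x", "id", scale_continuous = FALSE),
                   d)$beta["x"])
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.5), 0.05)
})

test_that("singular designs are rejected naming the collinear column", {
  d <- make_grouped_data(seed = 6)
  d$x2 <- 2 * d$x
  expect_error(fit_lmm(model_spec("y", c("x", "x2"), "id"), d),
               "collinear.*x2")
})

test_that("two crossed random intercepts are supported", {
  d <- make_grouped_data(n_id = 60, k = 3, seed = 7)
  f <- fit_lmm(model_spec("y", "x", c("id", "prior_tests")), d)
  expect_named(f$varcomp, c("id", "prior_tests", "residual"))
  expect_true(all(f$varcomp >= 0))
  expect_equal(unname(f$beta["x"]), 0.5 / sd(d$y), tolerance = 0.25)
})

test_that("binomial GLMM: symmetric extreme groups give a centred intercept", {
  ## half the individuals always enter, half never: huge latent variance,
  ## intercept near zero
  d <- data.frame(y = rep(c(1, 0), each = 60),
                  id = factor(rep(1:40, each = 3)))
  f <- fit_binomial_glmm(model_spec("y", random = "id",
                                    family = "binomial"), d)
  expect_gt(unname(f$varcomp["id"]), 5)
  ## the likelihood is flat in the intercept here; it should stay small
  ## relative to the (huge) latent between-individual spread
  expect_lt(abs(unname(f$beta[1])) / sqrt(unname(f$varcomp["id"])), 0.5)
})

test_that("binomial GLMM recovers generating parameters", {
  est <- sapply(1:30, function(i) {
    set.seed(200 + i)
    id <- rep(1:250, each = 4)
    x <- rnorm(1000)
    eta <- -0.5 + 1.0 * x + rnorm(250, 0, 1)[id]
    d <- data.frame(y = rbinom(1000, 1, plogis(eta)), x = x,
                    id = factor(id))
    f <- fit_binomial_glmm(model_spec("y", "x", "id", family = "binomial",
                                      scale_continuous = FALSE), d)
    c(f$beta[1], f$beta["x"], sqrt(f$varcomp["id"]))
  })
  expect_lt(abs(mean(est[1, ]) + 0.5), 0.15)
  expect_lt(abs(mean(est[2, ]) - 1.0), 0.15)
  expect_lt(abs(mean(est[3, ]) - 1.0), 0.15)
})

test_that("zero-variance binomial data reduce to plain logistic regression", {
  set.seed(9)
  x <- rnorm(400)
  y <- rbinom(400, 1, plogis(0.5 * x))
  d <- data.frame(y = y, x = x, id = factor(rep(1:100, 4)))
  ## independent responses: the GLMM's group variance collapses and the
  ## likelihood matches glm's
  f <- fit_binomial_glmm(model_spec("y", "x", "id", family = "binomial",
                                    scale_continuous = FALSE), d)
  g <- glm(y ~ x, binomial, d)
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-4)
})

test_that("complete separation by a covariate is reported", {
  set.seed(10)
  x <- c(rnorm(100, -3), rnorm(100, 3))
  d <- data.frame(y = as.integer(x > 0), x = x,
                  id = factor(rep(1:50, 4)))
  expect_error(fit_binomial_glmm(model_spec("y", "x", "id",
                                            family = "binomial"), d),
               "separation.*x")
})

test_that("transform offsets keep arguments positive and are recorded", {
  d <- make_grouped_data(seed = 11)
  d$y <- d$y - max(d$y)  # all non-positive
  sp <- model_spec("y", "x", "id", transform = "log_offset")
  f <- fit_lmm(sp, d)
  expect_true(is.finite(f$loglik))
  expect_equal(f$design$offset_used, abs(min(d$y)) + 0.01)
  expect_error(fit_lmm(model_spec("y", "x", "id", transform = "log_offset",
                                  offset = 0.001), d), "non-positive")
})
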