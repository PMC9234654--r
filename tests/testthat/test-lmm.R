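# Random-intercept mixed models, AICc, all-subsets selection

balanced_oneway <- function(seed, groups = 6, per = 5, sd_u = 1.2) {
  set.seed(seed)
  g <- rep(paste0("g", seq_len(groups)), each = per)
  data.frame(y = rnorm(groups * per) +
               rep(rnorm(groups, sd = sd_u), each = per), g = g)
}

test_that("REML variance components match the one-way ANOVA closed form", {
  for (s in 1:3) {
    d <- balanced_oneway(s)
    f <- fit_lmm(y ~ 1, d, "g", "REML")
    a <- anova(lm(y ~ g, d))
    msb <- a["g", "Mean Sq"]; msw <- a["Residuals", "Mean Sq"]
    expect_equal(f$sigma2, msw, tolerance = 1e-8)
    expect_equal(f$sigma_u2, max(0, (msb - msw) / 5), tolerance = 1e-8)
  }
})

test_that("zero group variance collapses to ordinary least squares", {
  set.seed(5)
  d <- data.frame(x = rnorm(40), g = sample(letters[1:4], 40, TRUE))
  d$y <- 2 + 0.7 * d$x + rnorm(40)
  f <- fit_lmm(y ~ x, d, "g", "REML")
  expect_equal(f$lambda, 0)
  expect_equal(f$coefficients$estimate, unname(coef(lm(y ~ x, d))),
               tolerance = 1e-6)
  fm <- fit_lmm(y ~ x, d, "g", "ML")
  expect_equal(f$coefficients$estimate, fm$coefficients$estimate,
               tolerance = 1e-6)
})

test_that("fits agree with lme4 on unbalanced data with covariates", {
  skip_if_not_installed("lme4")
  set.seed(2)
  n <- 45
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n),
                  g = sample(letters[1:5], n, TRUE))
  d$y <- 1 + 0.5 * d$x1 - 0.3 * d$x2 +
    rnorm(5, sd = 0.8)[as.integer(factor(d$g))] + rnorm(n, sd = 0.5)
  mine <- fit_lmm(y ~ x1 + x2, d, "g", "REML")
  ref <- lme4::lmer(y ~ x1 + x2 + (1 | g), d, REML = TRUE)
  expect_equal(mine$coefficients$estimate, unname(lme4::fixef(ref)),
               tolerance = 1e-6)
  expect_equal(mine$logLik, as.numeric(logLik(ref)), tolerance = 1e-6)
  expect_equal(mine$sigma_u2, as.data.frame(lme4::VarCorr(ref))$vcov[1],
               tolerance = 1e-5)
  mml <- fit_lmm(y ~ x1 + x2, d, "g", "ML")
  refml <- lme4::lmer(y ~ x1 + x2 + (1 | g), d, REML = FALSE)
  expect_equal(mml$logLik, as.numeric(logLik(refml)), tolerance = 1e-6)
})

test_that("the REML optimum dominates the boundary and designs are
           guarded", {
  d <- balanced_oneway(9)
  f <- fit_lmm(y ~ 1, d, "g")
  at0 <- gammapop:::lmm_objective(0, d$y, matrix(1, nrow(d), 1),
                                  stats::model.matrix(~ factor(d$g) - 1),
                                  reml = TRUE)$m2ll
  expect_lte(-2 * f$logLik, at0 + 1e-8)
  d$x_dup <- 1   # collinear with the intercept
  expect_error(fit_lmm(y ~ x_dup, d, "g"), "singular|collinear")
})

test_that("slope recovery on study-shaped data is unbiased", {
  set.seed(33)
  ests <- replicate(500, {
    river <- rep(paste0("R", 1:6), length.out = 34)
    x <- rnorm(34, 2, 0.8)                 # log-total-AOM-like spread
    y <- 3 - 0.2 * x + rnorm(6, sd = 0.15)[as.integer(factor(river))] +
      rnorm(34, sd = 0.25)
    d <- data.frame(y = y, x = x, river = river)
    fit_lmm(y ~ x, d, "river")$coefficients$estimate[2]
  })
  expect_lt(abs(mean(ests) - (-0.2)), 0.02)   # within 10% of -0.2
})

test_that("AICc matches hand arithmetic and its large-n limit", {
  expect_equal(aicc(-5, 2, 10), 14 + 12 / 7)
  expect_lt(abs(aicc(-100, 3, 1e5) - (2 * 100 + 6)), 1e-3)
  expect_warning(v <- aicc(-5, 9, 10), "undefined")
  expect_true(is.na(v))
})

test_that("a pure-noise covariate increases AICc in expectation", {
  set.seed(44)
  deltas <- replicate(60, {
    d <- balanced_oneway(sample.int(1e6, 1), groups = 5, per = 6)
    d$z <- rnorm(nrow(d))
    fit_lmm(y ~ z, d, "g", "ML")$AICc - fit_lmm(y ~ 1, d, "g", "ML")$AICc
  })
  expect_gt(mean(deltas), 0)
})

test_that("dredge enumerates subsets, keeps the null model visible, and
           is order-invariant", {
  set.seed(55)
  n <- 40
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n),
                  g = sample(letters[1:5], n, TRUE))
  d$y <- 1 + 1.2 * d$x1 + rnorm(n, sd = 0.4)
  rk <- dredge_lmm(y ~ x1 + x2, d, "g")
  expect_equal(rk$n_candidates, 4)
  expect_true("1" %in% rk$all$model)
  expect_equal(rk$all$delta[1], 0)
  expect_true(all(diff(rk$all$AICc) >= 0))
  rk2 <- dredge_lmm(y ~ x2 + x1, d, "g")
  expect_equal(rk$all$AICc[1], rk2$all$AICc[1], tolerance = 1e-8)
  expect_error(dredge_lmm(
    stats::as.formula(paste("y ~", paste0("x", 1:13, collapse = "+"))),
    cbind(d, matrix(rnorm(n * 13), n,
                    dimnames = list(NULL, paste0("x", 1:13)))), "g"),
    "refusing")
})

test_that("dredge recovers a strong predictor and tolerates pure noise", {
  set.seed(66)
  hits <- replicate(60, {
    n <- 40
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n),
                    g = sample(letters[1:5], n, TRUE))
    d$y <- 1 + 1.5 * d$x1 + rnorm(n, sd = 0.4)
    grepl("x1", dredge_lmm(y ~ x1 + x2, d, "g")$all$model[1])
  })
  expect_gte(mean(hits), 0.95)
  null_ok <- replicate(40, {
    n <- 30
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n),
                    g = sample(letters[1:5], n, TRUE))
    d$y <- rnorm(n)
    dredge_lmm(y ~ x1 + x2, d, "g")$null_retained
  })
  expect_gt(mean(null_ok), 0.5)
})
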