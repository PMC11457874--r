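test_that("the worse-than-reference label uses a strict inequality", {
  expect_equal(make_response(c(139, 140, 300), 140), c(1L, 0L, 0L))
  expect_error(make_response(100, NA_real_), "missing")
})

test_that("the IRLS fit matches glm coefficients, SEs and deviances", {
  set.seed(41)
  for (i in 1:5) {
    n <- sample(80:300, 1)
    sf <- runif(n, 0, 90)
    y <- rbinom(n, 1, plogis(-2 + 0.05 * sf))
    if (length(unique(y)) < 2) next
    fit <- fit_logistic(sf, y)
    ref <- glm(y ~ sf, family = binomial())
    expect_equal(fit$beta0, unname(coef(ref)[1]), tolerance = 1e-6)
    expect_equal(fit$beta1, unname(coef(ref)[2]), tolerance = 1e-6)
    se <- sqrt(diag(vcov(ref)))
    expect_equal(fit$se0, unname(se[1]), tolerance = 1e-4)
    expect_equal(fit$se1, unname(se[2]), tolerance = 1e-4)
    expect_equal(fit$residual_deviance, deviance(ref), tolerance = 1e-8)
    expect_equal(fit$null_deviance, ref$null.deviance, tolerance = 1e-8)
    expect_lte(fit$residual_deviance, fit$null_deviance + 1e-8)
  }
})

test_that("a null response yields a flat slope and non-significant chi-square", {
  set.seed(42)
  ok <- 0L; reps <- 100L
  for (i in seq_len(reps)) {
    sf <- runif(2000, 0, 80)
    y <- rbinom(2000, 1, 0.5)
    fit <- fit_logistic(sf, y)
    chi <- fit$null_deviance - fit$residual_deviance
    p <- pchisq(chi, df = 1, lower.tail = FALSE)
    if (abs(fit$beta1) < 0.01 && p > 0.05) ok <- ok + 1L
  }
  expect_gte(ok / reps, 0.90)
})

test_that("degenerate logistic inputs error clearly", {
  expect_error(fit_logistic(c(10, 90), c(0, 1), min_n = 2), "separation")
  expect_error(fit_logistic(runif(50), rep(1, 50)), "single-label")
  expect_error(fit_logistic(runif(5), rbinom(5, 1, 0.5)), "at least 10")
})

test_that("predicted probabilities follow the logistic closed form", {
  m <- logistic_model(beta0 = -2.1, beta1 = 0.06)
  expect_equal(predict_probability(m, -m$beta0 / m$beta1), 0.5)
  expect_equal(predict_probability(m, 0), 0.1091, tolerance = 1e-4)
  flat <- logistic_model(beta0 = 0.7, beta1 = 0)
  expect_equal(predict_probability(flat, c(0, 50, 100)),
               rep(plogis(0.7), 3))
})

test_that("benchmark inversion solves the logit equation and round-trips", {
  m <- logistic_model(beta0 = -2.1, beta1 = 0.06)
  b <- invert_logistic(m, 0.5)
  expect_equal(b$sf_value, 35)
  expect_equal(b$rounded_sf, 35L)
  expect_equal(invert_logistic(logistic_model(0, 2), 0.5)$sf_value, 0)
  for (p in seq(0.05, 0.95, by = 0.05))
    expect_equal(predict_probability(m, invert_logistic(m, p)$sf_value), p,
                 tolerance = 1e-12)
  expect_error(invert_logistic(logistic_model(-2, -0.01), 0.5), "positive")
  expect_error(invert_logistic(m, 1), "inside")
  # SR75 always exceeds SR50 for a positive slope
  expect_gt(invert_logistic(m, 0.75)$sf_value,
            invert_logistic(m, 0.5)$sf_value)
})

test_that("benchmark rounding is half away from zero", {
  m <- logistic_model(beta0 = -2.18, beta1 = 0.06)
  b <- invert_logistic(m, 0.75)
  expect_equal(b$sf_value, (qlogis(0.75) + 2.18) / 0.06, tolerance = 1e-12)
  expect_equal(b$rounded_sf, 55L)
  half <- logistic_model(beta0 = -0.5 * log(3), beta1 = 0.01 * log(3))
  expect_equal(invert_logistic(half, 0.75)$sf_value, 150)
})

test_that("the odds-ratio Wald interval matches the closed form", {
  m <- logistic_model(beta0 = -2, beta1 = 0.06, se1 = 0.01)
  ci <- odds_ratio_ci(m)
  expect_equal(unname(ci), c(1.0412, 1.0829), tolerance = 1e-4)
  degen <- logistic_model(beta0 = -2, beta1 = 0.06, se1 = 0)
  expect_equal(unname(odds_ratio_ci(degen)), rep(exp(0.06), 2))
  null <- logistic_model(beta0 = -2, beta1 = 0, se1 = 0.01)
  ci0 <- odds_ratio_ci(null)
  expect_lt(ci0[["low"]], 1); expect_gt(ci0[["high"]], 1)
})

test_that("the Hosmer-Lemeshow statistic matches a hand computation", {
  # 20 events in 4 groups of 5; expected counts summed by hand
  m <- logistic_model(beta0 = -3, beta1 = 0.05)
  sf <- seq(5, 100, by = 5)
  y <- c(0, 0, 0, 0, 0, 1, 0, 0, 1, 0, 0, 1, 1, 0, 1, 1, 1, 0, 1, 1)
  hl <- hosmer_lemeshow(m, sf, y, groups = 4)
  p <- plogis(-3 + 0.05 * sf)
  stat_hand <- 0
  for (g in 1:4) {
    idx <- ((g - 1) * 5 + 1):(g * 5)
    O <- sum(y[idx]); E <- sum(p[idx]); pb <- E / 5
    stat_hand <- stat_hand + (O - E)^2 / (5 * pb * (1 - pb))
  }
  expect_equal(hl$statistic, stat_hand, tolerance = 1e-12)
  expect_equal(hl$groups_used, 4L)
  expect_equal(hl$p_value,
               pchisq(stat_hand, df = 2, lower.tail = FALSE))
})

test_that("Hosmer-Lemeshow rejects at roughly its nominal rate when the model is true", {
  set.seed(43)
  reps <- 200L
  rejected <- 0L
  for (i in seq_len(reps)) {
    sf <- runif(600, 0, 90)
    y <- rbinom(600, 1, plogis(-2.2 + 0.05 * sf))
    fit <- try(fit_logistic(sf, y), silent = TRUE)
    if (inherits(fit, "try-error")) next
    hl <- hosmer_lemeshow(fit, sf, y, groups = 10)
    if (hl$p_value < 0.05) rejected <- rejected + 1L
  }
  expect_gte(rejected / reps, 0.01)
  expect_lte(rejected / reps, 0.10)
})

test_that("Hosmer-Lemeshow degenerate configurations error", {
  m <- logistic_model(beta0 = -2, beta1 = 0.05)
  expect_error(hosmer_lemeshow(m, runif(40, 0, 80), rbinom(40, 1, 0.5),
                               groups = 2), "3 groups")
  expect_error(hosmer_lemeshow(m, runif(10, 0, 80), rbinom(10, 1, 0.5),
                               groups = 10), "at least 20")
})

test_that("tied predicted probabilities never straddle HL group boundaries", {
  m <- logistic_model(beta0 = -2, beta1 = 0.05)
  sf <- rep(c(10, 20, 30, 40), each = 10)   # only 4 distinct probabilities
  set.seed(44)
  y <- rbinom(40, 1, predict_probability(m, sf))
  hl <- hosmer_lemeshow(m, sf, y, groups = 10)
  expect_lte(hl$groups_used, 4L)
  expect_equal(sum(hl$table$n), 40L)
})

test_that("model chi-square is the null-residual deviance gap and is non-negative", {
  set.seed(45)
  sf <- runif(300, 0, 90)
  y <- rbinom(300, 1, plogis(-2 + 0.05 * sf))
  fit <- fit_logistic(sf, y)
  dg <- logistic_diagnostics(fit, sf, y)
  expect_equal(dg$model_chi_square,
               fit$null_deviance - fit$residual_deviance)
  expect_gte(dg$model_chi_square, 0)
  expect_equal(dg$odds_ratio, exp(fit$beta1))
})
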