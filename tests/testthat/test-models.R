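test_that("likelihood ratio test matches the chi-square oracle and guards inputs", {
  d <- simulate_amplitude_table(n_trees = 8, n_days = 20, slope = 0.03, seed = 71)
  m1 <- lme4::lmer(A ~ x + (1 + x | tree_id), data = d, REML = FALSE)
  m0 <- lme4::lmer(A ~ 1 + (1 + x | tree_id), data = d, REML = FALSE)
  lt <- likelihood_ratio_test(m0, m1)
  oracle <- suppressMessages(anova(m0, m1))   # lme4's own LRT as cross-check
  expect_equal(lt$chisq, oracle$Chisq[2], tolerance = 1e-6)
  expect_equal(lt$df, oracle$Df[2])
  expect_equal(lt$p, oracle$`Pr(>Chisq)`[2], tolerance = 1e-6)
  expect_equal(lt$p, pchisq(lt$chisq, 1, lower.tail = FALSE))

  expect_error(likelihood_ratio_test(m1, m0), "not nested")
  m1r <- lme4::lmer(A ~ x + (1 + x | tree_id), data = d, REML = TRUE)
  expect_error(likelihood_ratio_test(m0, m1r), "REML")
})

test_that("variance explained recovers known components", {
  withr::with_seed(72, {
    n_g <- 80; n_per <- 40
    g <- factor(rep(seq_len(n_g), each = n_per))
    x <- rnorm(n_g * n_per)
    b <- rnorm(n_g, 0, sqrt(2))
    y <- x + b[as.integer(g)] + rnorm(n_g * n_per)
  })
  fit <- lme4::lmer(y ~ x + (1 | g), REML = TRUE)
  pv <- variance_explained(fit)
  # oracle from the realized components of this sample
  vf <- var(x * unname(lme4::fixef(fit)["x"]))
  vr <- var(b); ve <- 1
  expect_equal(pv[["pct_fixed"]], 100 * vf / (vf + vr + ve), tolerance = 0.05)
  expect_equal(pv[["pct_fixed_random"]], 100 * (vf + vr) / (vf + vr + ve),
               tolerance = 0.05)

  # zero fixed slope -> ~0% fixed
  withr::with_seed(73, {
    y0 <- b[as.integer(g)] + rnorm(n_g * n_per)
  })
  fit0 <- lme4::lmer(y0 ~ x + (1 | g), REML = TRUE)
  expect_lt(variance_explained(fit0)[["pct_fixed"]], 0.5)
})

test_that("amplitude mixed model recovers an injected driver slope", {
  d <- simulate_amplitude_table(n_trees = 20, n_days = 40, slope = 0.02,
                                slope_sd = 0.005, seed = 74)
  f <- fit_amplitude_mixed_model(d, driver = "x")
  s <- f$full$fixed[f$full$fixed$term == "x", ]
  expect_lt(abs(s$estimate - 0.02), 2 * s$sd)
  expect_lt(f$lrt$p, 0.001)
  expect_gt(f$delta_aic, 2)
  expect_lte(f$full$pct_var_fixed, f$full$pct_var_fixed_random)
  expect_lte(f$full$pct_var_fixed_random, 100)

  # the reported estimates are the REML lme4 fit, verbatim
  direct <- lme4::lmer(A ~ x + (1 + x | tree_id), data = d, REML = TRUE)
  expect_equal(s$estimate, unname(lme4::fixef(direct)["x"]), tolerance = 1e-6)

  # slope 0 injected -> Delta AIC ~ 0 (within 2)
  d0 <- simulate_amplitude_table(n_trees = 20, n_days = 40, slope = 0, seed = 75)
  f0 <- suppressWarnings(fit_amplitude_mixed_model(d0, driver = "x"))
  expect_lt(abs(f0$delta_aic), 2)

  expect_error(fit_amplitude_mixed_model(
    tibble::tibble(tree_id = d$tree_id, A = d$A, x = 1), driver = "x"),
    "zero variance")
})

test_that("rain mixed model recovers an injected rain effect", {
  d <- simulate_increment_table(n_trees = 15, n_days = 40, rain_effect = 0.12,
                                seed = 76)
  f <- fit_rain_mixed_model(d, bark = TRUE, irrigated = TRUE)
  expect_lt(abs(f$rain_effect$estimate - 0.12), 2 * f$rain_effect$sd)
  expect_lt(f$lrt$p[f$lrt$model == "rain" & f$lrt$vs == "null"], 0.001)
  # bark and irrigation carry no effect in the generator
  expect_gt(f$lrt$p[f$lrt$model == "rain_bark" & f$lrt$vs == "rain"], 0.01)
  expect_gt(f$lrt$p[f$lrt$model == "rain_irrigated" & f$lrt$vs == "rain"], 0.01)

  # identical I on rainy and rain-free days -> estimate ~ 0, no AIC gain
  d0 <- simulate_increment_table(n_trees = 15, n_days = 40, rain_effect = 0,
                                 rain_effect_sd = 0, intercept_sd = 0.01,
                                 sigma = 0.02, seed = 77)
  f0 <- fit_rain_mixed_model(d0)
  expect_lt(abs(f0$rain_effect$estimate), 2 * f0$rain_effect$sd + 0.01)
  expect_lt(f0$delta_aic, 2)

  expect_error(fit_rain_mixed_model(
    tibble::tibble(tree_id = "a", I = 1:4, rain = TRUE)),
    "both rainy and rain-free")
})
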