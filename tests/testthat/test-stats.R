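test_that("Box-Cox closed forms hold at lambda 1 and 0", {
  x <- c(0.5, 1, 2, 7, 11)
  expect_equal(boxcox_transform(x, 1)$y, x - 1)
  expect_equal(boxcox_transform(x, 0)$y, log(x))
  expect_equal(cor(x, boxcox_transform(x, 1)$y), 1)  # affine map
  expect_error(boxcox_transform(c(-1, 2, 3), 2), "non-positive")
  expect_warning(out <- boxcox_transform(c(-1, 2, 3), 1, shift = TRUE),
                 "shifting")
  expect_equal(out$shift_offset, 2)
})

test_that("the ML exponent recovers the log transform for lognormal data", {
  withr::with_seed(47, {
    x <- exp(rnorm(500, 1, 0.6))
    fit <- boxcox_transform(x, "mle")
    expect_lt(abs(fit$lambda), 0.15)
  })
})

test_that("the profile-likelihood exponent agrees with the MASS reference", {
  withr::with_seed(53, {
    for (rep in 1:5) {
      x <- rgamma(200, shape = 2, scale = 3)
      lam <- boxcox_transform(x, "mle")$lambda
      bc <- MASS::boxcox(x ~ 1, lambda = seq(-3, 3, 0.01), plotit = FALSE)
      lam_ref <- bc$x[which.max(bc$y)]
      expect_equal(lam, lam_ref, tolerance = 0.02)
    }
  })
})

test_that("Benjamini-Hochberg follows the step-up rule", {
  expect_equal(benjamini_hochberg(0.03), 0.03)  # m = 1
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
  withr::with_seed(59, {
    for (rep in 1:50) {
      p <- runif(sample(1:20, 1))
      adj <- benjamini_hochberg(p)
      expect_equal(adj, oracle_bh(p))
      expect_true(all(adj >= p - 1e-15))
      expect_true(all(adj <= 1))
      o <- order(p)
      expect_true(all(diff(adj[o]) >= -1e-15))  # monotone in raw-p order
    }
  })
})

test_that("fixed effects match ordinary least squares when random variance is zero", {
  d <- toy_lmm_data(n_cage = 8, sd_cage = 0, sd_noise = 1, seed = 61)
  fit <- fit_lmm(d, "y", fixed = ~ Genotype, transform = "none")
  ols <- lm(y ~ Genotype, data = d)
  expect_true(fit$dropped_day_slope)  # zero-variance slope is singular
  expect_equal(unname(lme4::fixef(fit$fit)), unname(coef(ols)),
               tolerance = 1e-6)
})

test_that("degenerate and undersized inputs are rejected", {
  d <- toy_lmm_data()
  d$y <- 5
  expect_error(fit_lmm(d, "y", fixed = ~ Genotype, transform = "none"),
               "constant")
  d2 <- toy_lmm_data()
  expect_error(fit_lmm(d2[d2$cage_id == "c01", ], "y", fixed = ~ Genotype,
                       transform = "none"), "fewer than 2 cages")
})

test_that("model comparison reproduces the likelihood-ratio chi-square", {
  d <- toy_lmm_data(n_cage = 10, sd_cage = 2, sd_noise = 1, seed = 67)
  f0 <- fit_lmm(d, "y", fixed = ~ 1, random = "intercept", transform = "none")
  f1 <- fit_lmm(d, "y", fixed = ~ Genotype, random = "intercept",
                transform = "none")
  tab <- compare_models(f0, f1)
  m0 <- lme4::refitML(f0$fit); m1 <- lme4::refitML(f1$fit)
  want <- 2 * (as.numeric(logLik(m1)) - as.numeric(logLik(m0)))
  expect_equal(tab$chisq[2], want)
  expect_equal(tab$chi_df[2], 1)
  expect_equal(tab$p_value[2], pchisq(want, 1, lower.tail = FALSE))
  # identical models: statistic 0, p = 1
  # hand-computable 2-parameter nested pair: intercept vs genotype model
  expect_equal(tab$n_par, c(3, 4))
  same <- compare_models(f1, f1)
  expect_equal(same$chisq[2], 0, tolerance = 1e-6)
  expect_equal(same$p_value[2], 1)
})

test_that("likelihood-ratio p-values are roughly uniform under the null", {
  withr::with_seed(71, {
    p <- replicate(60, {
      d <- toy_lmm_data(n_cage = 10, sd_cage = 1, sd_noise = 1,
                        seed = sample.int(1e6, 1), beta_geno = 0)
      d$noisefac <- factor(sample(c("a", "b"), nrow(d), TRUE))
      f0 <- fit_lmm(d, "y", fixed = ~ Genotype, random = "intercept",
                    transform = "none")
      f1 <- fit_lmm(d, "y", fixed = ~ Genotype + noisefac,
                    random = "intercept", transform = "none")
      compare_models(f0, f1)$p_value[2]
    })
    expect_gt(mean(p), 0.35)
    expect_lt(mean(p), 0.65)
    expect_lte(mean(p < 0.05), 0.15)
  })
})

test_that("marginal means equal raw group means in a balanced one-factor design", {
  d <- toy_lmm_data(n_cage = 8, sd_cage = 0, sd_noise = 1, seed = 73)
  fit <- fit_lmm(d, "y", fixed = ~ Genotype, random = "intercept",
                 transform = "none")
  emm <- as.data.frame(suppressMessages(
    emmeans::emmeans(fit$fit, ~ Genotype, lmer.df = "satterthwaite")))
  raw <- tapply(d$y, d$Genotype, mean)
  expect_equal(emm$emmean, as.numeric(raw), tolerance = 1e-6)
})

test_that("contrasts between identical groups are zero and BH-adjusted", {
  d <- toy_lmm_data(n_cage = 8, sd_cage = 0, sd_noise = 1, seed = 79)
  # make the two genotype groups identical by construction
  d$y <- rep(d$y[d$Genotype == "WT"], 2)[seq_len(nrow(d))]
  d$y <- ave(d$y, d$day, FUN = function(v) rep(v[1], length(v)))
  fit <- fit_lmm(d, "y", fixed = ~ Genotype, transform = "none")
  ct <- emmeans_contrasts(fit, ~ Genotype)
  expect_equal(ct$estimate, 0, tolerance = 1e-8)
  expect_true(all(ct$p_adj >= ct$p_value - 1e-15))
  expect_s3_class(ct, "contrast_result")
})

test_that("significance stars follow the figure convention", {
  p <- c(0.5, 0.03, 0.005, 5e-4, 5e-5)
  expect_equal(as.character(climbr:::significance_stars(p)),
               c("ns", "*", "**", "***", "****"))
})
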