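test_that("WAIC identities: single draw, duplication, pointwise sum", {
  y <- c(0.2, 0.5, 0.7, 0.9, 0.4)
  dat <- data.frame(y = y)
  one <- reduced_fake(alpha = c(0.3, 0.3), phi = c(9, 9), chains = 2)
  # draws identical in both chains: zero posterior variance
  w1 <- waic(one, dat)
  ll <- dbeta(y, plogis(0.3) * 9, (1 - plogis(0.3)) * 9, log = TRUE)
  expect_equal(w1$p_waic, 0, tolerance = 1e-12)
  expect_equal(w1$waic, -2 * sum(ll), tolerance = 1e-10)
  expect_equal(sum(w1$pointwise$waic_i), w1$waic)

  three <- reduced_fake(alpha = c(0.1, 0.4, -0.2, 0.1, 0.4, -0.2),
                        phi = c(5, 8, 12, 5, 8, 12), chains = 2)
  # duplicating every draw leaves WAIC unchanged (chain 2 repeats chain 1)
  half <- reduced_fake(alpha = c(0.1, 0.4, -0.2), phi = c(5, 8, 12),
                       chains = 1)
  expect_equal(waic(three, dat)$waic, waic(half, dat)$waic,
               tolerance = 1e-10)
})

test_that("WAIC matches hand-computed log-sum-exp arithmetic", {
  y <- c(0.15, 0.42, 0.58, 0.77, 0.95)
  alphas <- c(0.0, 0.5, -0.3)
  phis <- c(4, 9, 6)
  ll <- sapply(y, function(yy) {
    mapply(function(a, p) {
      dbeta(yy, plogis(a) * p, (1 - plogis(a)) * p, log = TRUE)
    }, alphas, phis)
  })
  # explicit max-subtracted log-sum-exp oracle
  lppd <- sum(apply(ll, 2, function(col) {
    m <- max(col)
    m + log(mean(exp(col - m)))
  }))
  p_waic <- sum(apply(ll, 2, function(col) mean((col - mean(col))^2)))
  fit <- reduced_fake(alpha = rep(alphas, 2), phi = rep(phis, 2), chains = 2)
  # draws duplicated across chains leave the per-draw set identical
  w <- waic(reduced_fake(alpha = alphas, phi = phis, chains = 1),
            data.frame(y = y))
  expect_equal(w$lppd, lppd, tolerance = 1e-10)
  expect_equal(w$p_waic, p_waic, tolerance = 1e-10)
  expect_equal(w$waic, -2 * (lppd - p_waic), tolerance = 1e-10)
})

test_that("log-sum-exp stays finite for extreme log-likelihoods", {
  ll <- matrix(c(-1e4, -1e4 + 2, -9999, -1e4), nrow = 2)
  out <- streamgut:::logcolmeanexp(ll)
  expect_true(all(is.finite(out)))
  expect_equal(out[1], log(mean(exp(c(0, 2)))) - 1e4, tolerance = 1e-8)
})

test_that("model comparison is reflexive and order-invariant", {
  set.seed(3)
  g <- tiny_pair_obs(n = 80)
  fit_a <- sample_posterior(g$observations, model_spec("none"), chains = 2,
                            iterations = 300, warmup = 150, seed = 2)
  fit_b <- sample_posterior(g$observations, model_spec("ffg"), chains = 2,
                            iterations = 300, warmup = 150, seed = 2)
  self <- compare_models(list(m1 = fit_a, m2 = fit_a), g$observations)
  expect_equal(self$waic_delta, c(0, 0))
  expect_equal(self$se_waic_delta, c(0, 0))

  ab <- compare_models(list(a = fit_a, b = fit_b), g$observations)
  ba <- compare_models(list(b = fit_b, a = fit_a), g$observations)
  expect_equal(ab$model, ba$model)
  expect_equal(ab$waic, ba$waic)
})

test_that("Bayesian R2 hits its analytic endpoints", {
  dat <- data.frame(y = c(0.3, 0.5, 0.8, 0.6))
  # intercept-only: mu identical across observations, R2 = 0
  fit0 <- reduced_fake(alpha = c(0.2, 0.4), phi = c(10, 10), chains = 2)
  expect_equal(bayes_r2(fit0, dat)$mean, 0)

  # spread means and enormous precision: residual variance vanishes, R2 -> 1
  spec <- model_spec("none")
  lv <- list(family = c("A", "B"), genus = "g", ffg = "f", site = "s")
  mat <- cbind("alpha" = rep(0, 4), "a_family[A]" = rep(-2, 4),
               "a_family[B]" = rep(2, 4), "a_genus[g]" = 0, "a_ffg[f]" = 0,
               "a_site[s]" = 0, "sigma_family" = 1, "sigma_genus" = 1,
               "sigma_ffg" = 1, "sigma_site" = 1, "phi" = 1e8)
  fit1 <- fake_fit(mat, spec, levels = lv)
  dat2 <- data.frame(y = c(0.1, 0.9), family = c("A", "B"), genus = "g",
                     ffg = "f", site = "s", stringsAsFactors = FALSE)
  expect_gt(bayes_r2(fit1, dat2)$mean, 0.999)
})

test_that("variance partition reports ranking probabilities and is
           invariant to chain order", {
  spec <- model_spec("none")
  set.seed(5)
  n <- 40
  mat <- cbind("alpha" = rnorm(n), "sigma_family" = runif(n, 0.1, 0.3),
               "sigma_genus" = runif(n, 0.1, 0.3),
               "sigma_ffg" = runif(n, 1.0, 1.5),
               "sigma_site" = runif(n, 0.4, 0.6), "phi" = runif(n, 5, 15))
  fit <- fake_fit(mat, spec, levels = list())
  vp <- variance_partition(fit)
  expect_equal(unname(vp$pr_largest["ffg"]), 1)
  expect_equal(vp$pr_greater["ffg", "genus"], 1)
  expect_equal(sum(vp$pr_largest), 1)

  swapped <- fit
  swapped$draws <- fit$draws[, c(2, 1), , drop = FALSE]
  vp2 <- variance_partition(swapped)
  expect_equal(vp2$summary$mean, vp$summary$mean)

  expect_error(variance_partition(reduced_fake(c(0, 0), c(5, 5))), "sigma")
})

test_that("level predictions are monotone in the effect and wider for new
           levels", {
  spec <- model_spec("none")
  lv <- list(family = c("A", "B"), genus = "g", ffg = "f", site = "s")
  set.seed(2)
  n <- 400
  mat <- cbind("alpha" = rep(0, n), "a_family[A]" = rep(0.0, n),
               "a_family[B]" = rep(0.8, n), "a_genus[g]" = 0, "a_ffg[f]" = 0,
               "a_site[s]" = 0, "sigma_family" = rep(1, n),
               "sigma_genus" = 1, "sigma_ffg" = 1, "sigma_site" = 1,
               "phi" = 10)
  fit <- fake_fit(mat, spec, levels = lv)
  pa <- predict_levels(fit, "family", "A")
  pb <- predict_levels(fit, "family", "B")
  expect_equal(pa$mean, 0.5)
  expect_lt(pa$mean, pb$mean)
  pnew <- predict_levels(fit, "family", new_level = TRUE, seed = 4)
  expect_gt(pnew$q97.5 - pnew$q2.5,
            max(pa$q97.5 - pa$q2.5, pb$q97.5 - pb$q2.5))
  expect_error(predict_levels(fit, "order", "A"), "unknown factor")
  expect_error(predict_levels(fit, "family", "Z"), "unknown level")
})
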