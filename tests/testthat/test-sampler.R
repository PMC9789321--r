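test_that("reduced-model posterior mean matches dense-grid quadrature", {
  set.seed(42)
  phi0 <- 15
  y <- rbeta(60, plogis(0.8) * phi0, (1 - plogis(0.8)) * phi0)
  dat <- data.frame(y = pmin(pmax(y, 1e-12), 1 - 1e-12))
  fit <- sample_posterior(dat, model_spec_reduced(), chains = 4,
                          iterations = 2000, warmup = 1000, seed = 7)
  quad <- quadrature_posterior(dat$y)
  dm <- as_draws_matrix(fit)
  expect_lt(abs(mean(dm[, "alpha"]) - quad$mean_alpha), 0.02)
  expect_lt(abs(mean(dm[, "phi"]) - quad$mean_phi) / quad$mean_phi, 0.05)
})

test_that("the sampler is deterministic under seed reuse", {
  g <- tiny_pair_obs(n = 60)
  f1 <- sample_posterior(g$observations, model_spec("none"), chains = 2,
                         iterations = 200, warmup = 100, seed = 3)
  f2 <- sample_posterior(g$observations, model_spec("none"), chains = 2,
                         iterations = 200, warmup = 100, seed = 3)
  expect_identical(f1$draws, f2$draws)
  f3 <- sample_posterior(g$observations, model_spec("none"), chains = 2,
                         iterations = 200, warmup = 100, seed = 4)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("warmup adaptation lands acceptance in the targeted band", {
  g <- tiny_pair_obs(n = 200)
  fit <- sample_posterior(g$observations, model_spec("none"), chains = 2,
                          iterations = 600, warmup = 300, seed = 5)
  expect_true(all(fit$accept_rate > 0.20 & fit$accept_rate < 0.45))
})

test_that("parameters are recovered from model-simulated data", {
  cfg <- sim_config(sigma_ffg = 0.8, sigma_site = 0.5, sigma_family = 0.3,
                    sigma_genus = 0.3, alpha = 0.85, phi = 20, seed = 31)
  g <- generate_pair_observations(
    list(family = 21, genus = 21, ffg = 21, site = 21), cfg, n_obs = 1500)
  fit <- sample_posterior(g$observations, model_spec("none"), chains = 4,
                          iterations = 800, warmup = 400, seed = 13)
  dm <- as_draws_matrix(fit)
  # phi is tightly identified with 1500 observations
  expect_lt(abs(mean(dm[, "phi"]) - 20) / 20, 0.15)
  # alpha within its own posterior uncertainty of the truth
  expect_lt(abs(mean(dm[, "alpha"]) - 0.85), 4 * sd(dm[, "alpha"]))
  # with finitely many levels the sigma posterior tracks the realized
  # spread of that seed's effects: its 95% interval must cover the
  # realized effect SD of each factor
  for (f in c("family", "genus", "ffg", "site")) {
    realized <- sd(g$truth$effects[[f]])
    ci <- quantile(dm[, paste0("sigma_", f)], c(0.025, 0.975))
    expect_true(realized >= ci[1] && realized <= ci[2], label = f)
  }
  # convergence at the study's own bar
  d <- diagnostics(fit)
  expect_true(all(d$rhat < 1.1, na.rm = TRUE))
})

test_that("simulation-based calibration ranks of alpha are uniform", {
  # parameters are drawn from the model's own priors, except that phi is
  # rejection-sampled into [0.5, 2000]: the Gamma(0.01, 0.01) prior puts
  # most mass at values so small that Beta draws underflow double
  # precision, which no floating-point generator can represent; within
  # the representable region the generator and the fitted model agree
  n_rep <- 100
  n_obs <- 25
  ranks <- integer(n_rep)
  set.seed(99)
  seeds <- sample.int(1e6, n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(seeds[r])
    a0 <- rnorm(1, 0, 1)
    repeat {
      phi0 <- rgamma(1, 0.01, 0.01)
      if (phi0 > 0.5 && phi0 < 2000) break
    }
    y <- rbeta(n_obs, plogis(a0) * phi0, (1 - plogis(a0)) * phi0)
    y <- pmin(pmax(y, 1e-12), 1 - 1e-12)
    fit <- sample_posterior(data.frame(y = y), model_spec_reduced(),
                            chains = 2, iterations = 700, warmup = 300,
                            seed = seeds[r])
    draws <- as_draws_matrix(fit)[, "alpha"]
    thinned <- draws[seq(1, length(draws), by = 40)]  # 20 draws, 21 ranks
    ranks[r] <- sum(thinned < a0)
  }
  bins <- cut(ranks, breaks = seq(-0.5, 20.5, by = 3))  # 7 equal bins
  p <- suppressWarnings(chisq.test(table(bins))$p.value)
  expect_gt(p, 0.01)
})

test_that("partial pooling shrinks sparse levels toward the grand mean", {
  # family "rare" has 2 high observations, family "common" has 40; the
  # rare level's posterior mean must sit strictly between its raw mean and
  # the grand mean on the logit scale, and shrink more than the common one
  set.seed(8)
  mk <- function(fam, n, mu, phi = 30) {
    data.frame(y = rbeta(n, mu * phi, (1 - mu) * phi), family = fam,
               genus = "g", ffg = "f", site = "s", stringsAsFactors = FALSE)
  }
  dat <- rbind(mk("rare", 2, 0.9), mk("common", 40, 0.9),
               mk("bulk1", 40, 0.55), mk("bulk2", 40, 0.6),
               mk("bulk3", 40, 0.5))
  dat$y <- pmin(pmax(dat$y, 1e-6), 1 - 1e-6)
  fit <- sample_posterior(dat, model_spec("none"), chains = 2,
                          iterations = 1500, warmup = 700, seed = 17)
  dm <- as_draws_matrix(fit)
  grand <- mean(dm[, "alpha"])
  lvl_mean <- function(lv) mean(dm[, "alpha"] + dm[, paste0("a_family[", lv,
                                                            "]")])
  raw <- function(lv) qlogis(mean(dat$y[dat$family == lv]))
  expect_gt(lvl_mean("rare"), grand)
  expect_lt(lvl_mean("rare"), raw("rare"))
  # more data, less shrinkage (relative to each level's raw mean)
  shrink_rare <- (raw("rare") - lvl_mean("rare")) / (raw("rare") - grand)
  shrink_common <- (raw("common") - lvl_mean("common")) /
    (raw("common") - grand)
  expect_gt(shrink_rare, shrink_common)
})

test_that("split R-hat and ESS behave on constructed chains", {
  set.seed(6)
  good <- array(rnorm(4000), dim = c(1000, 4, 1),
                dimnames = list(NULL, NULL, "theta"))
  d <- diagnostics(good)
  expect_lt(d$rhat, 1.05)
  expect_gt(d$ess, 1000)

  bad <- good
  bad[, 1, 1] <- bad[, 1, 1] + 10
  expect_gt(diagnostics(bad)$rhat, 1.5)

  const <- array(1, dim = c(100, 4, 1), dimnames = list(NULL, NULL, "c"))
  dc <- diagnostics(const)
  expect_true(dc$constant)
  expect_true(is.na(dc$rhat))

  expect_error(diagnostics(array(1, dim = c(1, 4, 1))), "4 draws")
  expect_error(diagnostics(array(1, dim = c(100, 1, 1))), "2 chains")
})
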