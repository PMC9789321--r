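test_that("generated metadata mirrors the emulated survey design", {
  md <- generate_metadata(sim_config(seed = 4))
  expect_equal(nrow(md), 41)
  expect_equal(length(unique(md$site)), 10)
  expect_equal(length(unique(md$ffg)), 5)
  expect_true(all(nchar(md$site) == 4))
  expect_false(any(is.na(md$family)))
  # family -> order and genus -> family maps are functions
  expect_true(all(tapply(md$order, md$family,
                         function(x) length(unique(x))) == 1))
  named <- md[!is.na(md$genus), ]
  if (nrow(named)) {
    expect_true(all(tapply(named$family, named$genus,
                           function(x) length(unique(x))) == 1))
  }
})

test_that("metadata generation is deterministic and handles the minimal case", {
  cfg <- sim_config(seed = 9)
  expect_identical(generate_metadata(cfg), generate_metadata(cfg))
  one <- generate_metadata(sim_config(n_sites = 1, samples_per_site = 1,
                                      n_orders = 1, n_families = 1,
                                      n_genera = 1, n_ffgs = 1, seed = 2))
  expect_equal(nrow(one), 1)
  expect_false(any(is.na(one[c("sample_id", "order", "family", "site",
                               "ffg")])))
})

test_that("invalid generator configs are rejected", {
  expect_error(sim_config(n_families = 2, n_orders = 5), "n_families")
  expect_error(sim_config(phi = 0))
  expect_error(sim_config(sigma_ffg = -1))
  expect_error(sim_config(depth_min = 10, depth_max = 5))
})

test_that("count generation respects library sizes and determinism", {
  cfg <- sim_config(n_sites = 2, samples_per_site = 3, n_asvs = 40,
                    n_orders = 2, n_families = 4, n_genera = 5,
                    n_ffgs = 2, depth_min = 1000, depth_max = 1000, seed = 3)
  g <- generate_counts(generate_metadata(cfg), cfg)
  expect_true(all(colSums(g$table$counts) == 1000))
  expect_true(all(g$table$counts >= 0))
  expect_true(all(g$table$counts == round(g$table$counts)))
  expect_equal(colSums(g$table$counts), g$truth$depth,
               ignore_attr = TRUE)
  g2 <- generate_counts(generate_metadata(cfg), cfg)
  expect_identical(g$table$counts, g2$table$counts)
  cfg0 <- cfg
  cfg0$n_asvs <- 0
  expect_error(generate_counts(generate_metadata(cfg), cfg0), "n_asvs")
})

test_that("with all effect scales zero, pooled counts match the baseline", {
  # every sample shares one expected composition; chi-square goodness-of-fit
  # of pooled counts against it should not reject at alpha = 0.01 in >= 95%
  # of seeds
  n_rej <- 0
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(n_sites = 2, samples_per_site = 4, n_asvs = 15,
                      n_orders = 2, n_families = 3, n_genera = 4, n_ffgs = 2,
                      sigma_site = 0, sigma_ffg = 0, sigma_family = 0,
                      sigma_genus = 0, depth_min = 2000, depth_max = 2000,
                      seed = s)
    md <- generate_metadata(cfg)
    g <- generate_counts(md, cfg)
    # the common expected composition is the softmax of the realized baseline
    expected <- exp(g$truth$baseline) / sum(exp(g$truth$baseline))
    pooled <- rowSums(g$table$counts)
    p <- suppressWarnings(chisq.test(pooled, p = expected)$p.value)
    if (p < 0.01) n_rej <- n_rej + 1
  }
  expect_lte(n_rej, 5)
})

test_that("strong FFG selection separates FFGs in Bray-Curtis space", {
  closer_within <- 0
  for (s in seq_len(20)) {
    cfg <- sim_config(n_sites = 2, samples_per_site = 6, n_asvs = 60,
                      n_orders = 2, n_families = 6, n_genera = 6, n_ffgs = 3,
                      sigma_site = 0, sigma_family = 0, sigma_genus = 0,
                      sigma_ffg = 2.5, depth_min = 3000, depth_max = 3000,
                      seed = 100 + s)
    md <- generate_metadata(cfg)
    g <- generate_counts(md, cfg)
    dm <- bray_curtis(g$table)
    same <- outer(md$ffg, md$ffg, "==") & upper.tri(dm)
    diff <- (!outer(md$ffg, md$ffg, "==")) & upper.tri(dm)
    if (mean(dm[same]) < mean(dm[diff])) closer_within <- closer_within + 1
  }
  expect_gte(closer_within, 18)
})

test_that("per-FFG dissimilarity spread grows with sigma_ffg", {
  spread <- function(sig, seed) {
    cfg <- sim_config(sigma_ffg = sig, sigma_site = 0.1, sigma_family = 0.1,
                      sigma_genus = 0.1, seed = seed)
    g <- generate_pair_observations(
      list(family = 5, genus = 5, ffg = 8, site = 5), cfg, n_obs = 800)
    sd(tapply(g$observations$y, g$observations$ffg, mean))
  }
  lo <- mean(vapply(1:8, function(s) spread(0.1, s), numeric(1)))
  hi <- mean(vapply(1:8, function(s) spread(1.2, s), numeric(1)))
  expect_gt(hi, lo)
})

test_that("direct Beta-model draws obey the stated moments and determinism", {
  cfg0 <- sim_config(alpha = 0, sigma_site = 0, sigma_ffg = 0,
                     sigma_family = 0, sigma_genus = 0, phi = 8, seed = 11)
  g <- generate_pair_observations(list(family = 3, genus = 3, ffg = 3,
                                       site = 3), cfg0, n_obs = 10000)
  y <- g$observations$y
  expect_true(all(y > 0 & y < 1))
  se <- sqrt(0.25 / (1 + 8) / length(y))
  expect_lt(abs(mean(y) - 0.5), 3 * se)

  cfg_big <- sim_config(alpha = 0, sigma_site = 0, sigma_ffg = 0,
                        sigma_family = 0, sigma_genus = 0, phi = 1e6,
                        seed = 12)
  g2 <- generate_pair_observations(list(family = 2, genus = 2, ffg = 2,
                                        site = 2), cfg_big, n_obs = 5000)
  expect_lt(var(g2$observations$y), 1e-5)

  g3 <- generate_pair_observations(list(family = 3, genus = 3, ffg = 3,
                                        site = 3), cfg0, n_obs = 100)
  g4 <- generate_pair_observations(list(family = 3, genus = 3, ffg = 3,
                                        site = 3), cfg0, n_obs = 100)
  expect_identical(g3$observations$y, g4$observations$y)
  cfg_bad <- sim_config(seed = 1)
  cfg_bad$phi <- -1
  expect_error(generate_pair_observations(
    list(family = 2, genus = 2, ffg = 2, site = 2), cfg_bad, n_obs = 10),
    "phi")
})
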