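euclid_dm <- function(pts, scale_to_unit = TRUE) {
  d <- as.matrix(dist(pts))
  if (scale_to_unit) d <- d / max(d)
  rownames(d) <- colnames(d) <- paste0("s", seq_len(nrow(pts)))
  d
}

test_that("NMDS recovers embeddable configurations with near-zero stress", {
  set.seed(8)
  pts <- matrix(runif(10), ncol = 2)
  dm <- euclid_dm(pts)
  ord <- nmds(dm, k = 2, n_starts = 5, seed = 3)
  expect_lt(ord$stress, 0.01)
  expect_equal(colMeans(ord$points), c(NMDS1 = 0, NMDS2 = 0),
               tolerance = 1e-8)
  expect_error(nmds(dm[1:2, 1:2], k = 2), "at least")
})

test_that("NMDS stress is label-invariant and non-increasing in k", {
  set.seed(10)
  ct <- random_counts(30, 8, seed = 10)
  dm <- bray_curtis(ct)
  s1 <- nmds(dm, k = 2, n_starts = 8, seed = 1)$stress
  perm <- sample(nrow(dm))
  s2 <- nmds(dm[perm, perm], k = 2, n_starts = 8, seed = 1)$stress
  expect_equal(s1, s2, tolerance = 1e-3)
  s_full <- nmds(dm, k = nrow(dm) - 1, n_starts = 8, seed = 1)$stress
  expect_lte(s_full, s1 + 1e-8)
})

test_that("PERMANOVA exhaustive enumeration gives the exact cluster p-value", {
  dm <- two_cluster_dm()
  g <- rep(c("a", "b"), each = 3)
  res <- permanova(dm, g, method = "exhaustive")
  # only the true split and its mirror reach the observed separation:
  # 2 of the C(6,3) = 20 labeled assignments
  expect_equal(res$n_permutations, 20)
  expect_equal(res$p, 0.1)
})

test_that("sampled-permutation p matches exhaustive enumeration within 2 MC SE", {
  B <- 2000
  for (seed in 1:4) {
    ct <- random_counts(12, 8, seed = 100 + seed)
    dm <- bray_curtis(ct)
    g <- rep(c("a", "b"), each = 4)
    ex <- permanova(dm, g, method = "exhaustive")
    sam <- permanova(dm, g, n_permutations = B, seed = seed)
    center <- (1 + B * ex$p) / (1 + B)  # exact mean of the add-one estimator
    se <- sqrt(B * ex$p * (1 - ex$p)) / (1 + B)
    expect_lt(abs(sam$p - center), 2 * se + 1e-12)
    expect_equal(sam$statistic, ex$statistic)
  }
})

test_that("PERMANOVA pseudo-F agrees with vegan's adonis2 and is invariant", {
  skip_if_not_installed("vegan")
  ct <- random_counts(25, 9, seed = 42)
  dm <- bray_curtis(ct)
  g <- c("x", "x", "x", "y", "y", "y", "z", "z", "z")
  ours <- permanova(dm, g, n_permutations = 99, seed = 1)
  ad <- vegan::adonis2(stats::as.dist(dm) ~ g, permutations = 99)
  expect_equal(ours$statistic, ad$F[1], tolerance = 1e-10)
  # invariant under group renaming and sample reordering
  ren <- permanova(dm, c("x" = "g1", "y" = "g2", "z" = "g3")[g],
                   n_permutations = 99, seed = 1)
  expect_equal(ren$statistic, ours$statistic)
  perm <- sample(9)
  reord <- permanova(dm[perm, perm], g[perm], n_permutations = 99, seed = 1)
  expect_equal(reord$statistic, ours$statistic, tolerance = 1e-10)
  # determinism under seed reuse
  again <- permanova(dm, g, n_permutations = 99, seed = 1)
  expect_identical(again$permuted, ours$permuted)
  expect_error(permanova(dm, rep("a", 9)), "2 groups")
})

test_that("PERMDISP flags degenerate inputs and excludes singleton groups", {
  # two groups of coincident points: all centroid distances zero -> 0/0
  res <- permdisp(two_cluster_dm() * 0.8, rep(c("a", "b"), each = 3))
  expect_true(res$degenerate)
  expect_true(is.nan(res$statistic) || is.na(res$p))

  ct <- random_counts(20, 7, seed = 5)
  dm2 <- bray_curtis(ct)
  g <- c("a", "a", "a", "b", "b", "b", "solo")
  expect_warning(res2 <- permdisp(dm2, g, n_permutations = 99, seed = 2),
                 "solo")
  expect_equal(sum(res2$group_sizes), 6)
  expect_false(res2$degenerate)
})

test_that("PERMDISP F is scale-invariant and calibrated under equal dispersion", {
  ct <- random_counts(20, 8, seed = 6)
  dm <- bray_curtis(ct)
  g <- rep(c("a", "b"), each = 4)
  f1 <- permdisp(dm, g, n_permutations = 49, seed = 1)$statistic
  f2 <- permdisp(dm / 2, g, n_permutations = 49, seed = 1)$statistic
  expect_equal(f1, f2, tolerance = 1e-8)

  # duplicated point cloud under two labels: dispersions equal by
  # construction, so rejections at 0.05 should be rare
  n_ok <- 0
  for (seed in 1:100) {
    set.seed(seed)
    pts <- matrix(rnorm(10), ncol = 2)
    dup <- rbind(pts, pts)
    dmd <- euclid_dm(dup)
    p <- suppressWarnings(
      permdisp(dmd, rep(c("a", "b"), each = 5), n_permutations = 99,
               seed = seed)$p)
    if (is.na(p) || p > 0.05) n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 90)
})

test_that("indicator screen ranks a perfectly separated taxon first", {
  set.seed(11)
  base <- matrix(rpois(100, 20), nrow = 10)
  base[1, ] <- c(rep(40, 5), rep(0, 5))  # present only in group a
  ct <- toy_counts(base)
  g <- rep(c("a", "b"), each = 5)
  res <- indicator_kw(ct, g)
  expect_equal(which.min(res$tests$p), 1)
  expect_equal(res$tests$q, p.adjust(res$tests$p, "BH"))
  # step-up rule on a known p-vector
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  # q >= p always; BH never beats the raw threshold rule
  expect_true(all(res$tests$q >= res$tests$p - 1e-12))
  expect_lte(length(res$significant), sum(res$tests$p <= res$q_threshold))
  # constant taxa get p = 1, not an error
  cst <- toy_counts(matrix(c(5, 5, 5, 5, 10, 20, 10, 20), nrow = 2,
                           byrow = TRUE))
  res2 <- indicator_kw(cst, c("a", "a", "b", "b"))
  expect_equal(res2$tests$p[1], 1)
})

test_that("indicator screen recovers spiked taxa with controlled FDP", {
  # 90 null taxa, 10 spiked with a strong but abundance-balanced group
  # shift (taxa 1-5 up, 6-10 down in group a), so null taxa keep their
  # relative abundance across groups
  set.seed(77)
  ct <- toy_counts(spiked_table(n_per = 8, seed = 77))
  g <- rep(c("a", "b", "c", "d", "e"), each = 8)
  res <- indicator_kw(ct, g)
  hits <- res$significant
  spiked <- paste0("t", 1:10)
  expect_gte(length(intersect(hits, spiked)), 8)
  fdp <- length(setdiff(hits, spiked)) / max(1, length(hits))
  expect_lte(fdp, 0.2)
  expect_equal(dim(res$group_means)[2], 5)
})
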