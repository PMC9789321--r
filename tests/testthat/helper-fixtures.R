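# shared builders for in-code fixtures

neon_metadata_path <- function() {
  system.file("extdata", "neon_sample_metadata.tsv", package = "streamgut")
}

toy_counts <- function(mat, taxa = NULL, samples = NULL, taxonomy = NULL) {
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(mat)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(mat)))
  dimnames(mat) <- list(taxa, samples)
  count_table(mat, taxonomy)
}

random_counts <- function(n_taxa, n_samples, lambda = 10, seed = 1) {
  set.seed(seed)
  mat <- matrix(rpois(n_taxa * n_samples, lambda), nrow = n_taxa)
  # ensure no all-zero sample
  for (j in which(colSums(mat) == 0)) mat[1, j] <- 1
  toy_counts(mat)
}

# independent brute-force Bray-Curtis (double loop, straight from the formula)
brute_bray <- function(counts) {
  n <- ncol(counts)
  m <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      xi <- counts[, i]; xj <- counts[, j]
      m[i, j] <- 1 - 2 * sum(pmin(xi, xj)) / (sum(xi) + sum(xj))
    }
  }
  m
}

tiny_metadata <- function() {
  md <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    order = c("Ephemeroptera", "Ephemeroptera", "Diptera", "Diptera"),
    family = c("FamA", "FamA", "FamB", "FamB"),
    genus = c("GenX", "GenX", NA, "GenY"),
    site = c("AAAA", "AAAA", "BBBB", "BBBB"),
    ffg = c("scrapers", "scrapers", "predators", "predators"),
    stringsAsFactors = FALSE)
  class(md) <- c("sample_metadata", "data.frame")
  md
}

# 100-taxon table, 5 groups: taxa 1-5 spiked up and 6-10 down in group "a"
# (balanced so the spiked set keeps its total expected abundance and null
# taxa keep their relative abundance); taxa 11-100 null
spiked_table <- function(n_per = 8, seed = 1, base_mean = 30, fold = 1.8) {
  stopifnot(fold <= 2)
  set.seed(seed)
  g <- rep(c("a", "b", "c", "d", "e"), each = n_per)
  mat <- matrix(rpois(100 * length(g), base_mean), nrow = 100)
  up <- base_mean * fold
  down <- 2 * base_mean - up  # keeps 5*up + 5*down = 10*base_mean
  for (t in 1:5) mat[t, g == "a"] <- rpois(n_per, up)
  for (t in 6:10) mat[t, g == "a"] <- rpois(n_per, down)
  mat
}

# two tight clusters of 3: zero within-cluster, unit between-cluster
two_cluster_dm <- function() {
  d <- matrix(1, 6, 6)
  d[1:3, 1:3] <- 0
  d[4:6, 4:6] <- 0
  diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("s", 1:6)
  d
}

# dense-grid quadrature posterior for the two-parameter reduced model
quadrature_posterior <- function(y, a_lim = c(-2, 2.5),
                                 lphi_lim = log(c(0.5, 200)), n_grid = 350) {
  agrid <- seq(a_lim[1], a_lim[2], length.out = n_grid)
  lpgrid <- seq(lphi_lim[1], lphi_lim[2], length.out = n_grid)
  lp <- outer(agrid, lpgrid, Vectorize(function(a, lp_) {
    phi <- exp(lp_)
    sum(dbeta(y, plogis(a) * phi, (1 - plogis(a)) * phi, log = TRUE)) +
      dnorm(a, 0, 1, log = TRUE) + 0.01 * lp_ - 0.01 * phi
  }))
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  list(mean_alpha = sum(rowSums(w) * agrid),
       mean_phi = sum(colSums(w) * exp(lpgrid)),
       sd_alpha = sqrt(sum(rowSums(w) * agrid^2) -
                         sum(rowSums(w) * agrid)^2))
}

# fabricate a posterior_draws object with prescribed parameter draws
fake_fit <- function(mat, spec, levels = NULL, chains = 2) {
  stopifnot(nrow(mat) %% chains == 0)
  draws <- array(NA_real_, dim = c(nrow(mat) / chains, chains, ncol(mat)),
                 dimnames = list(NULL, NULL, colnames(mat)))
  for (ch in seq_len(chains)) {
    idx <- seq((ch - 1) * nrow(mat) / chains + 1, ch * nrow(mat) / chains)
    draws[, ch, ] <- mat[idx, , drop = FALSE]
  }
  structure(list(draws = draws, params = colnames(mat), spec = spec,
                 levels = levels, accept_rate = rep(0.3, chains),
                 chains = chains, iterations = 2 * nrow(mat) / chains,
                 warmup = nrow(mat) / chains, seed = 1L),
            class = "posterior_draws")
}

reduced_fake <- function(alpha, phi, chains = 2) {
  fake_fit(cbind(alpha = alpha, phi = phi), model_spec_reduced(),
           levels = list(), chains = chains)
}

# small seeded pair-observation set for model tests
tiny_pair_obs <- function(n = 120, seed = 5, alpha = 0.5, phi = 15) {
  cfg <- sim_config(alpha = alpha, phi = phi, sigma_family = 0.4,
                    sigma_genus = 0.3, sigma_ffg = 0.6, sigma_site = 0.4,
                    seed = seed)
  generate_pair_observations(list(family = 4, genus = 5, ffg = 3, site = 4),
                             cfg, n_obs = n)
}
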