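#' Configuration for the synthetic-data generator
#'
#' Holds every knob of the generator: study design (sites, samples per site,
#' host orders/families/genera, functional feeding groups), the log-abundance
#' effect scales that drive community differences in count generation (and
#' double as logit-scale standard deviations when dissimilarity observations
#' are drawn directly from the Beta model), the Beta-model grand mean `alpha`
#' (logit scale) and precision `phi`, and the lognormal library-size model.
#'
#' Defaults emulate the study conditions of the survey the package targets:
#' 10 stream sites with 41 samples distributed as in the field metadata,
#' 7 host orders / 26 host families / 5 FFGs, ~20% of samples identified only
#' to family, logit-scale effect scales (ffg 0.8, site 0.5, family 0.3,
#' genus 0.3) around a grand mean of 0.85 with precision 20, and library
#' sizes clipped to the observed range 1235..98479 reads.
#'
#' @param n_sites Number of stream sites.
#' @param samples_per_site Scalar or per-site vector of sample counts.
#' @param n_asvs Number of ASVs in generated count tables.
#' @param n_orders,n_families,n_genera Host taxonomy pool sizes.
#' @param n_ffgs Number of functional feeding groups (max 5).
#' @param n_taxa_families Number of microbial families in generated lineages.
#' @param genus_missing_frac Fraction of samples with genus unidentified.
#' @param sigma_site,sigma_ffg,sigma_family,sigma_genus Non-negative effect
#'   scales (log-abundance for counts; logit-scale SDs for Beta-model draws).
#' @param alpha Grand mean on the logit scale.
#' @param phi Beta precision (> 0).
#' @param depth_log_mean,depth_log_sd Lognormal library-size parameters.
#' @param depth_min,depth_max Library-size clipping bounds.
#' @param seed Integer seed; all generator operations derive their RNG
#'   stream deterministically from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 10,
                       samples_per_site = c(2, 4, 5, 5, 4, 4, 5, 5, 5, 2),
                       n_asvs = 300,
                       n_orders = 7, n_families = 26, n_genera = 36,
                       n_ffgs = 5, n_taxa_families = 40,
                       genus_missing_frac = 0.2,
                       sigma_site = 0.5, sigma_ffg = 0.8,
                       sigma_family = 0.3, sigma_genus = 0.3,
                       alpha = 0.85, phi = 20,
                       depth_log_mean = 9.6, depth_log_sd = 1.0,
                       depth_min = 1235, depth_max = 98479,
                       seed = 1) {
  if (length(samples_per_site) == 1L) {
    samples_per_site <- rep(samples_per_site, n_sites)
  }
  cfg <- list(n_sites = n_sites, samples_per_site = samples_per_site,
              n_asvs = n_asvs, n_orders = n_orders, n_families = n_families,
              n_genera = n_genera, n_ffgs = n_ffgs,
              n_taxa_families = n_taxa_families,
              genus_missing_frac = genus_missing_frac,
              sigma_site = sigma_site, sigma_ffg = sigma_ffg,
              sigma_family = sigma_family, sigma_genus = sigma_genus,
              alpha = alpha, phi = phi,
              depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
              depth_min = depth_min, depth_max = depth_max,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_sites >= 1, n_orders >= 1, n_families >= 1, n_genera >= 0,
              n_ffgs >= 1, n_ffgs <= 5, length(samples_per_site) == n_sites,
              all(samples_per_site >= 1),
              sigma_site >= 0, sigma_ffg >= 0, sigma_family >= 0,
              sigma_genus >= 0, phi > 0,
              genus_missing_frac >= 0, genus_missing_frac <= 1,
              depth_min <= depth_max, depth_min >= 1)
  })
  if (cfg$n_families < cfg$n_orders) {
    stop("n_families must be >= n_orders so every order has a family")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Fixed per-operation seed derivation: each generator operation gets its own
# RNG stream from config$seed so metadata, counts and pair observations can be
# regenerated independently of one another.
stage_seed <- function(seed, stage) {
  offset <- c(metadata = 101L, counts = 202L, pairs = 303L, fixture = 404L)
  (as.integer(seed) + offset[[stage]]) %% .Machine$integer.max
}

host_order_pool <- c("Ephemeroptera", "Diptera", "Plecoptera", "Trichoptera",
                     "Coleoptera", "Odonata", "Megaloptera", "Hemiptera",
                     "Neuroptera", "Lepidoptera")

#' Generate synthetic sample metadata
#'
#' Draws a metadata table with one row per sample: sites with NEON-style
#' four-letter codes, a host taxonomy (order/family/genus, with family
#' nested in order and genus nested in family by construction) and an FFG
#' assigned per host family. A configurable fraction of samples has its
#' genus withheld (identified to family only). Every configured FFG is
#' guaranteed to appear among the samples.
#'
#' @param config A [sim_config()].
#' @return A `sample_metadata` data frame.
#' @export
generate_metadata <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "metadata"))
  n_sites <- config$n_sites
  sites <- character(0)
  while (length(unique(sites)) < n_sites) {
    sites <- unique(c(sites, paste(sample(LETTERS, 4, replace = TRUE),
                                   collapse = "")))
  }
  sites <- sites[seq_len(n_sites)]

  orders <- host_order_pool[seq_len(min(config$n_orders,
                                        length(host_order_pool)))]
  if (config$n_orders > length(host_order_pool)) {
    orders <- c(orders, sprintf("Order%02d",
                                seq_len(config$n_orders -
                                          length(host_order_pool))))
  }
  families <- sprintf("Family%02d", seq_len(config$n_families))
  # first block one family per order, remainder assigned at random
  fam_order <- c(orders,
                 sample(orders, config$n_families - config$n_orders,
                        replace = TRUE))
  names(fam_order) <- families
  ffgs <- ffg_vocabulary()[seq_len(config$n_ffgs)]
  fam_ffg <- c(rep(ffgs, length.out = min(config$n_ffgs, config$n_families)),
               sample(ffgs, max(0, config$n_families - config$n_ffgs),
                      replace = TRUE))
  names(fam_ffg) <- families
  genera <- if (config$n_genera > 0) {
    sprintf("Genus%03d", seq_len(config$n_genera))
  } else character(0)
  gen_fam <- if (length(genera)) {
    stats::setNames(sample(families, length(genera), replace = TRUE), genera)
  } else character(0)

  rows <- list()
  for (s in seq_len(n_sites)) {
    for (k in seq_len(config$samples_per_site[s])) {
      fam <- sample(families, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s-%02d", sites[s], k),
        order = fam_order[[fam]], family = fam, genus = NA_character_,
        site = sites[s], ffg = fam_ffg[[fam]], stringsAsFactors = FALSE)
    }
  }
  md <- do.call(rbind, rows)

  # guarantee FFG coverage: re-draw the family of arbitrary samples until
  # every configured FFG is represented (seeded, hence deterministic)
  for (iter in seq_len(1000)) {
    missing_ffg <- setdiff(ffgs, unique(md$ffg))
    if (!length(missing_ffg)) break
    cand <- names(fam_ffg)[fam_ffg == missing_ffg[1]]
    i <- sample(nrow(md), 1)
    fam <- if (length(cand) == 1) cand else sample(cand, 1)
    md$family[i] <- fam
    md$order[i] <- fam_order[[fam]]
    md$ffg[i] <- fam_ffg[[fam]]
  }

  # assign genera where the family has any, then blank a configured fraction
  for (i in seq_len(nrow(md))) {
    cand <- names(gen_fam)[gen_fam == md$family[i]]
    if (length(cand)) {
      md$genus[i] <- if (length(cand) == 1) cand else sample(cand, 1)
    }
  }
  blank <- stats::runif(nrow(md)) < config$genus_missing_frac
  md$genus[blank] <- NA_character_
  validate_metadata(md)
  class(md) <- c("sample_metadata", "data.frame")
  md
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Generate a synthetic ASV count table
#'
#' Compositional log-linear model: each ASV has a baseline log-abundance
#' drawn once; each sample's expected composition is the softmax of the
#' baseline plus site, FFG, host-family and host-genus effects (each drawn
#' Normal(0, sigma) per level per ASV); the library size is lognormal,
#' clipped to `[depth_min, depth_max]`; counts are multinomial. Every ASV
#' carries a bacterial taxonomy lineage down to a synthetic microbial family
#' and genus.
#'
#' @param metadata A `sample_metadata` data frame.
#' @param config A [sim_config()].
#' @return A list with elements `table` (a [count_table()]) and `truth`
#'   (realized per-level effect matrices plus the config).
#' @export
generate_counts <- function(metadata, config) {
  stopifnot(inherits(config, "sim_config"), nrow(metadata) >= 1)
  if (config$n_asvs < 1) stop("n_asvs must be >= 1")
  set.seed(stage_seed(config$seed, "counts"))
  n_asv <- config$n_asvs
  asvs <- sprintf("ASV%04d", seq_len(n_asv))

  mfam <- sprintf("mFam%03d", seq_len(config$n_taxa_families))
  asv_fam <- sample(mfam, n_asv, replace = TRUE)
  fam_phylum <- stats::setNames(
    sprintf("mPhylum%02d", 1 + (seq_along(mfam) - 1) %% 8), mfam)
  taxonomy <- stats::setNames(sprintf(
    "Bacteria;%s;%s_c;%s_o;%s;%s_g",
    fam_phylum[asv_fam], fam_phylum[asv_fam], asv_fam, asv_fam, asvs), asvs)

  baseline <- stats::rnorm(n_asv, 0, 1.5)
  draw_effects <- function(levels, sigma) {
    m <- matrix(stats::rnorm(length(levels) * n_asv, 0, sigma),
                nrow = length(levels), dimnames = list(levels, asvs))
    m
  }
  glev <- genus_levels(metadata)
  eff <- list(
    site = draw_effects(unique(metadata$site), config$sigma_site),
    ffg = draw_effects(unique(metadata$ffg), config$sigma_ffg),
    family = draw_effects(unique(metadata$family), config$sigma_family),
    genus = draw_effects(unique(glev), config$sigma_genus))

  depth <- round(stats::rlnorm(nrow(metadata), config$depth_log_mean,
                               config$depth_log_sd))
  depth <- pmin(pmax(depth, config$depth_min), config$depth_max)

  counts <- matrix(0, nrow = n_asv, ncol = nrow(metadata),
                   dimnames = list(asvs, metadata$sample_id))
  for (i in seq_len(nrow(metadata))) {
    eta <- baseline +
      eff$site[metadata$site[i], ] + eff$ffg[metadata$ffg[i], ] +
      eff$family[metadata$family[i], ] + eff$genus[glev[i], ]
    counts[, i] <- stats::rmultinom(1, depth[i], softmax(eta))
  }
  truth <- list(baseline = baseline, effects = eff, depth = depth,
                config = config)
  list(table = count_table(counts, taxonomy), truth = truth)
}

#' Draw dissimilarity observations directly from the hierarchical Beta model
#'
#' For each observation a level of each factor (family, genus, FFG, site) is
#' assigned uniformly at random; group effects are drawn Normal(0, sigma) per
#' level; the mean is the inverse logit of `alpha` plus the four effects and
#' the response is Beta(mu * phi, (1 - mu) * phi). The realized effects are
#' returned as ground truth, making parameter recovery checkable.
#'
#' @param levels Named list with character vectors (or level counts) for
#'   `family`, `genus`, `ffg`, `site`.
#' @param config A [sim_config()] supplying `alpha`, `phi` and the four
#'   sigma values.
#' @param n_obs Number of observations to draw.
#' @return A list with `observations` (a `pair_obs` data frame with column
#'   `y` and one level column per factor) and `truth` (effects, config).
#' @export
generate_pair_observations <- function(levels, config, n_obs = 1000) {
  stopifnot(inherits(config, "sim_config"))
  if (config$phi <= 0) stop("phi must be positive")
  levels <- lapply(levels, function(l) {
    if (is.numeric(l) && length(l) == 1) sprintf("L%03d", seq_len(l)) else l
  })
  stopifnot(all(c("family", "genus", "ffg", "site") %in% names(levels)))
  set.seed(stage_seed(config$seed, "pairs"))
  sigmas <- c(family = config$sigma_family, genus = config$sigma_genus,
              ffg = config$sigma_ffg, site = config$sigma_site)
  factors <- names(sigmas)
  eff <- lapply(factors, function(f) {
    stats::setNames(stats::rnorm(length(levels[[f]]), 0, sigmas[[f]]),
                    levels[[f]])
  })
  names(eff) <- factors
  assign <- lapply(factors, function(f) {
    sample(levels[[f]], n_obs, replace = TRUE)
  })
  names(assign) <- factors
  eta <- config$alpha +
    eff$family[assign$family] + eff$genus[assign$genus] +
    eff$ffg[assign$ffg] + eff$site[assign$site]
  mu <- stats::plogis(eta)
  y <- stats::rbeta(n_obs, mu * config$phi, (1 - mu) * config$phi)
  # Beta draws are strictly inside (0,1); guard against numerical underflow
  eps <- .Machine$double.eps
  y <- pmin(pmax(y, eps), 1 - eps)
  obs <- data.frame(sample_a = sprintf("obs%05d_a", seq_len(n_obs)),
                    sample_b = sprintf("obs%05d_b", seq_len(n_obs)),
                    y = y, family = assign$family, genus = assign$genus,
                    ffg = assign$ffg, site = assign$site,
                    stringsAsFactors = FALSE)
  class(obs) <- c("pair_obs", "data.frame")
  list(observations = obs, truth = list(effects = eff, config = config))
}
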