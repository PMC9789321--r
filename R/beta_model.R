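model_factors <- c("family", "genus", "ffg", "site")

#' Build Beta-regression observations from a distance matrix
#'
#' Turns a pairwise Bray-Curtis matrix plus sample metadata into the
#' observation set of the hierarchical Beta regression: one observation per
#' unordered sample pair. For each of the four factors (host family, host
#' genus, FFG, stream site) the observation's level is the shared label when
#' both samples agree and the sentinel `"mixed"` otherwise; `"mixed"` is
#' estimated like any other level downstream. Genus levels are made unique
#' within family (`"family/genus"`, with `"family:unknown"` for samples
#' identified only to family). Because the Beta density is undefined at 0
#' and 1 and Bray-Curtis attains both, every response is squeezed off the
#' boundary by `y' = (y (N - 1) + 0.5) / N` with `N` the number of pairs.
#'
#' @param dm Labeled symmetric dissimilarity matrix; its sample ids must all
#'   appear in `metadata$sample_id`.
#' @param metadata A `sample_metadata` data frame.
#' @param boundary_n Optional override of the squeeze denominator `N`.
#' @param shared_only_factor Optional factor name; if given, only pairs
#'   sharing that factor's level are kept (the alternative construction in
#'   which non-shared pairs are dropped for a single-factor analysis).
#' @return A `pair_obs` data frame with columns `sample_a`, `sample_b`, `y`,
#'   `family`, `genus`, `ffg`, `site`.
#' @export
build_pair_observations <- function(dm, metadata, boundary_n = NULL,
                                    shared_only_factor = NULL) {
  validate_distance_matrix(dm)
  ids <- rownames(dm)
  miss <- setdiff(ids, metadata$sample_id)
  if (length(miss)) {
    stop("sample(s) in distance matrix missing from metadata: ",
         paste(miss, collapse = ", "))
  }
  md <- metadata[match(ids, metadata$sample_id), ]
  lev <- list(family = md$family, genus = genus_levels(md),
              ffg = md$ffg, site = md$site)
  n <- length(ids)
  pair <- which(upper.tri(dm), arr.ind = TRUE)
  i <- pair[, 1]; j <- pair[, 2]
  obs <- data.frame(sample_a = ids[i], sample_b = ids[j],
                    y = dm[pair], stringsAsFactors = FALSE)
  for (f in model_factors) {
    obs[[f]] <- ifelse(lev[[f]][i] == lev[[f]][j], lev[[f]][i], "mixed")
  }
  if (!is.null(shared_only_factor)) {
    stopifnot(shared_only_factor %in% model_factors)
    obs <- obs[obs[[shared_only_factor]] != "mixed", , drop = FALSE]
  }
  N <- if (is.null(boundary_n)) nrow(obs) else boundary_n
  obs$y <- (obs$y * (N - 1) + 0.5) / N
  rownames(obs) <- NULL
  class(obs) <- c("pair_obs", "data.frame")
  obs
}

#' Specify a hierarchical Beta regression model
#'
#' The model is `y_i ~ Beta(mu_i phi, (1 - mu_i) phi)` with
#' `logit(mu_i) = alpha + a_family + a_genus + a_ffg + a_site`. At most one
#' factor is fixed (one unpooled coefficient per level, Normal(0,1) prior);
#' the remaining factors are varying intercepts with level effects
#' Normal(0, sigma_factor) and sigma_factor ~ Exponential(rate 0.5). The
#' grand mean has prior Normal(0,1) and the precision
#' phi ~ Gamma(shape 0.01, rate 0.01).
#'
#' @param fixed `"none"` (intercept-only, all four factors varying) or one
#'   of `"family"`, `"genus"`, `"ffg"`, `"site"`.
#' @return A list of class `beta_model_spec` with elements `fixed` and
#'   `varying`.
#' @export
model_spec <- function(fixed = c("none", "family", "genus", "ffg", "site")) {
  fixed <- match.arg(fixed)
  varying <- setdiff(model_factors, fixed)
  structure(list(fixed = fixed, varying = varying,
                 factors = model_factors,
                 prior = list(alpha_sd = 1, sigma_rate = 0.5,
                              phi_shape = 0.01, phi_rate = 0.01,
                              fixed_sd = 1)),
            class = "beta_model_spec")
}

#' Reduced two-parameter model specification
#'
#' A Beta regression with only the grand mean `alpha` and precision `phi`
#' (no group factors). Its posterior is two-dimensional and can be
#' integrated by dense-grid quadrature, which makes it the primary
#' correctness oracle for the MCMC sampler.
#'
#' @return A `beta_model_spec` with an empty factor set.
#' @export
model_spec_reduced <- function() {
  spec <- model_spec("none")
  spec$factors <- character(0)
  spec$varying <- character(0)
  spec
}

#' Beta log-likelihood in mean-precision parameterization
#'
#' Log density of `Beta(mu phi, (1 - mu) phi)` at `y`. All of `y` and `mu`
#' must be strictly inside (0, 1) — boundary squeezing must precede.
#'
#' @param y Observed values in (0, 1).
#' @param mu Means in (0, 1).
#' @param phi Positive precision.
#' @return Vector of log densities.
#' @export
beta_loglik <- function(y, mu, phi) {
  if (any(y <= 0 | y >= 1)) {
    stop("y on the boundary of (0, 1); apply the boundary squeeze first")
  }
  stopifnot(all(mu > 0 & mu < 1), phi > 0)
  stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE)
}

check_pair_obs <- function(data, factors = model_factors) {
  stopifnot(is.data.frame(data), nrow(data) >= 1,
            all(c("y", factors) %in% names(data)))
  if (any(data$y <= 0 | data$y >= 1)) {
    stop("responses must lie strictly in (0, 1)")
  }
  invisible(data)
}

factor_levels <- function(data, spec) {
  lapply(stats::setNames(spec$factors, spec$factors),
         function(f) sort(unique(as.character(data[[f]]))))
}

# linear predictor for a full parameter list
linear_predictor <- function(params, data, factors = model_factors) {
  eta <- rep(params$alpha, nrow(data))
  for (f in factors) {
    eta <- eta + unname(params$effects[[f]][as.character(data[[f]])])
  }
  eta
}

#' Joint log-posterior of the hierarchical Beta regression
#'
#' Reference implementation used for testing and quadrature: the sum of the
#' Beta log-likelihood, the Normal(0, sigma_factor) log densities of the
#' varying-intercept effects, and the prior log densities (alpha:
#' Normal(0,1); each sigma: Exponential(rate 0.5); phi: Gamma(0.01, 0.01);
#' fixed-factor coefficients: Normal(0,1)). Non-positive `sigma` or `phi`
#' yields `-Inf` rather than an error, as required by samplers.
#'
#' @param params List with `alpha`, `phi`, `sigma` (named vector over the
#'   varying factors) and `effects` (named list of named effect vectors per
#'   factor, covering every level in `data`).
#' @param data A `pair_obs` data frame.
#' @param spec A [model_spec()].
#' @return Scalar log-posterior (up to a constant in the data).
#' @export
log_posterior <- function(params, data, spec) {
  check_pair_obs(data, spec$factors)
  pr <- spec$prior
  if (params$phi <= 0) return(-Inf)
  if (length(spec$varying) && any(params$sigma[spec$varying] <= 0)) {
    return(-Inf)
  }
  eta <- linear_predictor(params, data, spec$factors)
  mu <- stats::plogis(eta)
  lp <- sum(beta_loglik(data$y, mu, params$phi))
  lp <- lp + stats::dnorm(params$alpha, 0, pr$alpha_sd, log = TRUE)
  for (f in spec$varying) {
    s <- params$sigma[[f]]
    lp <- lp + sum(stats::dnorm(params$effects[[f]], 0, s, log = TRUE))
    lp <- lp + stats::dexp(s, rate = pr$sigma_rate, log = TRUE)
  }
  if (spec$fixed != "none") {
    lp <- lp + sum(stats::dnorm(params$effects[[spec$fixed]], 0,
                                pr$fixed_sd, log = TRUE))
  }
  lp <- lp + stats::dgamma(params$phi, shape = pr$phi_shape,
                           rate = pr$phi_rate, log = TRUE)
  lp
}

#' Prior predictive simulation
#'
#' Draws parameters from their priors (alpha ~ Normal(0,1), sigma ~
#' Exponential(0.5), phi ~ Gamma(0.01, 0.01), effects from their implied
#' Normals), assigns each simulated observation a uniformly random level per
#' factor, and draws responses from the Beta likelihood. Used to check that
#' the priors generate plausible dissimilarities before seeing data.
#'
#' @param spec A [model_spec()].
#' @param levels Named list of level vectors (or counts) per factor.
#' @param n_draws Number of prior draws (one simulated y per draw).
#' @param seed Integer seed.
#' @return Numeric vector of `n_draws` simulated responses in (0, 1).
#' @export
prior_predictive <- function(spec, levels, n_draws = 1000, seed = 1) {
  stopifnot(inherits(spec, "beta_model_spec"))
  levels <- lapply(levels, function(l) {
    if (is.numeric(l) && length(l) == 1) sprintf("L%03d", seq_len(l)) else l
  })
  stopifnot(all(model_factors %in% names(levels)))
  set.seed(as.integer(seed))
  pr <- spec$prior
  y <- numeric(n_draws)
  for (s in seq_len(n_draws)) {
    alpha <- stats::rnorm(1, 0, pr$alpha_sd)
    eta <- alpha
    for (f in model_factors) {
      sd_f <- if (f %in% spec$varying) {
        stats::rexp(1, rate = pr$sigma_rate)
      } else {
        pr$fixed_sd
      }
      eff <- stats::rnorm(length(levels[[f]]), 0, sd_f)
      eta <- eta + eff[sample.int(length(eff), 1)]
    }
    phi <- stats::rgamma(1, shape = pr$phi_shape, rate = pr$phi_rate)
    mu <- stats::plogis(eta)
    y[s] <- stats::rbeta(1, mu * phi, (1 - mu) * phi)
  }
  eps <- .Machine$double.eps
  pmin(pmax(y, eps), 1 - eps)
}
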