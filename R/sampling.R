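#' Sample the posterior of the hierarchical Beta regression
#'
#' Adaptive Metropolis-within-Gibbs on a transformed space: varying-factor
#' effects are non-centered (`effect = sigma * z` with `z` updated on the
#' unit scale), `sigma` and `phi` are updated on the log scale with
#' Jacobian-corrected densities, and per-parameter proposal scales adapt
#' during warmup toward roughly 30% acceptance, after which they are
#' frozen. Chains are run sequentially from a single seeded RNG stream, so
#' the same seed reproduces the draws exactly.
#'
#' @param data A `pair_obs` data frame (see [build_pair_observations()] or
#'   [generate_pair_observations()]).
#' @param spec A [model_spec()].
#' @param chains Number of chains (default 4).
#' @param iterations Total iterations per chain (default 2000).
#' @param warmup Iterations discarded as warmup (default 1000).
#' @param seed Integer seed.
#' @return An object of class `posterior_draws`: `draws` is an
#'   iterations x chains x parameters array (post-warmup only) with named
#'   parameters (`alpha`, `a_<factor>[<level>]` effects on the natural
#'   scale, `sigma_<factor>` for varying factors, `phi`), plus sampler
#'   metadata (`spec`, `levels`, `accept_rate`, `seed`).
#' @export
sample_posterior <- function(data, spec = model_spec("none"), chains = 4,
                             iterations = 2000, warmup = 1000, seed = 1) {
  check_pair_obs(data, spec$factors)
  stopifnot(inherits(spec, "beta_model_spec"), chains >= 1,
            iterations > warmup, warmup >= 1)
  fct <- spec$factors
  levels <- factor_levels(data, spec)
  codes <- matrix(integer(0), nrow = nrow(data), ncol = length(fct))
  for (k in seq_along(fct)) {
    codes[, k] <- match(as.character(data[[fct[k]]]), levels[[fct[k]]]) - 1L
  }
  n_levels <- vapply(levels, length, integer(1))
  is_varying <- fct %in% spec$varying

  params <- c("alpha",
              unlist(lapply(fct, function(f) {
                sprintf("a_%s[%s]", f, levels[[f]])
              })),
              if (any(is_varying)) paste0("sigma_", fct[is_varying]),
              "phi")
  n_keep <- iterations - warmup
  draws <- array(NA_real_, dim = c(n_keep, chains, length(params)),
                 dimnames = list(NULL, NULL, params))
  accept <- numeric(chains)
  set.seed(as.integer(seed))
  for (ch in seq_len(chains)) {
    res <- .run_beta_chain(data$y, codes, as.integer(n_levels), is_varying,
                           as.integer(iterations), as.integer(warmup),
                           spec$prior$sigma_rate, spec$prior$phi_shape,
                           spec$prior$phi_rate)
    draws[, ch, ] <- res$draws
    accept[ch] <- res$accept_rate
  }
  if (!all(is.finite(draws))) stop("sampler produced non-finite draws")
  structure(list(draws = draws, params = params, spec = spec,
                 levels = levels, accept_rate = accept,
                 chains = chains, iterations = iterations, warmup = warmup,
                 seed = as.integer(seed)),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("posterior_draws:", x$chains, "chains x", dim(x$draws)[1],
      "post-warmup iterations,", length(x$params), "parameters",
      "( fixed factor:", x$spec$fixed, ")\n")
  cat("  mean acceptance:", round(mean(x$accept_rate), 3), "\n")
  invisible(x)
}

#' Flatten posterior draws to a matrix
#'
#' @param fit A `posterior_draws` object.
#' @return A (chains * iterations) x parameters matrix.
#' @export
as_draws_matrix <- function(fit) {
  stopifnot(inherits(fit, "posterior_draws"))
  d <- fit$draws
  out <- matrix(d, nrow = dim(d)[1] * dim(d)[2], ncol = dim(d)[3])
  colnames(out) <- fit$params
  out
}

# S x N matrix of linear predictors for the fitted observation set
draw_eta <- function(fit, data) {
  dm <- as_draws_matrix(fit)
  eta <- matrix(dm[, "alpha"], nrow = nrow(dm), ncol = nrow(data))
  for (f in fit$spec$factors) {
    eff <- dm[, sprintf("a_%s[%s]", f, fit$levels[[f]]), drop = FALSE]
    code <- match(as.character(data[[f]]), fit$levels[[f]])
    if (anyNA(code)) {
      stop("data contain levels of '", f, "' absent from the fit")
    }
    eta <- eta + eff[, code, drop = FALSE]
  }
  eta
}

#' Pointwise posterior log-likelihood matrix
#'
#' @param fit A `posterior_draws` object.
#' @param data The `pair_obs` data frame the model was fitted to.
#' @return A draws x observations matrix of Beta log densities.
#' @export
pointwise_loglik <- function(fit, data) {
  check_pair_obs(data, fit$spec$factors)
  eta <- draw_eta(fit, data)
  phi <- as_draws_matrix(fit)[, "phi"]
  mu <- stats::plogis(eta)
  a <- mu * phi          # phi recycles down columns (one value per draw)
  b <- (1 - mu) * phi
  S <- nrow(mu); N <- ncol(mu)
  logy <- matrix(log(data$y), S, N, byrow = TRUE)
  log1my <- matrix(log1p(-data$y), S, N, byrow = TRUE)
  lgamma(phi) - lgamma(a) - lgamma(b) + (a - 1) * logy + (b - 1) * log1my
}
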