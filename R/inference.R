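#' Convergence diagnostics: split R-hat and effective sample size
#'
#' Split-chain R-hat (each chain halved, between/within variance ratio;
#' rank normalization off) and effective sample size from the averaged
#' per-chain autocovariance with Geyer initial-monotone-positive-sequence
#' truncation. A parameter that is constant across all draws gets `NA` for
#' both (flagged in the `constant` column) rather than a spurious value.
#'
#' @param fit A `posterior_draws` object, or a draws array
#'   (iterations x chains x parameters).
#' @return Data frame with columns `param`, `rhat`, `ess`, `constant`.
#' @export
diagnostics <- function(fit) {
  d <- if (inherits(fit, "posterior_draws")) fit$draws else fit
  stopifnot(length(dim(d)) == 3)
  if (dim(d)[2] < 2) stop("diagnostics require at least 2 chains")
  if (dim(d)[1] < 4) stop("diagnostics require at least 4 draws per chain")
  params <- dimnames(d)[[3]]
  if (is.null(params)) params <- paste0("param", seq_len(dim(d)[3]))
  out <- data.frame(param = params, rhat = NA_real_, ess = NA_real_,
                    constant = FALSE, stringsAsFactors = FALSE)
  for (p in seq_len(dim(d)[3])) {
    x <- d[, , p, drop = FALSE]
    dim(x) <- dim(d)[1:2]
    if (stats::var(as.vector(x)) < .Machine$double.eps) {
      out$constant[p] <- TRUE
      next
    }
    out$rhat[p] <- split_rhat(x)
    out$ess[p] <- ess_geyer(x)
  }
  out
}

# x: iterations x chains
split_rhat <- function(x) {
  n <- nrow(x)
  half <- n %/% 2
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub); nn <- nrow(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  B <- nn * stats::var(means)
  W <- mean(vars)
  if (W < .Machine$double.eps) return(NA_real_)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

ess_geyer <- function(x) {
  n <- nrow(x)
  half <- n %/% 2
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub); nn <- nrow(sub)
  vars <- apply(sub, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(colMeans(sub))
  var_plus <- (nn - 1) / nn * W + B / nn
  # averaged per-chain autocovariance
  acov <- sapply(seq_len(m), function(ch) {
    a <- stats::acf(sub[, ch], lag.max = nn - 1, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a * (nn - 1) / nn
  })
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus  # rho[1] is lag 0 (= ~1)
  # Geyer: sum consecutive autocorrelation pairs while positive, with the
  # initial monotone sequence enforced by a running minimum
  max_pairs <- length(rho) %/% 2
  pair_sums <- numeric(0)
  for (k in seq_len(max_pairs)) {
    ps <- rho[2 * k - 1] + rho[2 * k]
    if (ps <= 0) break
    pair_sums <- c(pair_sums, ps)
  }
  if (length(pair_sums) > 1) pair_sums <- cummin(pair_sums)
  tau <- max(-1 + 2 * sum(pair_sums), 1e-3)
  min(m * nn / tau, m * nn)
}

logcolmeanexp <- function(ll) {
  M <- apply(ll, 2, max)
  M + log(colMeans(exp(sweep(ll, 2, M))))
}

#' Watanabe-Akaike information criterion
#'
#' `lppd = sum_i log mean_s exp(loglik_si)`, `p_WAIC = sum_i var_s
#' (loglik_si)`, `WAIC = -2 (lppd - p_WAIC)`, computed with log-sum-exp
#' stabilization from the pointwise posterior log-likelihood. The variance
#' is the population variance over draws (divisor S), so duplicating every
#' draw leaves WAIC exactly unchanged and a single draw gives `p_WAIC = 0`.
#'
#' @param fit A `posterior_draws` object.
#' @param data The `pair_obs` data frame the model was fitted to.
#' @return A list of class `waic_result`: `waic`, `lppd`, `p_waic`, and the
#'   per-observation `pointwise` data frame (`lppd_i`, `p_i`, `waic_i`).
#' @export
waic <- function(fit, data) {
  ll <- pointwise_loglik(fit, data)
  if (!all(is.finite(ll))) {
    bad <- which(!apply(is.finite(ll), 2, all))
    stop("non-finite pointwise log-likelihood for observation(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  lppd_i <- logcolmeanexp(ll)
  p_i <- colMeans(sweep(ll, 2, colMeans(ll))^2)  # population variance
  waic_i <- -2 * (lppd_i - p_i)
  structure(list(waic = sum(waic_i), lppd = sum(lppd_i), p_waic = sum(p_i),
                 pointwise = data.frame(lppd_i = lppd_i, p_i = p_i,
                                        waic_i = waic_i)),
            class = "waic_result")
}

#' @export
print.waic_result <- function(x, ...) {
  cat("WAIC:", round(x$waic, 2), "( lppd", round(x$lppd, 2), ", p_waic",
      round(x$p_waic, 2), ")\n")
  invisible(x)
}

#' Bayesian R-squared
#'
#' Per posterior draw, the ratio of the variance of the modeled means to
#' that variance plus the mean residual (Beta) variance:
#' `R2_s = var_i(mu_si) / (var_i(mu_si) + mean_i(mu_si (1 - mu_si) /
#' (1 + phi_s)))`, summarized over draws. The reported `se` is the
#' posterior standard deviation of R2.
#'
#' @inheritParams waic
#' @return A list with `mean`, `se`, and the per-draw vector `draws`.
#' @export
bayes_r2 <- function(fit, data) {
  eta <- draw_eta(fit, data)
  phi <- as_draws_matrix(fit)[, "phi"]
  mu <- stats::plogis(eta)
  var_mu <- apply(mu, 1, stats::var)
  resid <- rowMeans(mu * (1 - mu)) / (1 + phi)
  r2 <- var_mu / (var_mu + resid)
  list(mean = mean(r2), se = stats::sd(r2), draws = r2)
}

#' Compare fitted models by WAIC
#'
#' Ranks a set of fits on the same observation set by WAIC and reports
#' `WAIC_delta` (difference to the best model) with its standard error
#' `SE(delta) = sqrt(n * var_i(waic_i^(A) - waic_i^(B)))` from the
#' pointwise WAIC contributions, plus Bayesian R-squared per model.
#'
#' @param fits Named list of `posterior_draws` objects.
#' @param data The common `pair_obs` data frame all models were fitted to.
#' @return A data frame of class `model_comparison` with one row per model,
#'   ordered by WAIC: columns `model`, `fixed`, `random`, `waic`,
#'   `waic_delta`, `se_waic_delta`, `r2`, `se_r2`.
#' @export
compare_models <- function(fits, data) {
  stopifnot(length(fits) >= 1)
  if (is.null(names(fits))) {
    names(fits) <- vapply(fits, function(f) f$spec$fixed, character(1))
  }
  n <- nrow(data)
  ws <- lapply(fits, waic, data = data)
  r2s <- lapply(fits, bayes_r2, data = data)
  totals <- vapply(ws, function(w) w$waic, numeric(1))
  best <- which.min(totals)
  rows <- lapply(seq_along(fits), function(k) {
    diff_i <- ws[[k]]$pointwise$waic_i - ws[[best]]$pointwise$waic_i
    data.frame(model = names(fits)[k],
               fixed = fits[[k]]$spec$fixed,
               random = paste(fits[[k]]$spec$varying, collapse = ","),
               waic = totals[k],
               waic_delta = totals[k] - totals[best],
               se_waic_delta = sqrt(n * stats::var(diff_i)),
               r2 = r2s[[k]]$mean, se_r2 = r2s[[k]]$se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$waic), ]
  rownames(out) <- NULL
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' Partition dissimilarity variance among the varying intercepts
#'
#' From an intercept-only fit (all four factors varying), summarizes the
#' posterior of each factor's logit-scale standard deviation and the
#' probability that each factor has the largest sigma, plus all pairwise
#' `Pr(sigma_a > sigma_b)`.
#'
#' @param fit A `posterior_draws` object fitted with `model_spec("none")`.
#' @return A list of class `variance_partition`: `summary` (per-factor
#'   mean/sd/2.5%/97.5%), `pr_largest`, `pr_greater` (matrix).
#' @export
variance_partition <- function(fit) {
  stopifnot(inherits(fit, "posterior_draws"))
  sig_names <- paste0("sigma_", model_factors)
  missing <- setdiff(sig_names, fit$params)
  if (length(missing)) {
    stop("fit lacks sigma parameter(s) ", paste(missing, collapse = ", "),
         "; variance_partition needs the intercept-only model")
  }
  dm <- as_draws_matrix(fit)[, sig_names, drop = FALSE]
  colnames(dm) <- model_factors
  summ <- data.frame(
    factor = model_factors,
    mean = colMeans(dm),
    sd = apply(dm, 2, stats::sd),
    q2.5 = apply(dm, 2, stats::quantile, 0.025),
    q97.5 = apply(dm, 2, stats::quantile, 0.975),
    row.names = NULL, stringsAsFactors = FALSE)
  largest <- apply(dm, 1, which.max)
  pr_largest <- vapply(seq_along(model_factors),
                       function(k) mean(largest == k), numeric(1))
  names(pr_largest) <- model_factors
  pr_greater <- matrix(NA_real_, 4, 4,
                       dimnames = list(model_factors, model_factors))
  for (a in model_factors) for (b in model_factors) {
    if (a != b) pr_greater[a, b] <- mean(dm[, a] > dm[, b])
  }
  structure(list(summary = summ, pr_largest = pr_largest,
                 pr_greater = pr_greater),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("Posterior variance partition (logit-scale sigma):\n")
  print(cbind(x$summary,
              pr_largest = unname(x$pr_largest[x$summary$factor])),
        digits = 3)
  invisible(x)
}

#' Posterior predictive mean dissimilarity for a group level
#'
#' For an observed level, summarizes `plogis(alpha + a_factor[level])` over
#' the posterior draws. For a hypothetical new level of a varying factor,
#' the effect is drawn `Normal(0, sigma_factor)` per draw, propagating the
#' between-level uncertainty so predictions for unseen groups are wider.
#'
#' @param fit A `posterior_draws` object.
#' @param factor One of `"family"`, `"genus"`, `"ffg"`, `"site"`.
#' @param level An observed level name, or `NULL` with `new_level = TRUE`.
#' @param new_level If `TRUE`, predict for an unobserved level.
#' @param seed Seed for the new-level effect draws.
#' @return A list with `mean`, `median`, `q2.5`, `q97.5`, and the per-draw
#'   vector `draws` (on the Bray-Curtis scale).
#' @export
predict_levels <- function(fit, factor, level = NULL, new_level = FALSE,
                           seed = 1) {
  stopifnot(inherits(fit, "posterior_draws"))
  if (!factor %in% model_factors) stop("unknown factor: ", factor)
  dm <- as_draws_matrix(fit)
  alpha <- dm[, "alpha"]
  if (new_level) {
    sig_name <- paste0("sigma_", factor)
    if (!sig_name %in% fit$params) {
      stop("new-level prediction needs '", factor, "' as a varying factor")
    }
    set.seed(as.integer(seed))
    eff <- stats::rnorm(length(alpha), 0, dm[, sig_name])
  } else {
    pname <- sprintf("a_%s[%s]", factor, level)
    if (!pname %in% fit$params) {
      stop("unknown level '", level, "' of factor '", factor, "'")
    }
    eff <- dm[, pname]
  }
  draws <- stats::plogis(alpha + eff)
  list(mean = mean(draws), median = stats::median(draws),
       q2.5 = unname(stats::quantile(draws, 0.025)),
       q97.5 = unname(stats::quantile(draws, 0.975)),
       draws = draws)
}
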