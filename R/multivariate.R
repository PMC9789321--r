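#' Non-metric multidimensional scaling
#'
#' Minimizes Kruskal stress-1 by monotone (isotonic) regression of
#' configuration distances on the input dissimilarity ranks, via
#' [vegan::monoMDS()] (global model, primary tie-breaking). One start is
#' initialized from classical scaling (principal coordinates) of the
#' dissimilarities; the remaining starts are random; the lowest-stress
#' solution is returned with centered coordinates.
#'
#' @param dm Labeled symmetric dissimilarity matrix.
#' @param k Number of ordination axes (default 2).
#' @param n_starts Number of starts including the classical-scaling start.
#' @param max_iter Maximum iterations per start.
#' @param tol Stress convergence ratio passed to the optimizer.
#' @param seed Integer seed for the random starts.
#' @return A list of class `ordination`: `points` (samples x k, column means
#'   zero), `stress`, `converged`, `n_starts`, `seed`.
#' @export
nmds <- function(dm, k = 2, n_starts = 10, max_iter = 200, tol = 1e-7,
                 seed = 1) {
  validate_distance_matrix(dm)
  n <- nrow(dm)
  if (n < k + 1) stop("need at least k + 1 = ", k + 1, " samples")
  d <- stats::as.dist(dm)
  set.seed(as.integer(seed))
  best <- NULL
  init <- cmdscale(d, k = k)
  if (ncol(init) < k) {  # degenerate input: pad with tiny jitter
    init <- cbind(init, matrix(stats::rnorm(n * (k - ncol(init)), 0, 1e-4),
                               nrow = n))
  }
  for (s in seq_len(n_starts)) {
    y0 <- if (s == 1) init else
      matrix(stats::rnorm(n * k), nrow = n) * stats::sd(dm)
    fit <- vegan::monoMDS(d, y = y0, k = k, model = "global",
                          maxit = max_iter, sratmax = 1 - tol)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  rownames(pts) <- rownames(dm)
  colnames(pts) <- paste0("NMDS", seq_len(k))
  structure(list(points = pts, stress = best$stress,
                 converged = best$icause == 3 || best$icause == 4,
                 n_starts = n_starts, seed = as.integer(seed)),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat("NMDS ordination:", nrow(x$points), "samples, k =", ncol(x$points),
      ", stress =", signif(x$stress, 4), "\n")
  invisible(x)
}

permanova_F <- function(D2, groups, n) {
  k <- nlevels(groups)
  ss_total <- sum(D2) / (2 * n)
  ss_within <- 0
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    ss_within <- ss_within + sum(D2[idx, idx]) / (2 * length(idx))
  }
  ((ss_total - ss_within) / (k - 1)) / (ss_within / (n - k))
}

# all distinct assignments of a label multiset to positions (groups are
# labeled, so equal-sized groups still yield distinct assignments)
enumerate_assignments <- function(groups, limit = 1e5) {
  groups <- as.factor(groups)
  n <- length(groups)
  sizes <- table(groups)
  n_assign <- exp(lgamma(n + 1) - sum(lgamma(sizes + 1)))
  if (n_assign > limit) {
    stop("exhaustive enumeration infeasible: ", round(n_assign),
         " assignments exceed limit ", limit)
  }
  levs <- levels(groups)
  out <- list()
  recurse <- function(assigned, remaining, li) {
    if (li == length(levs)) {
      assigned[remaining] <- levs[li]
      out[[length(out) + 1L]] <<- assigned
      return(invisible(NULL))
    }
    picks <- utils::combn(remaining, sizes[[li]], simplify = FALSE)
    for (p in picks) {
      a <- assigned
      a[p] <- levs[li]
      recurse(a, setdiff(remaining, p), li + 1L)
    }
  }
  recurse(character(n), seq_len(n), 1L)
  lapply(out, factor, levels = levs)
}

#' Permutational multivariate analysis of variance (one-way)
#'
#' Pseudo-F computed from squared dissimilarities:
#' `SS_total = sum_{i<j} d_ij^2 / n`, within-group sums analogous, and
#' `F = (SS_between / (k - 1)) / (SS_within / (n - k))`. The p-value comes
#' from random relabeling with the add-one estimator
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_permutations)`, or from exhaustive
#' enumeration of all distinct label assignments (`method = "exhaustive"`,
#' feasible for small n), in which case `p` is the exact proportion of
#' assignments with `F >= F_obs`.
#'
#' @param dm Labeled symmetric dissimilarity matrix.
#' @param groups Group labels in `rownames(dm)` order.
#' @param n_permutations Number of random permutations (sampled method).
#' @param seed Integer seed for the permutations.
#' @param method `"sampled"` or `"exhaustive"`.
#' @return A list of class `permutation_test`: `statistic`, `p`,
#'   `n_permutations`, `seed`, `group_sizes`, `method`.
#' @export
permanova <- function(dm, groups, n_permutations = 999, seed = 1,
                      method = c("sampled", "exhaustive")) {
  method <- match.arg(method)
  validate_distance_matrix(dm)
  groups <- droplevels(as.factor(as.character(groups)))
  n <- nrow(dm)
  stopifnot(length(groups) == n)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (nlevels(groups) >= n) stop("group sizes leave no within-group variation")
  D2 <- dm^2
  f_obs <- permanova_F(D2, groups, n)
  if (method == "exhaustive") {
    perms <- enumerate_assignments(groups)
    f_perm <- vapply(perms, function(g) permanova_F(D2, g, n), numeric(1))
    p <- mean(f_perm >= f_obs)
    n_perm <- length(perms)
  } else {
    set.seed(as.integer(seed))
    f_perm <- numeric(n_permutations)
    for (b in seq_len(n_permutations)) {
      f_perm[b] <- permanova_F(D2, sample(groups), n)
    }
    p <- (1 + sum(f_perm >= f_obs)) / (1 + n_permutations)
    n_perm <- n_permutations
  }
  structure(list(statistic = f_obs, p = p, n_permutations = n_perm,
                 seed = as.integer(seed),
                 group_sizes = table(groups), method = method,
                 permuted = f_perm),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat("permutation test: statistic =", signif(x$statistic, 4),
      ", p =", signif(x$p, 4), "(", x$n_permutations, "permutations )\n")
  invisible(x)
}

#' Homogeneity of multivariate dispersions (PERMDISP)
#'
#' Embeds the dissimilarities in principal-coordinate space
#' ([vegan::betadisper()], group centroids, with the standard correction
#' subtracting imaginary-axis contributions), computes each sample's
#' distance to its group centroid, and tests the one-way ANOVA F on those
#' distances by permutation of group labels. Singleton groups are excluded
#' with a warning before testing (their dispersion is undefined). When all
#' centroid distances are zero the F ratio is 0/0: the result is flagged
#' `degenerate` with `statistic = NaN` and `p = NA`.
#'
#' @inheritParams permanova
#' @return A `permutation_test` list, with an added `degenerate` flag and
#'   `excluded_groups`.
#' @export
permdisp <- function(dm, groups, n_permutations = 999, seed = 1) {
  validate_distance_matrix(dm)
  groups <- droplevels(as.factor(as.character(groups)))
  stopifnot(length(groups) == nrow(dm))
  sizes <- table(groups)
  singletons <- names(sizes)[sizes < 2]
  if (length(singletons)) {
    warning("excluding singleton group(s) from PERMDISP: ",
            paste(singletons, collapse = ", "))
    keep <- !(groups %in% singletons)
    if (sum(keep) == 0 || nlevels(droplevels(groups[keep])) < 2) {
      stop("fewer than 2 groups with >= 2 members; PERMDISP undefined")
    }
    dm <- dm[keep, keep, drop = FALSE]
    groups <- droplevels(groups[keep])
  }
  if (max(dm) < 1e-12) {
    # all samples coincident: every centroid distance is 0 and F is 0/0
    return(structure(list(statistic = NaN, p = NA_real_,
                          n_permutations = 0L, seed = as.integer(seed),
                          group_sizes = table(groups), method = "sampled",
                          degenerate = TRUE, excluded_groups = character(0)),
                     class = "permutation_test"))
  }
  mod <- vegan::betadisper(stats::as.dist(dm), groups, type = "centroid")
  dists <- mod$distances
  if (all(abs(dists) < 1e-12)) {
    return(structure(list(statistic = NaN, p = NA_real_,
                          n_permutations = 0L, seed = as.integer(seed),
                          group_sizes = table(groups), method = "sampled",
                          degenerate = TRUE, excluded_groups = singletons),
                     class = "permutation_test"))
  }
  set.seed(as.integer(seed))
  pt <- vegan::permutest(mod, permutations = n_permutations)
  tab <- pt$tab
  structure(list(statistic = tab$F[1], p = tab$`Pr(>F)`[1],
                 n_permutations = n_permutations, seed = as.integer(seed),
                 group_sizes = table(groups), method = "sampled",
                 degenerate = FALSE, excluded_groups = singletons),
            class = "permutation_test")
}

#' Indicator-taxon screening by Kruskal-Wallis with FDR control
#'
#' Tests each taxon's relative abundance across groups with [kw_test()],
#' adjusts raw p-values over all tested taxa by Benjamini-Hochberg, and
#' reports the significant set at `q <= q_threshold` along with per-group
#' mean relative abundances for the significant taxa. Constant-abundance
#' taxa get p = 1 by convention.
#'
#' @param table A [count_table()] (rarefied counts or relative abundances).
#' @param groups Group labels in sample order.
#' @param q_threshold BH-adjusted significance threshold (default 0.05).
#' @return A list of class `indicator_result`: `tests` (data frame with
#'   `taxon`, `H`, `p`, `q`), `significant`, `group_means` (significant
#'   taxa x groups mean relative abundance), `q_threshold`.
#' @export
indicator_kw <- function(table, groups, q_threshold = 0.05) {
  stopifnot(inherits(table, "count_table"))
  groups <- droplevels(as.factor(as.character(groups)))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  stopifnot(length(groups) == ncol(table$counts))
  rel <- sweep(table$counts, 2, colSums(table$counts), "/")
  res <- lapply(seq_len(nrow(rel)), function(i) {
    kt <- kw_test(rel[i, ], groups)
    data.frame(taxon = rownames(rel)[i], H = kt$statistic, p = kt$p,
               stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, res)
  tests$q <- stats::p.adjust(tests$p, method = "BH")
  sig <- tests$taxon[tests$q <= q_threshold]
  group_means <- NULL
  if (length(sig)) {
    group_means <- t(apply(rel[sig, , drop = FALSE], 1, function(x) {
      tapply(x, groups, mean)
    }))
    colnames(group_means) <- levels(groups)
  }
  structure(list(tests = tests, significant = sig,
                 group_means = group_means, q_threshold = q_threshold),
            class = "indicator_result")
}

#' @export
print.indicator_result <- function(x, ...) {
  cat("indicator screen:", nrow(x$tests), "taxa tested,",
      length(x$significant), "significant at q <=", x$q_threshold, "\n")
  invisible(x)
}
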