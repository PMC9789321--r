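#' Per-sample alpha diversity indices
#'
#' Computes, for each sample: observed taxa (count with abundance > 0),
#' bias-corrected Chao1 richness `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` with
#' `F1`/`F2` the singleton/doubleton counts, Shannon diversity in bits
#' (`H = -sum p log2 p`), and Pielou-style evenness `H / log2(S_obs)`
#' (defined as 1 when a single taxon is present).
#'
#' @param table A [count_table()].
#' @return A data frame with one row per sample and columns `sample_id`,
#'   `observed`, `chao1`, `shannon`, `evenness`.
#' @export
alpha_diversity <- function(table) {
  stopifnot(inherits(table, "count_table"), ncol(table$counts) >= 1)
  zero <- colSums(table$counts) == 0
  if (any(zero)) {
    stop("all-zero sample(s): ",
         paste(colnames(table$counts)[zero], collapse = ", "))
  }
  res <- lapply(seq_len(ncol(table$counts)), function(j) {
    x <- table$counts[, j]
    x <- x[x > 0]
    s_obs <- length(x)
    f1 <- sum(x == 1)
    f2 <- sum(x == 2)
    chao1 <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
    h <- unname(vegan::diversity(x, index = "shannon", base = 2))
    evenness <- if (s_obs == 1) 1 else h / log2(s_obs)
    data.frame(observed = s_obs, chao1 = chao1, shannon = h,
               evenness = evenness)
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(sample_id = colnames(table$counts),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis rank-sum test
#'
#' Rank-based H statistic with tie correction and a chi-square reference
#' distribution on k - 1 degrees of freedom (the k-group generalization of
#' the two-group Wilcoxon test). The degenerate case in which every value
#' is identical (tie correction 0/0) is defined as H = 0, p = 1.
#'
#' @param values Numeric vector, one value per sample.
#' @param groups Group labels, same length as `values`.
#' @return A list with `statistic` (H), `p`, and `df`.
#' @export
kw_test <- function(values, groups) {
  if (!is.factor(groups)) groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) stop("kw_test needs at least 2 groups")
  if (any(table(groups) == 0)) stop("a group has zero observations")
  if (length(unique(values)) == 1L) {
    return(list(statistic = 0, p = 1, df = nlevels(groups) - 1L))
  }
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d_ij = 1 - 2 sum_t min(x_it, x_jt) / (sum_t x_it + sum_t x_jt)`,
#' computed with [vegan::vegdist()] and returned as a labeled symmetric
#' matrix with zero diagonal.
#'
#' @param table A [count_table()] with at least two samples.
#' @return A symmetric numeric matrix of pairwise dissimilarities in
#'   `[0, 1]`.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "count_table"))
  if (ncol(table$counts) < 2) stop("need at least 2 samples")
  zero <- colSums(table$counts) == 0
  if (any(zero)) {
    stop("all-zero sample(s): ",
         paste(colnames(table$counts)[zero], collapse = ", "))
  }
  m <- as.matrix(vegan::vegdist(t(table$counts), method = "bray"))
  diag(m) <- 0
  validate_distance_matrix(m, tol = 1e-8)
  m
}

#' Average alpha-diversity tables over rarefaction replicates
#'
#' Element-wise mean of the index columns across replicate tables, with the
#' replicate standard deviation reported alongside.
#'
#' @param alphas List of data frames from [alpha_diversity()], one per
#'   rarefaction replicate, sharing the same sample set.
#' @return A data frame of per-sample means with `<index>_sd` columns.
#' @export
aggregate_alpha <- function(alphas) {
  stopifnot(length(alphas) >= 1)
  ids <- alphas[[1]]$sample_id
  for (a in alphas) {
    if (!identical(a$sample_id, ids)) stop("replicates have mismatched samples")
  }
  idx <- c("observed", "chao1", "shannon", "evenness")
  arr <- sapply(alphas, function(a) as.matrix(a[, idx]), simplify = "array")
  out <- data.frame(sample_id = ids, apply(arr, c(1, 2), mean))
  sds <- apply(arr, c(1, 2), stats::sd)
  colnames(sds) <- paste0(idx, "_sd")
  cbind(out, sds)
}

#' Average distance matrices over rarefaction replicates
#'
#' @param dms List of labeled distance matrices sharing a sample set.
#' @return A list with `mean` (still a valid distance matrix) and `sd`
#'   (element-wise replicate standard deviation).
#' @export
aggregate_distance <- function(dms) {
  stopifnot(length(dms) >= 1)
  ids <- rownames(dms[[1]])
  for (d in dms) {
    if (!identical(rownames(d), ids)) stop("replicates have mismatched samples")
  }
  arr <- simplify2array(dms)
  m <- apply(arr, c(1, 2), mean)
  s <- apply(arr, c(1, 2), stats::sd)
  dimnames(m) <- dimnames(s) <- dimnames(dms[[1]])
  validate_distance_matrix(m)
  list(mean = m, sd = s)
}

#' Alpha diversity group tests across metadata variables
#'
#' Runs [kw_test()] for each alpha-diversity index against each grouping
#' variable (site, order, family, genus, FFG by default).
#'
#' @param alpha Data frame from [alpha_diversity()] or [aggregate_alpha()].
#' @param metadata A `sample_metadata` data frame covering the samples.
#' @param vars Grouping variables to test.
#' @return A data frame with columns `variable`, `index`, `chisq`, `df`, `p`.
#' @export
alpha_group_tests <- function(alpha, metadata,
                              vars = c("site", "order", "family", "genus",
                                       "ffg")) {
  md <- metadata[match(alpha$sample_id, metadata$sample_id), ]
  if (anyNA(md$sample_id)) stop("metadata does not cover all samples")
  rows <- list()
  for (v in vars) {
    g <- if (v == "genus") genus_levels(md) else md[[v]]
    for (idx in c("observed", "chao1", "shannon", "evenness")) {
      kt <- kw_test(alpha[[idx]], g)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, index = idx, chisq = kt$statistic, df = kt$df,
        p = kt$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
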