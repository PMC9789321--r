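lineage_ranks <- c("domain", "phylum", "class", "order", "family", "genus",
                   "species")

unassigned_tokens <- c("", "unassigned", "unclassified", "na", "none",
                       "unknown")

split_lineage <- function(lineage) {
  toks <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
  toks[tolower(toks) %in% unassigned_tokens] <- NA_character_
  toks
}

#' Curate an ASV count table
#'
#' Applies the two curation rules used before any community analysis: taxa
#' whose domain rank is unassigned are removed, taxa assigned to Eukaryota
#' are removed, and then samples whose remaining total falls below
#' `min_reads` are removed. The removal log is attached as attribute
#' `"removal"` (elements `taxa_removed`, `samples_removed`).
#'
#' @param table A [count_table()] with taxonomy attached.
#' @param min_reads Minimum per-sample read total to retain (default 1000).
#' @return The curated [count_table()].
#' @export
curate_table <- function(table, min_reads = 1000) {
  stopifnot(inherits(table, "count_table"))
  if (is.null(table$taxonomy)) {
    stop("curate_table requires taxonomy to identify domains")
  }
  domain <- vapply(table$taxonomy, function(l) split_lineage(l)[1],
                   character(1))
  drop_taxa <- is.na(domain) |
    tolower(domain) %in% c("eukaryota", "eukaryotes", "eukarya")
  kept <- table$counts[!drop_taxa, , drop = FALSE]
  totals <- colSums(kept)
  drop_samples <- totals < min_reads
  if (all(drop_samples)) {
    stop("curation removed every sample (all totals < ", min_reads, " reads)")
  }
  out <- count_table(kept[, !drop_samples, drop = FALSE],
                     table$taxonomy[!drop_taxa])
  attr(out, "removal") <- list(
    taxa_removed = rownames(table$counts)[drop_taxa],
    samples_removed = colnames(table$counts)[drop_samples])
  out
}

#' Collapse a count table to a taxonomic rank
#'
#' Sums counts over taxa sharing the full lineage prefix down to `rank`.
#' Taxa unassigned at `rank` are grouped under a
#' `"<deepest assigned lineage>;unclassified"` key, so reads unassigned at
#' the family level under different orders are never merged together.
#'
#' @param table A [count_table()] with taxonomy attached.
#' @param rank Target rank, one of the lineage schema
#'   (domain..species); default `"family"`.
#' @return A [count_table()] keyed by collapsed lineage.
#' @export
collapse_to_rank <- function(table, rank = "family") {
  stopifnot(inherits(table, "count_table"))
  if (is.null(table$taxonomy)) stop("collapse_to_rank requires taxonomy")
  ri <- match(rank, lineage_ranks)
  if (is.na(ri)) {
    stop("unknown rank '", rank, "'; expected one of: ",
         paste(lineage_ranks, collapse = ", "))
  }
  keys <- vapply(table$taxonomy, function(l) {
    toks <- split_lineage(l)
    toks <- toks[seq_len(min(ri, length(toks)))]
    if (length(toks) < ri || anyNA(toks)) {
      first_na <- which(is.na(toks))
      deepest <- if (length(first_na)) first_na[1] - 1L else length(toks)
      if (deepest == 0L) return("unclassified")
      paste(c(toks[seq_len(deepest)], "unclassified"), collapse = ";")
    } else {
      paste(toks, collapse = ";")
    }
  }, character(1))
  agg <- rowsum(table$counts, group = keys, reorder = TRUE)
  count_table(agg, stats::setNames(rownames(agg), rownames(agg)))
}

#' Rarefy a count table with replication
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric, via [vegan::rrarefy()]) to a common depth, independently
#' in each replicate. Samples whose total is below `depth` are dropped and
#' listed. Replicate `r` uses seed `seed + r`, so any replicate can be
#' regenerated on its own.
#'
#' @param table A [count_table()].
#' @param depth Target reads per sample (default 1110).
#' @param replicates Number of rarefaction replicates (default 10).
#' @param seed Integer base seed.
#' @return A list of class `rarefaction_result`: `depth`, `replicates`
#'   (list of [count_table()]), `dropped_samples`, `seed`.
#' @export
rarefy <- function(table, depth = 1110, replicates = 10, seed = 1) {
  stopifnot(inherits(table, "count_table"), depth >= 1, replicates >= 1)
  totals <- colSums(table$counts)
  keep <- totals >= depth
  if (!any(keep)) {
    stop("rarefaction depth ", depth, " exceeds every sample total (max ",
         max(totals), ")")
  }
  kept <- table$counts[, keep, drop = FALSE]
  reps <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    set.seed(as.integer(seed) + r)
    # rrarefy warns when the smallest count is large (suspecting normalized
    # data); our inputs are validated integer counts, so muffle that one
    sub <- withCallingHandlers(
      t(vegan::rrarefy(t(kept), depth)),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    reps[[r]] <- count_table(sub, table$taxonomy)
  }
  structure(list(depth = depth, replicates = reps,
                 dropped_samples = colnames(table$counts)[!keep],
                 seed = as.integer(seed)),
            class = "rarefaction_result")
}

#' @export
print.rarefaction_result <- function(x, ...) {
  cat("rarefaction_result: depth", x$depth, "x", length(x$replicates),
      "replicates;", length(x$dropped_samples), "sample(s) dropped\n")
  invisible(x)
}
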