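#' Controlled vocabulary of functional feeding groups
#'
#' The five functional feeding group (FFG) designations used for freshwater
#' macroinvertebrates: classification of taxa by how they acquire food
#' (filtering suspended particles, gathering deposited particles, scraping
#' biofilm, predation, shredding coarse detritus).
#'
#' @return Character vector of the five canonical FFG labels (lower case).
#' @export
ffg_vocabulary <- function() {
  c("filtering collectors", "gathering collectors", "scrapers",
    "predators", "shredder/detritivore")
}

#' Normalize functional feeding group labels
#'
#' Lower-cases, trims and collapses whitespace, then applies an optional
#' synonym map before checking membership in [ffg_vocabulary()].
#'
#' @param x Character vector of raw FFG labels.
#' @param synonyms Optional named character vector mapping normalized
#'   non-canonical labels to canonical ones, e.g.
#'   `c("shredders" = "shredder/detritivore")`.
#' @return Character vector of canonical FFG labels.
#' @export
normalize_ffg <- function(x, synonyms = NULL) {
  out <- tolower(trimws(gsub("[[:space:]]+", " ", x)))
  if (!is.null(synonyms)) {
    names(synonyms) <- tolower(trimws(names(synonyms)))
    hit <- out %in% names(synonyms)
    out[hit] <- unname(synonyms[out[hit]])
  }
  bad <- !is.na(out) & !(out %in% ffg_vocabulary())
  if (any(bad)) {
    stop("unknown functional feeding group label(s) after normalization: ",
         paste(unique(x[bad]), collapse = ", "),
         " (rows ", paste(which(bad), collapse = ", "), ")")
  }
  out
}

metadata_columns <- c("sample_id", "order", "family", "genus", "site", "ffg")

validate_metadata <- function(md) {
  stopifnot(is.data.frame(md))
  missing_cols <- setdiff(metadata_columns, names(md))
  if (length(missing_cols)) {
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  dup <- md$sample_id[duplicated(md$sample_id)]
  if (length(dup)) {
    stop("duplicated sample_id: ", paste(unique(dup), collapse = ", "))
  }
  for (col in c("sample_id", "order", "family", "site")) {
    if (any(is.na(md[[col]]) | md[[col]] == "")) {
      stop("empty or missing values in required metadata column '", col, "'")
    }
  }
  invisible(md)
}

#' Read a sample metadata table
#'
#' Reads a tab-separated metadata table with columns `sample_id`, `order`,
#' `family`, `genus`, `site`, `ffg` (UTF-8, `#` comment lines ignored).
#' FFG labels are normalized via [normalize_ffg()]; a literal `"NA"` (or
#' empty) genus is parsed as missing, mirroring metadata tables in which
#' specimens were identified only to family.
#'
#' @param path Path to the TSV file.
#' @param ffg_synonyms Optional synonym map passed to [normalize_ffg()].
#' @return A `data.frame` of class `sample_metadata`.
#' @export
read_metadata <- function(path, ffg_synonyms = NULL) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  md <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = "character", na.strings = c("NA", ""),
                          fileEncoding = "UTF-8", check.names = FALSE)
  md <- as.data.frame(md, stringsAsFactors = FALSE)
  validate_metadata(md)
  md$ffg <- normalize_ffg(md$ffg, ffg_synonyms)
  md <- md[, metadata_columns]
  class(md) <- c("sample_metadata", "data.frame")
  md
}

#' Write a sample metadata table
#'
#' @param metadata A `sample_metadata` data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  validate_metadata(metadata)
  out <- metadata
  out$genus[is.na(out$genus)] <- "NA"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Family-scoped genus labels
#'
#' Genus labels made unique within host family: a named genus becomes
#' `"<family>/<genus>"` and a missing genus becomes the family-scoped
#' placeholder `"<family>:unknown"`. This respects the nesting of genus
#' within family (the same genus name can never span two families) and lets
#' family-only identifications participate as their own level.
#'
#' @param metadata A `sample_metadata` data frame.
#' @param qualify If `TRUE` (default), prefix named genera with their family.
#' @return Character vector of genus levels, one per sample.
#' @export
genus_levels <- function(metadata, qualify = TRUE) {
  ifelse(is.na(metadata$genus),
         paste0(metadata$family, ":unknown"),
         if (qualify) paste0(metadata$family, "/", metadata$genus)
         else metadata$genus)
}

#' Summarize sample metadata
#'
#' Counts samples per level of each grouping variable (site, order, family,
#' genus, FFG) and the number of distinct levels of each. Missing genera are
#' counted under their family-scoped placeholder (`"<family>:unknown"`) and
#' also reported separately as `n_missing_genus`.
#'
#' @param metadata A `sample_metadata` data frame.
#' @return A list of class `metadata_summary` with per-variable count tables
#'   and distinct-level totals.
#' @export
summarize_metadata <- function(metadata) {
  validate_metadata(metadata)
  if (nrow(metadata) == 0L) stop("metadata is empty")
  tab <- function(x) {
    t <- table(x)
    sort(stats::setNames(as.integer(t), names(t)), decreasing = TRUE)
  }
  genus_all <- genus_levels(metadata, qualify = FALSE)
  out <- list(
    n_samples = nrow(metadata),
    samples_per_site   = tab(metadata$site),
    samples_per_order  = tab(metadata$order),
    samples_per_family = tab(metadata$family),
    samples_per_genus  = tab(genus_all),
    samples_per_ffg    = tab(metadata$ffg),
    n_missing_genus    = sum(is.na(metadata$genus)),
    n_sites    = length(unique(metadata$site)),
    n_orders   = length(unique(metadata$order)),
    n_families = length(unique(metadata$family)),
    n_genera   = length(unique(genus_all)),
    n_named_genera = length(unique(metadata$genus[!is.na(metadata$genus)])),
    n_ffgs     = length(unique(metadata$ffg))
  )
  class(out) <- "metadata_summary"
  out
}

#' @export
print.metadata_summary <- function(x, ...) {
  cat("Sample metadata summary\n")
  cat("  samples:", x$n_samples, "\n")
  cat("  sites:", x$n_sites, " orders:", x$n_orders,
      " families:", x$n_families, " genera:", x$n_genera,
      "(", x$n_named_genera, "named +", x$n_missing_genus,
      "family-only records ) ffgs:", x$n_ffgs, "\n")
  invisible(x)
}

# ---- count tables -----------------------------------------------------------

#' Construct a count table
#'
#' A samples-by-taxa abundance container stored as a taxa x samples integer
#' matrix (rows = taxa, QIIME orientation) with an optional taxonomy lineage
#' per taxon (semicolon-delimited, domain..genus).
#'
#' @param counts Non-negative integer matrix, taxa in rows, samples in
#'   columns, both with unique dimnames.
#' @param taxonomy Optional named character vector of semicolon-delimited
#'   lineages, names matching `rownames(counts)`.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must have taxon rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicated taxon ids")
  if (anyDuplicated(colnames(counts))) stop("duplicated sample ids")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop("counts must be non-negative integers; offending cell(s): ",
         paste(sprintf("[%s, %s]", rownames(counts)[bad[, 1]],
                       colnames(counts)[bad[, 2]]), collapse = ", "))
  }
  storage.mode(counts) <- "double"
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[rownames(counts)]
    if (any(is.na(names(taxonomy))) || any(is.na(taxonomy))) {
      stop("taxonomy must cover every taxon id in the count matrix")
    }
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "taxa x", ncol(x$counts), "samples;",
      if (is.null(x$taxonomy)) "no taxonomy" else "taxonomy attached", "\n")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

sample_ids <- function(x) colnames(x$counts)
taxon_ids <- function(x) rownames(x$counts)

#' Read a count table (TSV or BIOM-style JSON)
#'
#' TSV dialect: first column taxon id, remaining columns one per sample,
#' optional trailing `taxonomy` column with a semicolon-delimited lineage;
#' `#` comment lines ignored. The JSON dialect is minimal BIOM 1.0: `shape`,
#' row/column ids, sparse `[row, col, value]` data triples, and an optional
#' per-row `metadata$taxonomy` lineage.
#'
#' @param path Input path.
#' @param format `"tsv"` or `"biom-json"`.
#' @return A [count_table()].
#' @export
read_count_table <- function(path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("count table file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                            check.names = FALSE, fileEncoding = "UTF-8")
    taxa <- as.character(df[[1]])
    taxonomy <- NULL
    if ("taxonomy" %in% names(df)) {
      taxonomy <- stats::setNames(as.character(df$taxonomy), taxa)
      df$taxonomy <- NULL
    }
    mat <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(mat)) stop("non-numeric count cells in ", path)
    rownames(mat) <- taxa
    count_table(mat, taxonomy)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    shape <- unlist(obj$shape)
    if (length(shape) != 2) stop("BIOM-style JSON lacks a valid 'shape'")
    taxa <- vapply(obj$rows, function(r) r$id, character(1))
    samples <- vapply(obj$columns, function(cc) cc$id, character(1))
    if (length(taxa) != shape[1] || length(samples) != shape[2]) {
      stop("BIOM-style JSON shape does not match row/column ids")
    }
    mat <- matrix(0, nrow = shape[1], ncol = shape[2],
                  dimnames = list(taxa, samples))
    for (trip in obj$data) {
      i <- trip[[1]] + 1L; j <- trip[[2]] + 1L
      mat[i, j] <- trip[[3]]
    }
    taxonomy <- NULL
    lineages <- lapply(obj$rows, function(r) r$metadata$taxonomy)
    if (!all(vapply(lineages, is.null, logical(1)))) {
      taxonomy <- stats::setNames(
        vapply(lineages, function(l) paste(unlist(l), collapse = ";"),
               character(1)), taxa)
    }
    count_table(mat, taxonomy)
  }
}

#' Write a count table (TSV or BIOM-style JSON)
#'
#' @param x A [count_table()].
#' @param path Output path.
#' @param format `"tsv"` or `"biom-json"`.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "count_table"))
  if (format == "tsv") {
    df <- data.frame(taxon_id = rownames(x$counts), x$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    if (!is.null(x$taxonomy)) df$taxonomy <- unname(x$taxonomy)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  } else {
    nz <- which(x$counts != 0, arr.ind = TRUE)
    data_triples <- lapply(seq_len(nrow(nz)), function(k) {
      list(nz[k, 1] - 1L, nz[k, 2] - 1L, x$counts[nz[k, 1], nz[k, 2]])
    })
    rows <- lapply(rownames(x$counts), function(id) {
      md <- NULL
      if (!is.null(x$taxonomy)) {
        lineage <- x$taxonomy[[id]]
        toks <- strsplit(lineage, ";", fixed = TRUE)[[1]]
        n_fields <- sum(charToRaw(lineage) == charToRaw(";")) + 1L
        toks <- c(toks, rep("", n_fields - length(toks)))  # trailing blanks
        md <- list(taxonomy = as.list(toks))
      }
      list(id = id, metadata = md)
    })
    cols <- lapply(colnames(x$counts), function(id) list(id = id, metadata = NULL))
    obj <- list(
      id = "streamgut count table",
      format = "Biological Observation Matrix 1.0.0",
      format_url = "http://biom-format.org",
      type = "OTU table",
      generated_by = paste0("streamgut ",
                            as.character(utils::packageVersion("streamgut"))),
      date = "1970-01-01T00:00:00",
      matrix_type = "sparse",
      matrix_element_type = "int",
      shape = dim(x$counts),
      rows = rows,
      columns = cols,
      data = data_triples
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read / write a taxonomy table
#'
#' Two-column TSV: taxon id and a semicolon-delimited lineage
#' (domain;phylum;class;order;family;genus, deeper ranks optional).
#'
#' @param path TSV path.
#' @return Named character vector of lineages.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = "character", fileEncoding = "UTF-8")
  stats::setNames(df[[2]], df[[1]])
}

#' @rdname read_taxonomy
#' @param taxonomy Named character vector of lineages.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(
    data.frame(taxon_id = names(taxonomy), lineage = unname(taxonomy)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# ---- distance matrices ------------------------------------------------------

validate_distance_matrix <- function(m, tol = 1e-9) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m))) {
    stop("distance matrix row and column labels must match")
  }
  if (max(abs(m - t(m))) > tol) stop("distance matrix is not symmetric")
  if (any(abs(diag(m)) > tol)) stop("distance matrix diagonal must be zero")
  if (any(m < -tol) || any(m > 1 + tol)) {
    stop("dissimilarities must lie in [0, 1]")
  }
  invisible(m)
}

#' Write / read a labeled square distance matrix as TSV
#'
#' Lossless round trip at >= 12 significant digits; the reader rejects
#' asymmetric matrices (|d_ij - d_ji| > 1e-9) and mismatched labels.
#'
#' @param dm Symmetric numeric matrix with matching row/column names.
#' @param path TSV path.
#' @return `path` invisibly (write); the matrix (read).
#' @export
write_distance_matrix <- function(dm, path) {
  validate_distance_matrix(dm)
  df <- data.frame(sample_id = rownames(dm),
                   formatC(dm, format = "g", digits = 15),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", colnames(dm))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, fileEncoding = "UTF-8")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  validate_distance_matrix(m)
  m
}
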