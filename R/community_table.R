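#' Validate a community table
#'
#' A community table is a plain integer matrix of read counts with samples as
#' rows and ASVs as columns, both axes carrying unique identifiers as
#' dimnames. This is the vegan-style representation used throughout the
#' package.
#'
#' @param x matrix to validate.
#' @param allow_zero_samples keep samples whose row sum is zero (default
#'   `FALSE`: an all-zero sample is an error, since every downstream metric is
#'   undefined for it).
#' @return `x`, invisibly, with integer storage mode.
#' @export
validate_community_table <- function(x, allow_zero_samples = FALSE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("community table must be a numeric matrix (samples x ASVs)")
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("community table needs at least one sample and one ASV")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("community table must carry sample ids (rownames) and ASV ids (colnames)")
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate ASV ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (anyNA(x) || any(x < 0))
    stop("community table counts must be non-negative and non-missing")
  if (any(abs(x - round(x)) > 1e-8))
    stop("community table counts must be integers (read counts)")
  if (!allow_zero_samples && any(rowSums(x) == 0))
    stop("all-zero sample(s): ",
         paste(rownames(x)[rowSums(x) == 0], collapse = ", "))
  storage.mode(x) <- "integer"
  invisible(x)
}

#' Read a community composition table from delimited text
#'
#' Reads a TSV (or other delimited) export of a samples x ASVs read-count
#' table. Trailing non-numeric columns -- the taxonomy strings that
#' BIOM-style exports append after the counts -- are split off into a
#' separate taxonomy data frame, never mixed into the counts.
#'
#' Orientation is auto-detected: when a phylogeny is supplied, the axis whose
#' labels overlap the tree's tips is taken as the ASV axis; otherwise rows
#' are assumed to be samples (amplicon studies have few samples and many
#' ASVs, so a table with more rows than columns triggers a message).
#'
#' @param path path to the delimited file; first column holds row identifiers.
#' @param orientation `"auto"`, `"samples_as_rows"` or `"samples_as_columns"`.
#' @param tree optional `phylo` used by `"auto"` to identify the ASV axis.
#' @param sep field separator (default tab).
#' @return list with components `counts` (integer matrix, samples x ASVs) and
#'   `taxonomy` (`NULL`, or a data frame with column `asv_id` followed by the
#'   trailing text columns).
#' @export
read_community_table <- function(path, orientation = c("auto", "samples_as_rows",
                                                       "samples_as_columns"),
                                 tree = NULL, sep = "\t") {
  orientation <- match.arg(orientation)
  raw <- read.delim(path, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (ncol(raw) < 2L) stop("expected an id column plus at least one data column in ", path)
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate row identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- raw[-1L]

  is_num <- vapply(body, function(col) {
    if (is.numeric(col)) return(TRUE)
    suppressWarnings(all(!is.na(as.numeric(col[!is.na(col) & col != ""]))))
  }, logical(1L))

  # taxonomy = maximal block of trailing non-numeric columns
  n_tax <- 0L
  while (n_tax < length(is_num) && !is_num[length(is_num) - n_tax]) n_tax <- n_tax + 1L
  if (any(!is_num[seq_len(length(is_num) - n_tax)])) {
    bad <- names(body)[!is_num & seq_along(is_num) <= length(is_num) - n_tax]
    stop("non-numeric count column(s) not in a trailing taxonomy block: ",
         paste(bad, collapse = ", "))
  }

  taxonomy <- NULL
  if (n_tax > 0L) {
    tax_cols <- body[(length(body) - n_tax + 1L):length(body)]
    taxonomy <- data.frame(asv_id = ids, tax_cols,
                           check.names = FALSE, stringsAsFactors = FALSE)
    body <- body[seq_len(length(body) - n_tax)]
    if (length(body) == 0L) stop("no numeric count columns found in ", path)
  }

  counts <- as.matrix(data.frame(lapply(body, as.numeric), check.names = FALSE))
  dimnames(counts) <- list(ids, names(body))
  if (anyNA(counts) || any(counts < 0)) {
    bad <- which(is.na(counts) | counts < 0, arr.ind = TRUE)[1L, ]
    stop("negative or non-numeric count at row '", rownames(counts)[bad[1L]],
         "', column '", colnames(counts)[bad[2L]], "'")
  }

  flip <- switch(orientation,
    samples_as_rows    = FALSE,
    samples_as_columns = TRUE,
    auto = {
      if (!is.null(tree)) {
        tips <- tree$tip.label
        row_hits <- mean(rownames(counts) %in% tips)
        col_hits <- mean(colnames(counts) %in% tips)
        if (row_hits > col_hits) TRUE else FALSE   # ASVs on rows -> transpose
      } else {
        if (nrow(counts) > ncol(counts))
          message("orientation 'auto' without a tree: assuming samples as rows (",
                  nrow(counts), " rows > ", ncol(counts), " columns)")
        FALSE
      }
    })
  if (flip) counts <- t(counts)

  validate_community_table(counts, allow_zero_samples = TRUE)
  storage.mode(counts) <- "integer"
  list(counts = counts, taxonomy = taxonomy)
}

#' Write a community table as TSV
#'
#' @param x community table (samples x ASVs integer matrix).
#' @param path output path.
#' @export
write_community_table <- function(x, path) {
  validate_community_table(x, allow_zero_samples = TRUE)
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (transect positions)
#'
#' Expects a TSV with columns `sample_id` and `position_m` (metres along the
#' transect).
#'
#' @param path input path.
#' @return data frame with columns `sample_id` (character) and `position_m`
#'   (numeric).
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "position_m") %in% names(df)))
    stop("metadata must have columns 'sample_id' and 'position_m'")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  if (anyNA(df$position_m) || any(!is.finite(df$position_m)))
    stop("missing or non-finite position_m in metadata")
  df[c("sample_id", "position_m")]
}

#' Read a taxonomy table
#'
#' One row per ASV; first column the ASV id, remaining columns the ranked
#' lineage (kingdom ... genus). Empty cells mean unclassified at that rank.
#'
#' @param path input path.
#' @return data frame whose first column is `asv_id`.
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[1L] <- "asv_id"
  df$asv_id <- as.character(df$asv_id)
  if (anyDuplicated(df$asv_id)) stop("duplicate asv_id in taxonomy table")
  df
}

#' Write / read a labelled square distance matrix
#'
#' The on-disk form is a square TSV with matching row and column labels.
#' Read-back reproduces the matrix to better than 1e-9.
#'
#' @param dm a `dist` object or labelled symmetric matrix with zero diagonal.
#' @param path file path.
#' @return `write_distance_matrix` returns the path invisibly;
#'   `read_distance_matrix` returns a `dist` object.
#' @export
write_distance_matrix <- function(dm, path) {
  m <- as.matrix(dm)
  if (is.null(rownames(m))) stop("distance matrix must be labelled")
  if (!isSymmetric(unname(m), tol = 1e-12)) stop("distance matrix must be symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  if (anyNA(m) || any(!is.finite(m)) || any(m < 0))
    stop("distances must be finite and non-negative")
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1L]])
  m <- as.matrix(df[-1L])
  dimnames(m) <- list(labels, colnames(df)[-1L])
  if (!identical(rownames(m), colnames(m)))
    stop("row and column labels disagree in ", path)
  stats::as.dist(m)
}

#' Write a tabular result report as TSV
#'
#' Thin wrapper used for SES tables, alpha-diversity tables and partition
#' files so every report shares one dialect (tab-separated, no quoting, no
#' row names).
#'
#' @param results a data frame.
#' @param path output path.
#' @export
write_report <- function(results, path) {
  stopifnot(is.data.frame(results))
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
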