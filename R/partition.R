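#' Rare/abundant partition of one sample by read-count quartiles
#'
#' For a single site, the first and third quartiles of the distribution of
#' its nonzero ASV read counts (ordered low to high) define the thresholds:
#' rare ASVs have counts at or below Q1, abundant ASVs at or above Q3 (ties
#' included on both sides). Quartiles use the nearest-rank estimator by
#' default, so the thresholds are observed integer read counts; the
#' interpolating type-7 estimator is available for sensitivity checks.
#'
#' @param table community table.
#' @param sample_id which sample to partition.
#' @param method `"nearest_rank"` (default) or `"type7"`.
#' @return list of class `subcommunity_partition`: `sample_id`,
#'   `q1_threshold`, `q3_threshold`, `rare_asvs`, `abundant_asvs`,
#'   `degenerate` (TRUE when Q1 == Q3, in which case the two sets overlap
#'   and a warning is raised).
#' @export
quartile_partition <- function(table, sample_id,
                               method = c("nearest_rank", "type7")) {
  method <- match.arg(method)
  validate_community_table(table)
  if (!sample_id %in% rownames(table)) stop("unknown sample ", sample_id)
  counts <- table[sample_id, ]
  nz <- counts[counts > 0]
  if (length(nz) < 4L)
    stop("sample ", sample_id, " has ", length(nz),
         " nonzero ASVs; need >= 4 for quartiles")
  x <- sort(as.numeric(nz))
  q <- switch(method,
    nearest_rank = c(x[ceiling(0.25 * length(x))], x[ceiling(0.75 * length(x))]),
    type7 = unname(quantile(x, c(0.25, 0.75), type = 7)))
  degenerate <- q[1L] == q[2L]
  if (degenerate)
    warning("Q1 == Q3 (", q[1L], ") for sample ", sample_id,
            "; rare and abundant sets overlap")
  structure(list(
    sample_id = sample_id,
    q1_threshold = q[1L], q3_threshold = q[2L],
    rare_asvs = names(nz)[nz <= q[1L]],
    abundant_asvs = names(nz)[nz >= q[2L]],
    degenerate = degenerate), class = "subcommunity_partition")
}

#' Quartile partitions for every sample of a table
#'
#' @inheritParams quartile_partition
#' @return named list of [quartile_partition()] results, one per sample.
#' @export
quartile_partitions <- function(table, method = c("nearest_rank", "type7")) {
  method <- match.arg(method)
  out <- lapply(rownames(table), function(s) quartile_partition(table, s, method))
  names(out) <- rownames(table)
  out
}

#' Equalize rare and abundant set sizes
#'
#' Subsamples the larger of the two sets, uniformly and seeded, down to the
#' size of the smaller, so the subcommunities are compared at an equivalent
#' ASV number per site. Identity when the sizes already match.
#'
#' @param p a [quartile_partition()] result (non-degenerate).
#' @param seed optional integer seed.
#' @return a `subcommunity_partition` with `|rare| == |abundant|`.
#' @export
balance_partition <- function(p, seed = NULL) {
  stopifnot(inherits(p, "subcommunity_partition"))
  if (isTRUE(p$degenerate)) stop("cannot balance a degenerate partition")
  n <- min(length(p$rare_asvs), length(p$abundant_asvs))
  with_seed_or_stream(seed, {
    if (length(p$rare_asvs) > n) p$rare_asvs <- sample(p$rare_asvs, n)
    if (length(p$abundant_asvs) > n) p$abundant_asvs <- sample(p$abundant_asvs, n)
  })
  p
}

#' Whole-table relative-abundance partition
#'
#' Classifies units (ASVs, or genera after aggregating counts through a
#' taxonomy table) as abundant when their share of the table's total reads
#' exceeds `threshold_pct` percent, and rare otherwise -- the ">1% / <1%
#' relative abundance" rule. Genus-level aggregation sums counts over all
#' samples within each genus; units with no genus assignment are aggregated
#' under `"unclassified"`.
#'
#' @param table community table.
#' @param threshold_pct abundance threshold in percent of total reads
#'   (default 1).
#' @param level `"asv"` or `"genus"`.
#' @param taxonomy data frame with columns `asv_id` and `genus` (required for
#'   `level = "genus"`).
#' @return list: `abundant` and `rare` (character vectors of unit ids),
#'   `read_fraction` (named numeric: share of total reads in each class),
#'   `rel_abundance` (per-unit relative abundance), `threshold_pct`.
#' @export
relabund_partition <- function(table, threshold_pct = 1.0,
                               level = c("asv", "genus"), taxonomy = NULL) {
  level <- match.arg(level)
  validate_community_table(table)
  totals <- colSums(table)
  if (level == "genus") {
    if (is.null(taxonomy) || !all(c("asv_id", "genus") %in% names(taxonomy)))
      stop("level='genus' needs a taxonomy with columns 'asv_id' and 'genus'")
    genus <- taxonomy$genus[match(colnames(table), taxonomy$asv_id)]
    genus[is.na(genus) | genus == ""] <- "unclassified"
    totals <- tapply(totals, genus, sum)
  }
  rel <- totals / sum(totals)
  abundant <- names(rel)[rel > threshold_pct / 100]
  rare <- setdiff(names(rel), abundant)
  list(abundant = abundant, rare = rare,
       read_fraction = c(abundant = sum(rel[abundant]), rare = sum(rel[rare])),
       rel_abundance = rel, threshold_pct = threshold_pct)
}

#' Shared-ASV intersection summary (UpSet counts) and core
#'
#' Assigns every ASV to the exact subset of samples where it has nonzero
#' count and tabulates the subset sizes -- the numbers behind an UpSet plot.
#' The core is the all-samples subset; its read fraction is the share of the
#' table's total reads carried by core ASVs.
#'
#' @param table community table with >= 2 samples.
#' @return list of class `intersection_summary`: `subsets` (data frame with
#'   `subset` as a sample-id bitmask string like `"S1+S3"`, `n_samples`,
#'   `n_asvs`), `core_asvs`, `core_count`, `core_read_fraction`.
#' @export
shared_intersections <- function(table) {
  validate_community_table(table, allow_zero_samples = TRUE)
  if (nrow(table) < 2L) stop("need at least two samples")
  pres <- table > 0
  seen <- colSums(pres) > 0
  key <- apply(pres[, seen, drop = FALSE], 2L,
               function(col) paste(rownames(table)[col], collapse = "+"))
  tab <- table(key)
  subsets <- data.frame(
    subset = names(tab),
    n_samples = lengths(strsplit(names(tab), "+", fixed = TRUE)),
    n_asvs = as.integer(tab),
    stringsAsFactors = FALSE)
  subsets <- subsets[order(-subsets$n_samples, subsets$subset), ]
  rownames(subsets) <- NULL
  core_key <- paste(rownames(table), collapse = "+")
  core_asvs <- colnames(table)[seen][key == core_key]
  structure(list(
    subsets = subsets,
    core_asvs = core_asvs,
    core_count = length(core_asvs),
    core_read_fraction = sum(table[, core_asvs, drop = FALSE]) / sum(table)),
    class = "intersection_summary")
}

#' @export
print.intersection_summary <- function(x, ...) {
  cat("ASV intersections over", max(x$subsets$n_samples), "samples:",
      sum(x$subsets$n_asvs), "ASVs present somewhere\n")
  cat(sprintf("  core (all samples): %d ASVs, %.1f%% of reads\n",
              x$core_count, 100 * x$core_read_fraction))
  invisible(x)
}
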