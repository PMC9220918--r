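#' Rarefy a community table to even depth
#'
#' Seeded subsampling of each sample's reads without replacement (one
#' multivariate-hypergeometric draw per sample, via [vegan::rrarefy()]),
#' the standard meaning of "rarefied to N reads per sample".
#'
#' @param table community table (samples x ASVs integer matrix).
#' @param depth target reads per sample.
#' @param seed optional integer seed.
#' @param drop_empty drop ASV columns that end up all-zero (default keeps
#'   them so column sets stay comparable across depths).
#' @param on_small what to do with samples whose total is below `depth`:
#'   `"error"` (default, names the samples) or `"drop"` with a warning.
#' @return rarefied community table; every row sums to `depth`.
#' @export
rarefy <- function(table, depth, seed = NULL, drop_empty = FALSE,
                   on_small = c("error", "drop")) {
  on_small <- match.arg(on_small)
  validate_community_table(table)
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1")
  small <- rowSums(table) < depth
  if (any(small)) {
    if (on_small == "error")
      stop("sample(s) below rarefaction depth ", depth, ": ",
           paste(rownames(table)[small], collapse = ", "))
    warning("dropping ", sum(small), " sample(s) below depth ", depth, ": ",
            paste(rownames(table)[small], collapse = ", "))
    table <- table[!small, , drop = FALSE]
    if (nrow(table) == 0L) stop("no sample reaches rarefaction depth ", depth)
  }
  # rrarefy emits an advisory warning whenever the smallest nonzero count
  # exceeds 1; counts are already validated as integer reads, so muffle it
  out <- with_seed_or_stream(seed, withCallingHandlers(
    vegan::rrarefy(table, depth),
    warning = function(w) {
      if (grepl("smallest count", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  storage.mode(out) <- "integer"
  if (drop_empty) out <- out[, colSums(out) > 0, drop = FALSE]
  out
}

#' Alpha diversity: observed richness and Shannon index
#'
#' Observed richness is the count of ASVs with nonzero reads; Shannon is
#' \eqn{H = -\sum_i p_i \log p_i} over the sample's nonzero relative
#' abundances. The log base is an explicit, recorded parameter because
#' different amplicon toolchains default to base 2 or base e.
#'
#' @param table community table.
#' @param log_base `"e"` (nats, default) or `"2"` (bits).
#' @return data frame with columns `sample_id`, `observed`, `shannon`,
#'   `log_base`.
#' @export
alpha_diversity <- function(table, log_base = c("e", "2")) {
  log_base <- match.arg(log_base)
  validate_community_table(table)
  base <- if (log_base == "2") 2 else exp(1)
  data.frame(
    sample_id = rownames(table),
    observed = as.integer(rowSums(table > 0)),
    shannon = as.numeric(vegan::diversity(table, index = "shannon", base = base)),
    log_base = log_base,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Beta diversity distance matrix
#'
#' Bray-Curtis on counts, \eqn{\sum_i |u_i - v_i| / \sum_i (u_i + v_i)}, or
#' the Jaccard distance \eqn{1 - |A \cap B| / |A \cup B|} on
#' presence/absence sets (vegan's binary Jaccard). Both lie in \[0, 1\].
#'
#' @param table community table with at least two samples.
#' @param metric `"bray_curtis"` or `"jaccard"`.
#' @return a labelled [stats::dist] over samples.
#' @export
beta_diversity <- function(table, metric = c("bray_curtis", "jaccard")) {
  metric <- match.arg(metric)
  validate_community_table(table)
  if (nrow(table) < 2L) stop("need at least two samples")
  switch(metric,
         bray_curtis = vegan::vegdist(table, method = "bray"),
         jaccard = vegan::vegdist(table, method = "jaccard", binary = TRUE))
}

#' UPGMA dendrogram of samples
#'
#' Average-linkage agglomerative clustering of a sample distance matrix,
#' returned as an ultrametric [ape::phylo] whose tip-to-node heights are the
#' merge heights (half the average between-cluster distance, so two samples
#' at distance d merge at height d/2). Merge heights, ordered as the
#' agglomeration proceeds, are attached as attribute `"merge_heights"`.
#'
#' @param dm a `dist` or labelled symmetric matrix.
#' @return an ultrametric [ape::phylo].
#' @export
upgma <- function(dm) {
  d <- stats::as.dist(dm)
  if (attr(d, "Size") < 2L) stop("need at least two labels")
  if (anyNA(d) || any(!is.finite(d))) stop("distance matrix contains NA/NaN/Inf")
  hc <- hclust(d, method = "average")
  phy <- ape::as.phylo(hc)
  attr(phy, "merge_heights") <- hc$height / 2
  phy
}

#' Pairwise geographic distances along a transect
#'
#' @param meta data frame with columns `sample_id` and `position_m`.
#' @return labelled [stats::dist] of absolute position differences (metres).
#' @export
geographic_distances <- function(meta) {
  if (!all(c("sample_id", "position_m") %in% names(meta)))
    stop("metadata must have columns 'sample_id' and 'position_m'")
  if (anyNA(meta$position_m) || any(!is.finite(meta$position_m)))
    stop("missing position for sample(s): ",
         paste(meta$sample_id[!is.finite(meta$position_m)], collapse = ", "))
  pos <- meta$position_m
  names(pos) <- meta$sample_id
  dist(pos)
}

# all permutations of 1..n (n small; used for exhaustive Mantel enumeration)
.all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- vector("list", factorial(n))
  k <- 0L
  for (i in seq_len(n)) {
    for (p in .all_perms(n - 1L)) {
      rest <- seq_len(n)[-i]
      k <- k + 1L
      out[[k]] <- c(i, rest[p])
    }
  }
  out
}

#' Mantel test between two distance matrices
#'
#' Correlation r of the strictly-lower-triangle vectors, with a one-sided
#' (greater) permutation test that permutes the rows and columns of `dm_b`
#' jointly. When the number of label permutations n! does not exceed
#' `n_permutations`, the test enumerates all of them and the p-value is
#' exact: \eqn{p = \#\{r_{perm} \ge r_{obs}\} / n!}. Otherwise p is the usual
#' randomization estimate \eqn{(1 + \#\{r_{perm} \ge r_{obs}\}) /
#' (n_{perm} + 1)}.
#'
#' @param dm_a,dm_b `dist` objects or labelled symmetric matrices over the
#'   same labels in the same order.
#' @param n_permutations number of random permutations (default 999).
#' @param seed optional integer seed.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list of class `mantel_result`: `r`, `p`, `n_permutations`,
#'   `exhaustive`, `method`.
#' @export
mantel_test <- function(dm_a, dm_b, n_permutations = 999L, seed = NULL,
                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  a <- as.matrix(dm_a); b <- as.matrix(dm_b)
  if (!identical(dim(a), dim(b))) stop("distance matrices differ in size")
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b)))
    stop("distance matrices must share labels in the same order")
  n <- nrow(a)
  if (n < 3L) stop("need at least three labels")
  low <- lower.tri(a)
  va <- a[low]
  if (sd(va) == 0 || sd(b[low]) == 0)
    stop("zero variance in a distance matrix's lower triangle")
  r_obs <- cor(va, b[low], method = method)

  exhaustive <- factorial(n) <= n_permutations
  if (exhaustive) {
    perms <- .all_perms(n)
    r_perm <- vapply(perms, function(p) cor(va, b[p, p][low], method = method),
                     numeric(1L))
    p_val <- mean(r_perm >= r_obs - 1e-12)
    n_used <- length(perms)
  } else {
    r_perm <- with_seed_or_stream(seed, {
      vapply(seq_len(n_permutations), function(i) {
        p <- sample.int(n)
        cor(va, b[p, p][low], method = method)
      }, numeric(1L))
    })
    p_val <- (1 + sum(r_perm >= r_obs - 1e-12)) / (n_permutations + 1)
    n_used <- n_permutations
  }
  structure(list(r = r_obs, p = p_val, n_permutations = n_used,
                 exhaustive = exhaustive, method = method),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (%s, one-sided greater): r = %.4f, p = %.4f (%s%d permutations)\n",
              x$method, x$r, x$p,
              if (x$exhaustive) "exhaustive, " else "", x$n_permutations))
  invisible(x)
}
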