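# fast core of the richness null: per sample, reassign the multiset of
# nonzero counts to a uniformly random subset of the pool (all columns by
# default, or the column indices in `pool`) of the same size
.richness_null_counts <- function(table, pool = NULL) {
  if (is.null(pool)) pool <- seq_len(ncol(table))
  out <- matrix(0L, nrow(table), ncol(table), dimnames = dimnames(table))
  for (s in seq_len(nrow(table))) {
    v <- table[s, ]
    nz <- v[v > 0L]
    idx <- pool[sample.int(length(pool), length(nz))]
    out[s, idx] <- nz          # random order: counts permuted over taxa
  }
  out
}

#' Richness-preserving randomization of a community table
#'
#' The null model behind the standardized effect sizes: for each sample
#' independently, the multiset of its nonzero read counts is reassigned to a
#' uniformly random subset of the full ASV pool of the same size. Per-sample
#' richness and per-sample read totals are both conserved ("total sample
#' diversity constant"); taxon identities are randomized.
#'
#' @param table community table.
#' @param seed optional integer seed.
#' @return randomized community table of the same shape.
#' @export
richness_null <- function(table, seed = NULL) {
  validate_community_table(table, allow_zero_samples = TRUE)
  with_seed_or_stream(seed, .richness_null_counts(table))
}

#' Classify a standardized effect size
#'
#' SES below -2 means more phylogenetic clustering than expected by chance
#' alone (`"clustered"`), above +2 more overdispersion (`"overdispersed"`),
#' and values in \[-2, +2\] are consistent with the null model (`"null"`).
#' Boundary values map to `"null"`.
#'
#' @param ses numeric vector of standardized effect sizes.
#' @param thresholds two-sided classification bound (default 2).
#' @return character vector of labels.
#' @export
classify_ses <- function(ses, thresholds = 2) {
  if (anyNA(ses) || any(!is.finite(ses))) stop("SES values must be finite")
  ifelse(ses < -thresholds, "clustered",
         ifelse(ses > thresholds, "overdispersed", "null"))
}

# rare/abundant index sets of a count vector by the nearest-rank (or type-7)
# quartile rule; returns column indices
.quartile_sets <- function(v, method = "nearest_rank") {
  nz <- which(v > 0L)
  x <- as.numeric(v[nz])
  if (length(nz) < 4L) return(list(rare = integer(0L), abundant = integer(0L)))
  xs <- sort(x)
  q <- if (method == "nearest_rank")
    c(xs[ceiling(0.25 * length(xs))], xs[ceiling(0.75 * length(xs))])
  else unname(quantile(xs, c(0.25, 0.75), type = 7))
  list(rare = nz[x <= q[1L]], abundant = nz[x >= q[2L]])
}

#' Standardized effect sizes of PD or PSC under the richness null
#'
#' For each sample (and each rare/abundant subset when `partition =
#' "quartile"`), computes the observed metric, then a null distribution from
#' `n_replicates` richness-null randomizations of the whole table with the
#' same subset rule re-applied inside every replicate. SES = (observed -
#' null mean) / null sd, classified by [classify_ses()].
#'
#' `freeze_subsets = TRUE` is the sensitivity variant that mirrors handing
#' the null model pre-built rare/abundant matrices: the observed partition
#' is frozen, each subset's counts form their own community matrix, and the
#' richness null randomizes that matrix with the taxon pool restricted to
#' the subset's ASV union across samples -- instead of re-partitioning the
#' randomized full table with the full pool.
#'
#' ASVs absent from the tree are dropped from the metric (with a logged
#' count) but remain part of the randomization pool.
#'
#' @param table community table (typically rarefied).
#' @param tree an [ape::phylo] or [phylo_edge_index()].
#' @param metric `"PD"` or `"PSC"`.
#' @param partition `"none"` (whole-sample sets) or `"quartile"`
#'   (rare/abundant subsets, re-derived per replicate).
#' @param n_replicates null replicates (default 1000).
#' @param seed optional integer seed fixing the entire null distribution.
#' @param freeze_subsets with `partition = "quartile"`, run the null on the
#'   frozen observed subset matrices (restricted pools) instead of
#'   re-deriving subsets per replicate; see Details.
#' @param balance equalize rare/abundant set sizes (subsampling the larger)
#'   before the metric, observed and nulls alike.
#' @param include_root PD convention, see [faith_pd()].
#' @param quartile_method passed to the quartile rule.
#' @param keep_replicates attach the replicate metric matrix as attribute
#'   `"replicates"` for inspection.
#' @return data frame with one row per sample x subset: `sample_id`,
#'   `subset_label`, `metric`, `observed`, `null_mean`, `null_sd`, `ses`,
#'   `n_replicates`, `label`, `degenerate`.
#' @export
ses_metric <- function(table, tree, metric = c("PD", "PSC"),
                       partition = c("none", "quartile"),
                       n_replicates = 1000L, seed = NULL,
                       freeze_subsets = FALSE, balance = FALSE,
                       include_root = TRUE,
                       quartile_method = c("nearest_rank", "type7"),
                       keep_replicates = FALSE) {
  metric <- match.arg(metric)
  partition <- match.arg(partition)
  quartile_method <- match.arg(quartile_method)
  validate_community_table(table)
  if (n_replicates < 2L) stop("n_replicates must be >= 2")
  ix <- .as_edge_index(tree)

  col2tip <- match(colnames(table), ix$tip_labels)
  n_off_tree <- sum(is.na(col2tip))
  if (n_off_tree > 0L)
    message(n_off_tree, " ASVs absent from the tree are excluded from the ",
            metric, " metric (they stay in the randomization pool)")

  eval_metric <- function(cols) {
    idx <- col2tip[cols]
    idx <- idx[!is.na(idx)]
    if (metric == "PD") {
      if (length(idx) < 1L) return(NA_real_)
      .pd_idx(ix, idx, include_root)
    } else {
      if (length(idx) < 2L) return(NA_real_)
      .psc_idx(ix, idx)
    }
  }

  subset_labels <- if (partition == "none") "all" else c("rare", "abundant")
  sample_sets <- function(tab) {
    lapply(seq_len(nrow(tab)), function(s) {
      if (partition == "none") {
        list(all = which(tab[s, ] > 0L))
      } else {
        sets <- .quartile_sets(tab[s, ], quartile_method)
        if (balance) {
          n <- min(lengths(sets))
          sets <- lapply(sets, function(x) if (length(x) > n) sample(x, n) else x)
        }
        sets
      }
    })
  }

  res <- with_seed_or_stream(seed, {
    obs_sets <- sample_sets(table)
    observed <- vapply(obs_sets, function(sets) vapply(sets, eval_metric, numeric(1L)),
                       numeric(length(subset_labels)))
    observed <- matrix(observed, nrow = length(subset_labels))

    null_vals <- array(NA_real_,
                       dim = c(n_replicates, length(subset_labels), nrow(table)))
    if (freeze_subsets && partition == "quartile") {
      # one community matrix per subset label, counts outside the observed
      # sets zeroed; the randomization pool is the subset's ASV union
      subs <- lapply(seq_along(subset_labels), function(k) {
        m <- matrix(0L, nrow(table), ncol(table), dimnames = dimnames(table))
        for (s in seq_len(nrow(table)))
          m[s, obs_sets[[s]][[k]]] <- table[s, obs_sets[[s]][[k]]]
        m
      })
      pools <- lapply(subs, function(m) which(colSums(m) > 0L))
      for (r in seq_len(n_replicates)) {
        for (k in seq_along(subset_labels)) {
          tabr <- .richness_null_counts(subs[[k]], pool = pools[[k]])
          for (s in seq_len(nrow(table)))
            null_vals[r, k, s] <- eval_metric(which(tabr[s, ] > 0L))
        }
      }
    } else {
      for (r in seq_len(n_replicates)) {
        tabr <- .richness_null_counts(table)
        sets_r <- sample_sets(tabr)
        for (s in seq_len(nrow(table)))
          null_vals[r, , s] <- vapply(sets_r[[s]], eval_metric, numeric(1L))
      }
    }
    list(observed = observed, null_vals = null_vals)
  })

  rows <- list()
  for (s in seq_len(nrow(table))) {
    for (k in seq_along(subset_labels)) {
      nv <- res$null_vals[, k, s]
      nm <- mean(nv, na.rm = TRUE)
      ns <- sd(nv, na.rm = TRUE)
      obs <- res$observed[k, s]
      degenerate <- !is.finite(ns) || ns == 0 || !is.finite(obs) || !is.finite(nm)
      ses <- if (degenerate) NA_real_ else (obs - nm) / ns
      if (degenerate)
        warning("degenerate null (sd = 0 or undefined metric) for sample ",
                rownames(table)[s], ", subset ", subset_labels[k])
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = rownames(table)[s], subset_label = subset_labels[k],
        metric = metric, observed = obs, null_mean = nm, null_sd = ns,
        ses = ses, n_replicates = n_replicates,
        label = if (degenerate) "null" else classify_ses(ses),
        degenerate = degenerate, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_replicates) attr(out, "replicates") <- res$null_vals
  out
}
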