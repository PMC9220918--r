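#' Precompute the tip-by-edge incidence of a phylogeny
#'
#' Faith PD and the phylogenetic correlation matrix are both linear in the
#' branch lengths along root-to-tip paths, so they reduce to operations on a
#' sparse tip x edge incidence matrix (1 where the edge lies on the tip's
#' path to the root). Building it once per tree makes the thousands of
#' subset-metric evaluations inside the null model cheap.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @return list of class `phylo_edge_index`: `inc` (sparse incidence), `B`
#'   (`inc` scaled by sqrt branch length, so shared path length is
#'   `tcrossprod(B)`), `len` (edge lengths), `depth` (root-to-tip distances),
#'   `tip_labels`.
#' @export
phylo_edge_index <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  n_tip <- length(tree$tip.label)
  edge <- tree$edge
  len <- tree$edge.length
  n_node <- max(edge)
  parent <- integer(n_node)
  edge_of <- integer(n_node)
  parent[edge[, 2L]] <- edge[, 1L]
  edge_of[edge[, 2L]] <- seq_len(nrow(edge))
  root <- n_tip + 1L

  ii <- vector("list", n_tip)
  for (tip in seq_len(n_tip)) {
    path <- integer(0L)
    v <- tip
    while (v != root && parent[v] != 0L) {
      path <- c(path, edge_of[v])
      v <- parent[v]
    }
    ii[[tip]] <- path
  }
  inc <- Matrix::sparseMatrix(i = rep.int(seq_len(n_tip), lengths(ii)),
                              j = unlist(ii), x = 1,
                              dims = c(n_tip, nrow(edge)))
  rownames(inc) <- tree$tip.label
  B <- inc %*% Matrix::Diagonal(x = sqrt(len))
  depth <- as.numeric(inc %*% len)
  # for moderate trees, cache the full tip correlation matrix so subset PSC
  # inside the null loops is a plain dense subset + row max
  C <- NULL
  if (n_tip <= 4000L && all(depth > 0)) {
    V <- as.matrix(Matrix::tcrossprod(B))
    C <- V / sqrt(outer(depth, depth))
    dimnames(C) <- list(tree$tip.label, tree$tip.label)
  }
  structure(list(inc = inc, B = B, len = len, depth = depth, C = C,
                 tip_labels = tree$tip.label),
            class = "phylo_edge_index")
}

.as_edge_index <- function(tree) {
  if (inherits(tree, "phylo_edge_index")) tree else phylo_edge_index(tree)
}

# resolve taxa labels against the index, dropping (with a message) those
# absent from the tree
.resolve_taxa <- function(ix, taxa) {
  idx <- match(unique(taxa), ix$tip_labels)
  n_missing <- sum(is.na(idx))
  if (n_missing > 0L)
    message(n_missing, " taxa absent from the tree dropped from the metric")
  idx[!is.na(idx)]
}

.pd_idx <- function(ix, tip_idx, include_root = TRUE) {
  hits <- Matrix::colSums(ix$inc[tip_idx, , drop = FALSE])
  covered <- hits > 0
  if (!include_root) covered <- covered & hits < length(tip_idx)
  sum(ix$len[covered])
}

.phylo_cor_idx <- function(ix, tip_idx) {
  d <- ix$depth[tip_idx]
  if (any(d <= 0))
    stop("tip(s) at zero distance from the root: ",
         paste(ix$tip_labels[tip_idx[d <= 0]], collapse = ", "))
  if (!is.null(ix$C)) return(ix$C[tip_idx, tip_idx, drop = FALSE])
  V <- as.matrix(Matrix::tcrossprod(ix$B[tip_idx, , drop = FALSE]))
  C <- V / sqrt(outer(d, d))
  dimnames(C) <- list(ix$tip_labels[tip_idx], ix$tip_labels[tip_idx])
  C
}

.psc_idx <- function(ix, tip_idx) {
  C <- .phylo_cor_idx(ix, tip_idx)
  n <- length(tip_idx)
  # row max excluding the unit diagonal
  1 - sum(apply(C - diag(2, n), 1L, max)) / n
}

#' Faith's Phylogenetic Diversity of a taxon set
#'
#' Sum of the branch lengths of the minimal subtree connecting the taxa,
#' extended to the tree's root when `include_root = TRUE` (the default,
#' matching the common toolchain convention; with it, PD of a single taxon
#' is its root-to-tip distance, and PD of all tips is the total tree
#' length).
#'
#' @param tree an [ape::phylo] or a prebuilt [phylo_edge_index()].
#' @param taxa character vector of tip labels; labels absent from the tree
#'   are dropped with a logged count.
#' @param include_root include the branches between the taxa's MRCA and the
#'   root.
#' @return non-negative PD value.
#' @export
faith_pd <- function(tree, taxa, include_root = TRUE) {
  ix <- .as_edge_index(tree)
  idx <- .resolve_taxa(ix, taxa)
  if (length(idx) == 0L) stop("no taxa left after dropping tips absent from the tree")
  .pd_idx(ix, idx, include_root)
}

#' Phylogenetic correlation matrix of a taxon set
#'
#' \eqn{V_{ij}} is the branch length shared by the root-to-tip paths of taxa
#' i and j (the depth of their MRCA); the correlation is
#' \eqn{C_{ij} = V_{ij} / \sqrt{V_{ii} V_{jj}}}. C is symmetric with unit
#' diagonal and entries in \[0, 1\]; on an ultrametric tree it equals MRCA
#' depth over total depth. No ultrametricity is assumed.
#'
#' @inheritParams faith_pd
#' @return square correlation matrix over the (resolved) taxa.
#' @export
phylo_correlation <- function(tree, taxa) {
  ix <- .as_edge_index(tree)
  idx <- .resolve_taxa(ix, taxa)
  if (length(idx) < 2L) stop("need at least two taxa on the tree")
  .phylo_cor_idx(ix, idx)
}

#' Phylogenetic Species Clustering (PSC)
#'
#' \eqn{PSC = 1 - \mathrm{mean}_i \max_{j \ne i} C_{ij}}: one minus the mean,
#' over taxa, of each taxon's maximum phylogenetic correlation with any other
#' taxon in the set. Values near 0 mean the set is phylogenetically
#' clustered (every taxon has a close relative in the set); a star phylogeny
#' gives 1. Invariant to rescaling all branch lengths.
#'
#' @inheritParams faith_pd
#' @return PSC value in \[0, 1\].
#' @export
psc <- function(tree, taxa) {
  ix <- .as_edge_index(tree)
  idx <- .resolve_taxa(ix, taxa)
  if (length(idx) < 2L) stop("PSC needs at least two taxa on the tree")
  .psc_idx(ix, idx)
}

#' Per-sample phylogenetic metrics, optionally by subcommunity
#'
#' Evaluates PD and PSC for each sample's present ASVs (count > 0; both
#' metrics are abundance-blind) and, when a partition list is supplied, for
#' the rare and abundant subsets as well.
#'
#' @param table community table.
#' @param tree an [ape::phylo] or [phylo_edge_index()].
#' @param partitions optional named list of [quartile_partition()] results
#'   (one per sample), as returned by [quartile_partitions()].
#' @param include_root passed to the PD computation.
#' @return long data frame: `sample_id`, `subset_label`
#'   (all/rare/abundant), `metric` (PD/PSC), `value`.
#' @export
phylo_metrics <- function(table, tree, partitions = NULL, include_root = TRUE) {
  validate_community_table(table)
  ix <- .as_edge_index(tree)
  rows <- list()
  for (s in rownames(table)) {
    sets <- list(all = colnames(table)[table[s, ] > 0])
    if (!is.null(partitions)) {
      p <- partitions[[s]]
      if (is.null(p)) stop("no partition supplied for sample ", s)
      sets$rare <- p$rare_asvs
      sets$abundant <- p$abundant_asvs
    }
    for (lab in names(sets)) {
      idx <- .resolve_taxa(ix, sets[[lab]])
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, subset_label = lab,
        metric = c("PD", "PSC"),
        value = c(if (length(idx) > 0L) .pd_idx(ix, idx, include_root) else NA_real_,
                  if (length(idx) > 1L) .psc_idx(ix, idx) else NA_real_),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
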