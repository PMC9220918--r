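# Independent brute-force oracles. These deliberately avoid the package's
# edge-incidence machinery: paths are enumerated with ape::nodepath and
# metrics computed from explicit edge sets, so agreement is a genuine
# two-route check.

# edge keys ("parent>child") on the path from `from` to tip label `taxon`
.oracle_path_edges <- function(tree, from, taxon) {
  tip <- match(taxon, tree$tip.label)
  nodes <- ape::nodepath(tree, from, tip)
  if (length(nodes) < 2L) return(character(0L))
  paste(nodes[-length(nodes)], nodes[-1L], sep = ">")
}

.oracle_edge_lengths <- function(tree) {
  keys <- paste(tree$edge[, 1L], tree$edge[, 2L], sep = ">")
  stats::setNames(tree$edge.length, keys)
}

oracle_pd <- function(tree, taxa, include_root = TRUE) {
  root <- length(tree$tip.label) + 1L
  start <- if (include_root || length(taxa) == 1L) root else ape::getMRCA(tree, taxa)
  if (!include_root && length(taxa) == 1L) return(0)
  lens <- .oracle_edge_lengths(tree)
  edges <- unique(unlist(lapply(taxa, function(tx) .oracle_path_edges(tree, start, tx))))
  sum(lens[edges])
}

oracle_phylo_cor <- function(tree, taxa) {
  root <- length(tree$tip.label) + 1L
  lens <- .oracle_edge_lengths(tree)
  paths <- lapply(taxa, function(tx) .oracle_path_edges(tree, root, tx))
  n <- length(taxa)
  V <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n)) for (j in seq_len(n))
    V[i, j] <- sum(lens[intersect(paths[[i]], paths[[j]])])
  V / sqrt(outer(diag(V), diag(V)))
}

oracle_psc <- function(tree, taxa) {
  C <- oracle_phylo_cor(tree, taxa)
  mx <- vapply(seq_len(nrow(C)), function(i) max(C[i, -i]), numeric(1L))
  1 - mean(mx)
}

# exhaustive Mantel p by direct definition: correlate the lower triangles
# under every joint row/column permutation of the second matrix
.oracle_all_perms <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(.oracle_all_perms(v[-i]), function(p) c(v[i], p)))
  out
}

oracle_mantel_exhaustive <- function(a, b, method = "pearson") {
  a <- as.matrix(a); b <- as.matrix(b)
  low <- lower.tri(a)
  r_obs <- stats::cor(a[low], b[low], method = method)
  rs <- vapply(.oracle_all_perms(seq_len(nrow(a))),
               function(p) stats::cor(a[low], b[p, p][low], method = method),
               numeric(1L))
  list(r = r_obs, p = mean(rs >= r_obs - 1e-12))
}

# a small random non-ultrametric tree for property tests
random_test_tree <- function(n_tips, seed) {
  withr::with_seed(seed, {
    tree <- ape::rphylo(n_tips, birth = 1, death = 0)
    tree$edge.length <- tree$edge.length + stats::runif(length(tree$edge.length),
                                                        0.01, 0.5)
    tree
  })
}

# tiny deterministic community fixture shared across tests
toy_table <- function() {
  m <- matrix(c(10L, 0L, 5L, 2L, 7L, 1L,
                5L,  5L, 5L, 0L, 3L, 9L,
                1L,  8L, 0L, 4L, 6L, 2L),
              nrow = 3L, byrow = TRUE,
              dimnames = list(c("S1", "S2", "S3"), paste0("asv", 1:6)))
  m
}
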