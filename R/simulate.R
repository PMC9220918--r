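#' Simulation parameters for synthetic mat communities
#'
#' Bundles and validates the knobs of the synthetic community generator. The
#' defaults emulate the structure of a hypersaline mat transect: ten samples,
#' a community where ~3% of ASVs form a high-count core shared by every
#' sample and carrying ~72.5% of the reads, and a long lognormal rare tail in
#' which each ASV occurs in any given sample with moderate probability, so
#' that almost no rare ASV is shared by all samples.
#'
#' @param n_samples number of samples (sites along the transect).
#' @param n_taxa number of ASVs in the pool (the tree must have at least this
#'   many tips).
#' @param depth reads per sample after sequencing (every sample total equals
#'   this exactly).
#' @param core_size number of abundant core ASVs (default 3% of `n_taxa`).
#' @param core_read_fraction expected fraction of each sample's reads carried
#'   by the core, in (0, 1).
#' @param abundance_shape lognormal sigma of the rare-tail abundance
#'   distribution (larger = more uneven tail).
#' @param abundant_placement `"random"` scatters the core across the tree;
#'   `"clade"` takes it from the smallest clade holding at least `core_size`
#'   of the community's tips, producing a phylogenetically clustered core.
#' @param occupancy_rare probability that a rare ASV occurs in any given
#'   sample (independent across samples).
#' @param seed optional integer seed for the whole dataset.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(n_samples = 10L,
                       n_taxa = 1000L,
                       depth = 100000L,
                       core_size = ceiling(0.03 * n_taxa),
                       core_read_fraction = 0.725,
                       abundance_shape = 1.5,
                       abundant_placement = c("random", "clade"),
                       occupancy_rare = 0.35,
                       seed = NULL) {
  abundant_placement <- match.arg(abundant_placement)
  p <- list(n_samples = as.integer(n_samples), n_taxa = as.integer(n_taxa),
            depth = as.integer(depth), core_size = as.integer(core_size),
            core_read_fraction = core_read_fraction,
            abundance_shape = abundance_shape,
            abundant_placement = abundant_placement,
            occupancy_rare = occupancy_rare, seed = seed)
  if (p$n_samples < 1L) stop("n_samples must be >= 1")
  if (p$core_size < 1L || p$core_size >= p$n_taxa)
    stop("core_size must satisfy 1 <= core_size < n_taxa")
  if (p$core_read_fraction <= 0 || p$core_read_fraction >= 1)
    stop("core_read_fraction must be in (0, 1)")
  if (p$occupancy_rare < 0 || p$occupancy_rare > 1)
    stop("occupancy_rare must be in [0, 1]")
  if (p$depth <= p$core_size)
    stop("depth must exceed core_size (every core ASV carries >= 1 read)")
  class(p) <- "sim_params"
  p
}

# tips of every internal node, counted within `taxa`; returns the tip-label
# sets, ordered as the internal node numbers of `tree`
.clade_tip_sets <- function(tree, taxa) {
  n_tip <- length(tree$tip.label)
  sets <- ape::prop.part(tree)
  lapply(sets, function(idx) intersect(tree$tip.label[idx], taxa))
}

#' Simulate multi-sample mat communities over a phylogeny
#'
#' Generative model: `core_size` ASVs form an abundant core present in every
#' sample and carrying an expected `core_read_fraction` of each sample's
#' reads (core weights are lognormal with sigma 0.5, fixed across samples --
#' the core is the stable dominant community). The remaining ASVs form the
#' rare tail: each gets a lognormal base weight (sigma `abundance_shape`)
#' and occurs in each sample independently with probability `occupancy_rare`.
#' Per sample, relative abundances are normalized so the core block sums to
#' `core_read_fraction`, and counts are drawn multinomially at `depth` reads
#' after reserving one read per core ASV (which guarantees the core is
#' present everywhere and keeps sample totals exactly at `depth`).
#'
#' With `abundant_placement = "clade"` the core is drawn from the smallest
#' clade containing at least `core_size` of the community's tips, so the
#' abundant subcommunity is phylogenetically clustered -- the ground truth
#' the null-model tests must recover.
#'
#' @param tree an [ape::phylo] with at least `params$n_taxa` tips.
#' @param params a [sim_params()] object.
#' @return a list of class `synthetic_dataset` with components `table`
#'   (samples x ASVs integer matrix), `tree`, and `truth` (the params plus
#'   the realized `core_asvs`, `rare_asvs` and `taxa` used).
#' @export
simulate_communities <- function(tree, params) {
  stopifnot(inherits(params, "sim_params"), inherits(tree, "phylo"))
  if (length(tree$tip.label) < params$n_taxa)
    stop("tree has ", length(tree$tip.label), " tips but n_taxa = ", params$n_taxa)

  with_seed_or_stream(params$seed, {
    taxa <- if (length(tree$tip.label) == params$n_taxa) tree$tip.label
            else sort(sample(tree$tip.label, params$n_taxa))

    core <- switch(params$abundant_placement,
      random = sample(taxa, params$core_size),
      clade = {
        sets <- .clade_tip_sets(tree, taxa)
        sizes <- lengths(sets)
        # exclude the root set (all taxa): a root-wide "clade" is no clustering
        ok <- which(sizes >= params$core_size & sizes < length(taxa))
        if (length(ok) == 0L)
          stop("no clade holds >= ", params$core_size,
               " of the community's tips; use a smaller core_size")
        best <- ok[which.min(sizes[ok])]
        sample(sets[[best]], params$core_size)
      })
    rare <- setdiff(taxa, core)

    w_core <- rlnorm(length(core), meanlog = 0, sdlog = 0.5)
    w_rare <- rlnorm(length(rare), meanlog = 0, sdlog = params$abundance_shape)

    counts <- matrix(0L, params$n_samples, length(taxa),
                     dimnames = list(sprintf("S%d", seq_len(params$n_samples)),
                                     taxa))
    for (s in seq_len(params$n_samples)) {
      present <- runif(length(rare)) < params$occupancy_rare
      p <- numeric(length(taxa))
      names(p) <- taxa
      if (any(present)) {
        p[core] <- params$core_read_fraction * w_core / sum(w_core)
        p[rare[present]] <- (1 - params$core_read_fraction) *
          w_rare[present] / sum(w_rare[present])
      } else {
        p[core] <- w_core / sum(w_core)
      }
      draw <- rmultinom(1L, params$depth - params$core_size, p)[, 1L]
      draw[core] <- draw[core] + 1L   # reserve one read per core ASV
      counts[s, ] <- draw
    }
    storage.mode(counts) <- "integer"
    validate_community_table(counts)

    structure(list(table = counts, tree = tree,
                   truth = list(params = params, core_asvs = sort(core),
                                rare_asvs = sort(rare), taxa = taxa)),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  p <- x$truth$params
  cat("Synthetic community dataset:", nrow(x$table), "samples x",
      ncol(x$table), "ASVs,", p$depth, "reads/sample\n")
  cat("  core:", length(x$truth$core_asvs), "ASVs (",
      p$abundant_placement, "placement ), expected read fraction",
      p$core_read_fraction, "\n")
  invisible(x)
}
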