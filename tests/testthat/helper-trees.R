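# Shared fixtures and independent oracles, built in code at test time.

# Random binary unrooted tree with unit-ish branch lengths.
rand_tree <- function(n, seed = NULL) {
  dendroblast:::with_seed(seed, ape::rtopology(n, rooted = FALSE,
    br = function(k) stats::runif(k, 0.1, 1)))
}

# Brute-force bipartition oracle, independent of ape::prop.part: remove
# each internal edge of the tree graph and collect the leaf component on
# the child side by BFS over the remaining edges.
oracle_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  n <- ape::Ntip(tree)
  tips <- sort(tree$tip.label)
  ref <- tips[1L]
  out <- character(0)
  for (k in seq_len(nrow(tree$edge))) {
    child <- tree$edge[k, 2L]
    if (child <= n) next                      # trivial split
    keep <- tree$edge[-k, , drop = FALSE]
    seen <- child
    repeat {
      grow <- unique(c(keep[keep[, 1L] %in% seen, 2L],
                       keep[keep[, 2L] %in% seen, 1L]))
      grow <- setdiff(grow, seen)
      if (!length(grow)) break
      seen <- c(seen, grow)
    }
    blk <- tree$tip.label[seen[seen <= n]]
    if (length(blk) <= 1L || length(blk) >= n - 1L) next
    if (ref %in% blk) blk <- setdiff(tips, blk)
    out <- c(out, paste(sort(blk), collapse = ","))
  }
  unique(out)
}

# TRUE iff two canonical split keys are compatible on the given leaf set.
splits_compatible <- function(key1, key2, tips) {
  a <- strsplit(key1, ",")[[1]]
  b <- strsplit(key2, ",")[[1]]
  ac <- setdiff(tips, a); bc <- setdiff(tips, b)
  !length(intersect(a, b)) || !length(intersect(a, bc)) ||
    !length(intersect(ac, b)) || !length(intersect(ac, bc))
}

# Additive distance matrix of a tree from its branch lengths.
tree_distances <- function(tree) {
  as.matrix(ape::cophenetic.phylo(tree))
}

# A small protein family with two identical sequences (mutually
# top-scoring, identical hit profiles) plus distinct relatives.
duplicated_pair_family <- function(seed = 1) {
  fam <- simulate_family(n_taxa = 5, length = 120, branch_mean = 0.2,
                         seed = seed)
  seqs <- unclass(fam$seqs)
  seq_set(stats::setNames(c(seqs, seqs[[1L]]), c(names(seqs), "twin")))
}
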