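#' Infer an unrooted tree from a distance matrix
#'
#' `method = "bme_nni"` (default) follows the minimum-evolution route:
#' a neighbour-joining starting tree refined by nearest-neighbour
#' interchanges under the balanced minimum-evolution criterion (the FastME
#' strategy; SPR moves are not used). `method = "nj"` returns the plain
#' neighbour-joining tree. Negative branch-length estimates are clamped to
#' zero. The result is strictly bifurcating and unrooted, and its topology
#' does not depend on taxon input order.
#'
#' @param d symmetric numeric distance matrix with >= 4 taxa and finite
#'   entries, taxon ids as dimnames (or a `dist`).
#' @param method `"bme_nni"` or `"nj"`.
#' @return An [ape::phylo] tree.
#' @export
infer_tree <- function(d, method = c("bme_nni", "nj")) {
  method <- match.arg(method)
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d)))
    stop("distance matrix must carry taxon ids as dimnames")
  if (nrow(d) < 4L)
    stop("fewer than 4 taxa: tree inference needs 4 or more")
  if (any(!is.finite(d)))
    stop("non-finite distances")
  tr <- switch(method,
    nj = ape::nj(d),
    bme_nni = ape::fastme.bal(d, nni = TRUE, spr = FALSE, tbr = FALSE))
  tr <- ape::unroot(tr)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Balanced minimum-evolution tree length (Pauplin's formula)
#'
#' The balanced ME criterion scores an unrooted binary topology by the
#' topology-weighted average of pairwise distances:
#' `L(T) = sum_{i<j} 2^(1 - p_ij) * d_ij`, where `p_ij` is the number of
#' edges on the path between leaves `i` and `j`. NNI refinement
#' under the criterion never increases this length, and on additive
#' distances the generating topology attains the sum of the true branch
#' lengths.
#'
#' @param tree an unrooted binary [ape::phylo] topology.
#' @param d distance matrix with the tree's tip labels as dimnames.
#' @return The balanced tree length.
#' @export
bme_length <- function(tree, d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  tree <- ape::unroot(tree)
  if (!ape::is.binary(tree))
    stop("balanced tree length is defined for binary topologies")
  tips <- tree$tip.label
  stopifnot(all(tips %in% rownames(d)))
  n <- length(tips)
  # p_ij: edges on the i-j path, by BFS over the unweighted tree graph
  steps <- matrix(0L, n + tree$Nnode, n + tree$Nnode)
  g <- vector("list", n + tree$Nnode)
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1L]; b <- tree$edge[k, 2L]
    g[[a]] <- c(g[[a]], b); g[[b]] <- c(g[[b]], a)
  }
  for (i in seq_len(n)) {           # BFS from each leaf
    dist_i <- rep(NA_integer_, n + tree$Nnode)
    dist_i[i] <- 0L
    queue <- i
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in g[[v]]) if (is.na(dist_i[w])) {
        dist_i[w] <- dist_i[v] + 1L
        queue <- c(queue, w)
      }
    }
    steps[i, ] <- dist_i
  }
  total <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    total <- total + 2^(1 - steps[i, j]) * d[tips[i], tips[j]]
  total
}

#' Read and write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that validate
#' the parse and error on malformed input.
#'
#' @param path file path.
#' @param tree an [ape::phylo] object.
#' @param ... passed to the underlying ape function.
#' @return `read_newick` returns a `phylo`; `write_newick` returns `path`
#'   invisibly.
#' @export
read_newick <- function(path, ...) {
  tr <- tryCatch(ape::read.tree(path, ...),
                 error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr))
    stop("malformed Newick in '", path, "'")
  tr
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path, ...) {
  ape::write.tree(tree, file = path, ...)
  invisible(path)
}
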