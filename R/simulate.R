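#' Random unrooted binary tree
#'
#' Topologies are drawn uniformly (random sequential addition, via
#' [ape::rtopology()]); branch lengths are independent exponentials with the
#' given mean, a simple stand-in for the branch-length variation of real
#' protein-family trees.
#'
#' @param n_taxa number of leaves, >= 4.
#' @param branch_mean mean branch length in expected substitutions per site.
#' @param seed optional integer seed.
#' @return An unrooted binary [ape::phylo] with tips `t1..tn`.
#' @export
random_tree <- function(n_taxa, branch_mean = 0.3, seed = NULL) {
  if (n_taxa < 4L) stop("n_taxa must be >= 4")
  if (branch_mean <= 0) stop("branch_mean must be > 0")
  with_seed(seed,
    ape::rtopology(n_taxa, rooted = FALSE,
                   br = function(n) rexp(n, rate = 1 / branch_mean)))
}

# Reversible rate matrix on the 20 amino acids, normalised to one expected
# substitution per site per unit branch length. Stationary frequencies are
# uniform; exchangeabilities come from BLOSUM62 log-odds (2^(B/2), the
# matrix being in half-bits) or are flat.
aa_rate_matrix <- function(model = c("blosum", "flat")) {
  model <- match.arg(model)
  R <- switch(model,
    blosum = 2^(blosum62() / 2),
    flat = matrix(1, 20L, 20L, dimnames = list(.STD_AA, .STD_AA)))
  pi <- rep(1 / 20, 20L)
  Q <- R * rep(pi, each = 20L)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q / sum(-pi * diag(Q))
}

# Discrete-gamma site-rate categories (mean 1), equal-probability bins
# represented by their median rates, renormalised to mean 1.
gamma_rates <- function(shape, k) {
  if (is.null(shape) || !is.finite(shape)) return(1)
  q <- stats::qgamma((seq_len(k) - 0.5) / k, shape = shape, rate = shape)
  q / mean(q)
}

#' Evolve protein sequences along a tree
#'
#' Simulates a continuous-time substitution process along every branch of a
#' known tree: the root sequence is drawn from the stationary composition,
#' and each branch applies the transition matrix `expm(Q * t * r_s)` with
#' `t` the branch length and `r_s` an optional per-site discrete-gamma rate
#' multiplier. Branch lengths are in expected substitutions per site at
#' rate 1. No indels are introduced, matching the gap-free input contract
#' of the downstream method.
#'
#' @param tree a [ape::phylo] with branch lengths.
#' @param length sequence length in residues.
#' @param model `"blosum"` (BLOSUM62-derived exchangeabilities, default) or
#'   `"flat"`.
#' @param rate_shape shape of the gamma distribution of site rates
#'   (smaller = stronger heterogeneity); `NULL` or `Inf` for equal rates.
#' @param rate_categories number of discrete gamma categories (default 4).
#' @param seed optional integer seed.
#' @return A [seq_set()] of leaf sequences named by the tree's tip labels.
#' @export
evolve_sequences <- function(tree, length = 300L,
                             model = c("blosum", "flat"),
                             rate_shape = 1, rate_categories = 4L,
                             seed = NULL) {
  stopifnot(inherits(tree, "phylo"), length >= 1L)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  Q <- aa_rate_matrix(match.arg(model))
  eig <- eigen(Q, symmetric = TRUE)   # symmetric under uniform frequencies
  pmat <- function(t) {
    P <- eig$vectors %*% (exp(eig$values * t) * t(eig$vectors))
    P[P < 0] <- 0
    P / rowSums(P)
  }
  rates <- gamma_rates(rate_shape, rate_categories)
  with_seed(seed, {
    site_cat <- sample.int(length(rates), length, replace = TRUE)
    n_tip <- ape::Ntip(tree)
    root <- n_tip + 1L
    states <- matrix(NA_integer_, n_tip + tree$Nnode, length)
    states[root, ] <- sample.int(20L, length, replace = TRUE)
    ord <- rev(ape::postorder(tree))    # parents before children
    for (k in ord) {
      par <- tree$edge[k, 1L]; chd <- tree$edge[k, 2L]
      t_e <- tree$edge.length[k]
      for (cat in seq_along(rates)) {
        at <- which(site_cat == cat)
        if (!length(at)) next
        if (t_e * rates[cat] == 0) {
          states[chd, at] <- states[par, at]
          next
        }
        P <- pmat(t_e * rates[cat])
        for (a in unique(states[par, at])) {
          pos <- at[states[par, at] == a]
          states[chd, pos] <- sample.int(20L, length(pos), replace = TRUE,
                                         prob = P[a, ])
        }
      }
    }
    res <- apply(states[seq_len(n_tip), , drop = FALSE], 1L,
                 function(s) paste(.STD_AA[s], collapse = ""))
    seq_set(setNames(res, tree$tip.label))
  })
}

#' Simulate a protein family with a known reference tree
#'
#' Draws a random tree ([random_tree()]) and evolves sequences along it
#' ([evolve_sequences()]), giving a test family whose true topology is
#' known, so topology recovery and comparison metrics can be exercised
#' end-to-end without external data.
#'
#' @param n_taxa number of sequences (>= 4; default 12).
#' @param length sequence length (default 300 residues).
#' @param branch_mean mean branch length (default 0.3 substitutions/site).
#' @param seed optional integer seed.
#' @param ... further arguments to [evolve_sequences()].
#' @return A list of class `sim_family`: `seqs` (a [seq_set()]) and `tree`
#'   (the generating [ape::phylo]).
#' @export
simulate_family <- function(n_taxa = 12L, length = 300L, branch_mean = 0.3,
                            seed = NULL, ...) {
  with_seed(seed, {
    tree <- random_tree(n_taxa, branch_mean)
    seqs <- evolve_sequences(tree, length = length, ...)
    structure(list(seqs = seqs, tree = tree), class = "sim_family")
  })
}

#' @export
print.sim_family <- function(x, ...) {
  cat("Simulated protein family:", length(x$seqs), "sequences of",
      nchar(x$seqs[[1L]]), "residues on a known tree\n")
  invisible(x)
}
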