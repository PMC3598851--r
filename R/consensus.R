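#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge of an unrooted tree splits the leaves into two blocks;
#' trivial splits (one leaf against the rest) are excluded. Splits are
#' returned as canonical keys — the block not containing the
#' lexicographically smallest leaf, sorted and comma-joined — so two trees'
#' split sets can be compared as string sets. Any rooting in the input is
#' discarded.
#'
#' @param tree an [ape::phylo] tree.
#' @return Character vector of canonical split keys (possibly empty).
#' @export
bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  ref <- tips[1L]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(idx) {
    blk <- labs[idx]
    if (ref %in% blk) blk <- setdiff(tips, blk)
    if (length(blk) <= 1L || length(blk) >= length(tips) - 1L)
      return(NA_character_)
    paste(sort(blk), collapse = ",")
  }, character(1))
  unique(keys[!is.na(keys)])
}

#' Majority-rule consensus of replicate trees
#'
#' Returns the tree containing exactly the bipartitions present in strictly
#' more than half of the input trees (an exact 50% split is excluded).
#' Majority bipartitions are pairwise compatible, so the result is always a
#' tree, though possibly multifurcating. Node labels carry each retained
#' split's support frequency.
#'
#' @param trees a list (or `multiPhylo`) of trees on an identical leaf set.
#' @return An unrooted [ape::phylo] consensus tree.
#' @export
majority_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) < 1L) stop("need at least one tree")
  sets <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(sets, identical, logical(1), y = sets[[1L]])))
    stop("trees must share an identical leaf set")
  if (length(trees) == 1L) return(ape::unroot(trees[[1L]]))
  class(trees) <- "multiPhylo"
  ape::unroot(ape::consensus(trees, p = 0.5, rooted = FALSE))
}

#' Compare an inferred tree with a reference tree by bipartitions
#'
#' Over the non-trivial bipartition sets: true positives (TP) are splits in
#' both trees; false positives (FP) are in the inferred tree only; false
#' negatives (FN) in the reference only. The Robinson-Foulds distance is
#' `FP + FN`; precision is `TP/(TP+FP)` and recall `TP/(TP+FN)`, the
#' reference taken as truth. A ratio with a zero denominator (e.g. precision
#' of a star tree) is reported as 1 with its `*_defined` flag set to FALSE.
#'
#' @param inferred,reference [ape::phylo] trees on the same leaf set.
#' @return An object of class `tree_comparison`: `tp`, `fp`, `fn`, `rf`,
#'   `precision`, `recall`, `precision_defined`, `recall_defined`.
#' @export
compare_trees <- function(inferred, reference) {
  if (!setequal(inferred$tip.label, reference$tip.label))
    stop("trees must share an identical leaf set")
  bi <- bipartitions(inferred)
  br <- bipartitions(reference)
  tp <- length(intersect(bi, br))
  fp <- length(setdiff(bi, br))
  fn <- length(setdiff(br, bi))
  structure(list(
    tp = tp, fp = fp, fn = fn, rf = fp + fn,
    precision = if (tp + fp > 0) tp / (tp + fp) else 1,
    recall    = if (tp + fn > 0) tp / (tp + fn) else 1,
    precision_defined = tp + fp > 0,
    recall_defined    = tp + fn > 0),
    class = "tree_comparison")
}

#' @export
print.tree_comparison <- function(x, ...) {
  cat(sprintf("Bipartition comparison: TP %d  FP %d  FN %d  RF %d\n",
              x$tp, x$fp, x$fn, x$rf))
  cat(sprintf("  precision %.3f%s  recall %.3f%s\n",
              x$precision, if (x$precision_defined) "" else " (undefined)",
              x$recall, if (x$recall_defined) "" else " (undefined)"))
  invisible(x)
}

#' Fit the mean-RF-vs-theta curve and locate its minimum
#'
#' Fits a polynomial of the given degree to mean Robinson-Foulds distances
#' observed over a grid of Gamma scale values and returns the minimiser of
#' the fitted curve over the grid interval. A flat fitted curve (range below
#' `tol`) returns the interval lower bound with a tie warning.
#'
#' @param theta numeric grid of Gamma scale values.
#' @param mean_rf mean RF distance at each grid point.
#' @param degree polynomial degree (default 4).
#' @param tol flatness tolerance on the fitted range.
#' @return A list: `theta_opt`, `fit` (the `lm`), `fitted_min`.
#' @export
fit_rf_curve <- function(theta, mean_rf, degree = 4L, tol = 1e-8) {
  stopifnot(length(theta) == length(mean_rf), degree >= 1L)
  if (length(theta) < degree + 2L)
    stop("need at least degree + 2 = ", degree + 2L, " grid points")
  fit <- lm(mean_rf ~ poly(theta, degree, raw = TRUE))
  f <- function(x) predict(fit, newdata = data.frame(theta = x))
  lo <- min(theta); hi <- max(theta)
  grid <- seq(lo, hi, length.out = 4001L)
  y <- f(grid)
  if (diff(range(y)) < tol) {
    warning("fitted curve is flat over the interval; returning its ",
            "lower bound")
    return(list(theta_opt = lo, fit = fit, fitted_min = y[1L]))
  }
  i <- which.min(y)
  bracket <- c(grid[max(1L, i - 1L)], grid[min(length(grid), i + 1L)])
  opt <- if (bracket[1L] < bracket[2L])
    optimize(f, interval = bracket) else
    list(minimum = grid[i], objective = y[i])
  # the boundary can undercut the interior optimum of the bracket
  cand_x <- c(opt$minimum, lo, hi)
  cand_y <- c(opt$objective, y[1L], y[length(y)])
  k <- which.min(cand_y)
  list(theta_opt = cand_x[k], fit = fit, fitted_min = cand_y[k])
}

#' Calibrate the Gamma scale of the replacement model
#'
#' For each value of the Gamma scale on a grid, runs the full pipeline
#' (perturbed replicates, per-replicate trees, majority-rule consensus) on
#' every test family, scores each consensus against the family's reference
#' tree, and records the mean Robinson-Foulds distance. The per-scale means
#' are then fitted with a polynomial ([fit_rf_curve()]) and the minimiser of
#' the fitted curve over the grid interval is returned. A grid value of 0
#' means no perturbation (equivalent to plain score-based clustering).
#'
#' @param families list of families; each element a list with components
#'   `seqs` (a [seq_set()]) and `tree` (reference [ape::phylo]), as produced
#'   by [simulate_family()].
#' @param theta_grid numeric grid of Gamma scale values (>= 0).
#' @param replicates perturbed replicates per family per scale.
#' @param poly_degree polynomial degree for the fitted curve.
#' @param seed master seed.
#' @param method tree-inference method, see [infer_tree()].
#' @param params an [aligner_params()].
#' @return Object of class `theta_calibration`: `theta_opt`, `table`
#'   (theta, mean_rf, mean_fp, mean_fn), `fit`.
#' @export
calibrate_theta <- function(families, theta_grid, replicates = 100L,
                            poly_degree = 4L, seed = NULL,
                            method = "bme_nni",
                            params = aligner_params()) {
  stopifnot(length(families) >= 1L, all(theta_grid >= 0))
  if (length(theta_grid) < poly_degree + 2L)
    stop("need at least poly_degree + 2 = ", poly_degree + 2L,
         " grid points")
  seeds <- with_seed(seed,
    sample.int(.Machine$integer.max, length(theta_grid)))
  rows <- lapply(seq_along(theta_grid), function(g) {
    th <- theta_grid[g]
    cmps <- lapply(seq_along(families), function(fi) {
      fam <- families[[fi]]
      fit <- dendroblast(fam$seqs, replicates = replicates, theta = th,
                         method = method, params = params,
                         seed = (seeds[g] + fi) %% .Machine$integer.max)
      compare_trees(fit$consensus, fam$tree)
    })
    data.frame(theta = th,
               mean_rf = mean(vapply(cmps, `[[`, numeric(1), "rf")),
               mean_fp = mean(vapply(cmps, `[[`, numeric(1), "fp")),
               mean_fn = mean(vapply(cmps, `[[`, numeric(1), "fn")))
  })
  tab <- do.call(rbind, rows)
  fitres <- fit_rf_curve(tab$theta, tab$mean_rf, degree = poly_degree)
  structure(list(theta_opt = fitres$theta_opt, table = tab,
                 fit = fitres$fit),
            class = "theta_calibration")
}

#' @export
print.theta_calibration <- function(x, ...) {
  cat("Gamma-scale calibration over", nrow(x$table), "grid points\n")
  cat("  optimal theta:", format(x$theta_opt, digits = 5), "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
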