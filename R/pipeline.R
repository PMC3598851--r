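#' Fit an alignment-free tree to a protein family
#'
#' Runs the full inference pipeline on a set of unaligned protein
#' sequences:
#' \enumerate{
#'   \item all-vs-all local-alignment bit scores (internal engine, or a
#'     pre-parsed `raw_scores` object from [parse_blast_tabular()]);
#'   \item missing-score repair, hit-overlap weighting and the
#'     negative-log similarity transform into a distance matrix;
#'   \item a strictly bifurcating guide tree inferred from the unperturbed
#'     distances;
#'   \item `replicates` perturbed copies of the family under the
#'     Gamma/BLOSUM62 replacement model at scale `theta`, one tree per
#'     replicate;
#'   \item the strict majority-rule consensus of the replicate trees, which
#'     discards weakly supported bipartitions.
#' }
#' The run is fully deterministic given `seed`. With `theta = 0` the
#' replicates are unperturbed and the consensus equals the guide tree.
#'
#' @param seqs a [seq_set()], a path to a FASTA file, or a `raw_scores`
#'   object (e.g. parsed blastp output).
#' @param replicates number of perturbed replicates (default 100).
#' @param theta Gamma scale of the replacement model; 0 disables
#'   perturbation. Default 1.9644, the calibrated optimum.
#' @param method tree inference method, see [infer_tree()].
#' @param params an [aligner_params()].
#' @param form hit-overlap weight form, see [overlap_weight()].
#' @param seed master integer seed.
#' @return An object of class `dendroblast` with components `consensus`
#'   (majority-rule consensus tree), `guide` (bifurcating tree from the
#'   unperturbed distances), `dist` (distance matrix), `scores`
#'   (`raw_scores`), `trees` (replicate trees, `multiPhylo`),
#'   `replicate_rf` (RF distance of each replicate tree to the guide tree),
#'   and the run configuration.
#' @examples
#' fam <- simulate_family(n_taxa = 6, length = 120, seed = 1)
#' fit <- dendroblast(fam$seqs, replicates = 10, seed = 1)
#' fit
#' compare_trees(fit$consensus, fam$tree)
#' @export
dendroblast <- function(seqs, replicates = 100L, theta = 1.9644,
                        method = c("bme_nni", "nj"),
                        params = aligner_params(),
                        form = c("dice", "max"), seed = NULL) {
  method <- match.arg(method)
  form <- match.arg(form)
  if (replicates < 1L) stop("replicates must be >= 1")
  if (theta < 0) stop("theta must be >= 0")
  cl <- match.call()

  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs))
    seqs <- read_fasta(seqs)
  scores <- NULL
  if (inherits(seqs, "raw_scores")) {
    if (theta > 0 && replicates > 1L)
      stop("perturbation needs the sequences themselves; pass a seq_set ",
           "(or set theta = 0) when starting from a pre-computed score ",
           "matrix")
    scores <- seqs
    seqs <- NULL
  } else {
    seqs <- as_seq_set(seqs)
    check_min_taxa(seqs)
    scores <- compute_scores_internal(seqs, params)
  }

  d <- to_distance(similarity(fill_missing_scores(scores), form))
  guide <- infer_tree(d, method)

  model <- remap_blosum(theta = theta)
  if (theta == 0 || is.null(seqs)) {
    trees <- rep(list(guide), replicates)
  } else {
    reps <- make_replicates(seqs, model, n = replicates, seed = seed)
    trees <- lapply(reps, function(r)
      infer_tree(blast_distances(r, params, form), method))
  }
  class(trees) <- "multiPhylo"
  cons <- majority_consensus(trees)
  rep_rf <- vapply(trees, function(t) compare_trees(t, guide)$rf,
                   numeric(1))

  structure(list(
    consensus = cons, guide = guide, dist = d, scores = scores,
    trees = trees, replicate_rf = rep_rf, seqs = seqs, model = model,
    replicates = replicates, theta = theta, method = method,
    params = params, form = form, seed = seed, call = cl),
    class = "dendroblast")
}

#' @export
print.dendroblast <- function(x, ...) {
  n <- length(x$consensus$tip.label)
  cat("Alignment-free tree inference (", n, " sequences, ",
      x$replicates, " replicates, theta = ", x$theta, ", ",
      x$method, ")\n", sep = "")
  cat("Consensus tree: ", length(bipartitions(x$consensus)),
      " of ", n - 3L, " possible internal splits retained\n", sep = "")
  cat("Consensus (Newick): ", ape::write.tree(x$consensus), "\n", sep = "")
  invisible(x)
}

#' @export
summary.dendroblast <- function(object, ...) {
  x <- object
  n <- length(x$consensus$tip.label)
  cat("Call: ", deparse(x$call), "\n\n")
  cat("Sequences:      ", n, "\n")
  cat("Replicates:     ", x$replicates, " (theta = ", x$theta, ")\n",
      sep = "")
  cat("Tree method:    ", x$method, "\n")
  cat("Distance range: ", sprintf("%.4f - %.4f",
      min(x$dist[upper.tri(x$dist)]), max(x$dist)), "\n", sep = "")
  cat("Guide tree splits:     ", length(bipartitions(x$guide)), "\n")
  cat("Consensus tree splits: ", length(bipartitions(x$consensus)), "\n")
  cat("Replicate RF to guide: mean ", sprintf("%.2f", mean(x$replicate_rf)),
      ", range ", min(x$replicate_rf), "-", max(x$replicate_rf), "\n",
      sep = "")
  invisible(x)
}

#' @export
plot.dendroblast <- function(x, which = c("consensus", "guide"), ...) {
  which <- match.arg(which)
  tr <- x[[which]]
  ape::plot.phylo(tr, type = "unrooted",
                  main = paste(which, "tree"), ...)
  invisible(x)
}

#' Draw new perturbed replicates from a fitted object
#'
#' Regenerates perturbed copies of the fitted family under the fitted
#' replacement model — useful for inspecting the sequence-change process
#' itself.
#'
#' @param object a `dendroblast` fit built from sequences.
#' @param nsim number of replicate sequence sets.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of [seq_set()] objects.
#' @export
simulate.dendroblast <- function(object, nsim = 1L, seed = NULL, ...) {
  if (is.null(object$seqs))
    stop("fit was built from a pre-computed score matrix; no sequences ",
         "to perturb")
  make_replicates(object$seqs, object$model, n = nsim, seed = seed)
}

#' Write the results of a fitted pipeline run to a directory
#'
#' Writes the consensus tree and the guide tree as Newick, the distance
#' matrix in square PHYLIP format, and a tab-delimited run report
#' (parameters, seed, and per-replicate RF distance to the guide tree), so
#' a run is fully reproducible from its output directory.
#'
#' @param x a `dendroblast` object.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_dendroblast <- function(x, dir) {
  stopifnot(inherits(x, "dendroblast"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(consensus = file.path(dir, "consensus.nwk"),
             guide = file.path(dir, "guide.nwk"),
             dist = file.path(dir, "distances.phylip"),
             report = file.path(dir, "report.tsv"))
  write_newick(x$consensus, paths[["consensus"]])
  write_newick(x$guide, paths[["guide"]])
  write_phylip_dist(x$dist, paths[["dist"]])
  hdr <- c(
    paste0("# replicates\t", x$replicates),
    paste0("# theta\t", x$theta),
    paste0("# method\t", x$method),
    paste0("# overlap_form\t", x$form),
    paste0("# hit_threshold\t", x$params$hit_threshold),
    paste0("# gap_open\t", x$params$gap_open),
    paste0("# gap_extend\t", x$params$gap_extend),
    paste0("# lambda\t", x$params$lambda),
    paste0("# K\t", x$params$K),
    paste0("# seed\t", x$seed %||% "NULL"),
    "replicate\trf_to_guide")
  writeLines(c(hdr, paste(seq_along(x$replicate_rf), x$replicate_rf,
                          sep = "\t")),
             paths[["report"]])
  invisible(paths)
}
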