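#' The 20x20 BLOSUM62 substitution matrix
#'
#' The standard integer BLOSUM62 log-odds matrix restricted to the 20
#' standard amino acids (taken from the copy bundled with Biostrings).
#'
#' @return Integer matrix with amino-acid letters as dimnames.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[.STD_AA, .STD_AA]
  storage.mode(m) <- "integer"
  m
}

#' Remap a substitution matrix into per-row replacement distances
#'
#' Builds the substitution model of the sequence-perturbation scheme. Each
#' row of the substitution matrix is transformed so that its highest-scoring
#' substitution maps to 0 and every other substitution to a positive
#' integer: `Bremap(i,j) = B_max(i) - B(i,j)`. For BLOSUM62 the diagonal is
#' the strict row maximum, so `Bremap(i,i) = 0` for every amino acid — "no
#' change" is the best-scoring replacement. Amino acids sharing one remapped
#' value within a row form a tie group; the replacement is drawn uniformly
#' within the group. Replacement weights follow a Gamma density with shape 1
#' and scale `theta` evaluated at the remapped distance:
#' `f(x; 1, theta) = (1/theta) * exp(-x/theta)`.
#'
#' @param B complete 20x20 integer substitution matrix with amino-acid
#'   dimnames; defaults to [blosum62()].
#' @param theta Gamma scale, > 0 (or 0 for the no-perturbation model).
#'   Default 1.9644, the calibrated optimum of the replacement scheme.
#' @return An object of class `subst_model` with elements `B`, `B_max`,
#'   `remap`, `tie_size` (per-cell size of the tie group the cell belongs
#'   to) and `theta`.
#' @export
remap_blosum <- function(B = blosum62(), theta = 1.9644) {
  if (!is.matrix(B) || nrow(B) != 20L || ncol(B) != 20L ||
      anyNA(B) || is.null(rownames(B)))
    stop("B must be a complete 20x20 substitution matrix with dimnames")
  if (!setequal(rownames(B), .STD_AA) || !setequal(colnames(B), .STD_AA))
    stop("B must cover exactly the 20 standard amino acids")
  if (theta < 0) stop("theta must be >= 0")
  B <- B[.STD_AA, .STD_AA]
  bmax <- apply(B, 1L, max)
  remap <- bmax - B
  tie_size <- t(apply(remap, 1L, function(r) table(r)[as.character(r)]))
  dimnames(tie_size) <- dimnames(remap)
  structure(list(B = B, B_max = bmax, remap = remap,
                 tie_size = tie_size, theta = theta),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat("Gamma/BLOSUM substitution model: theta =", x$theta,
      "(shape fixed at 1)\n")
  cat("Remapped distances span", min(x$remap), "-", max(x$remap),
      "; diagonal all zero:", all(diag(x$remap) == 0), "\n")
  invisible(x)
}

#' Tie group of a row at a remapped distance
#'
#' @param model a `subst_model`.
#' @param i amino-acid letter (row).
#' @param x remapped distance value.
#' @return Character vector of amino acids `j` with `Bremap(i,j) = x`.
#' @export
tie_group <- function(model, i, x) {
  colnames(model$remap)[model$remap[i, ] == x]
}

#' Replacement probability of one amino acid by another
#'
#' The unnormalised replacement weight of `j` for `i` is the Gamma(shape 1,
#' scale theta) density at the remapped distance, split uniformly across the
#' tie group: `f(Bremap(i,j); 1, theta) / |tie_group(i, Bremap(i,j))|`.
#' With `normalized = TRUE` (default) the weights of row `i` are rescaled to
#' sum to 1 over all 20 outcomes (including `j = i`), giving the per-site
#' sampling distribution.
#'
#' @param model a `subst_model` with `theta > 0`.
#' @param i,j amino-acid letters.
#' @param normalized return the row-normalised probability (default) or the
#'   raw density-based weight.
#' @return A probability (or weight).
#' @export
substitution_probability <- function(model, i, j, normalized = TRUE) {
  P <- substitution_probs(model, normalized)
  P[i, j]
}

#' Full per-row replacement distribution
#'
#' @param model a `subst_model` with `theta > 0`.
#' @param normalized row-normalise to proper distributions (default TRUE).
#' @return 20x20 matrix, rows indexed by the current residue.
#' @export
substitution_probs <- function(model, normalized = TRUE) {
  stopifnot(inherits(model, "subst_model"))
  if (model$theta <= 0)
    stop("theta must be > 0 to evaluate replacement probabilities")
  W <- (1 / model$theta) * exp(-model$remap / model$theta) / model$tie_size
  if (normalized) W <- W / rowSums(W)
  W
}

#' Perturb a sequence set under the substitution model
#'
#' Every residue position is independently resampled from its row
#' distribution (see [substitution_probs()]); at the default theta the modal
#' outcome is "no change". Sequence ids and lengths are preserved. Positions
#' holding ambiguity codes (B, Z, X, U) are never mutated. `theta = 0` is
#' the explicit no-perturbation model: the input is returned unchanged.
#'
#' @param seqs a [seq_set()].
#' @param model a `subst_model`.
#' @param seed optional integer seed; the result is deterministic given the
#'   seed, and the caller's RNG state is left untouched.
#' @return A perturbed [seq_set()].
#' @export
perturb <- function(seqs, model = remap_blosum(), seed = NULL) {
  seqs <- as_seq_set(seqs)
  stopifnot(inherits(model, "subst_model"))
  if (model$theta == 0) return(seqs)
  P <- substitution_probs(model)
  with_seed(seed, {
    lens <- nchar(seqs)
    res <- strsplit(paste(unclass(seqs), collapse = ""), "")[[1]]
    code <- match(res, .STD_AA)           # NA for ambiguity codes
    for (i in seq_along(.STD_AA)) {
      at <- which(code == i)
      if (length(at))
        res[at] <- .STD_AA[sample.int(20L, length(at), replace = TRUE,
                                      prob = P[i, ])]
    }
    ends <- cumsum(lens)
    starts <- c(1L, head(ends, -1L) + 1L)
    out <- substring(paste(res, collapse = ""), starts, ends)
    seq_set(setNames(out, names(seqs)))
  })
}

#' Generate perturbed replicate sequence sets
#'
#' Creates `n` independent perturbed copies of the input family, each with
#' its own set of randomly introduced sequence changes. Replicate `k` uses a
#' seed stream derived reproducibly from the master seed, so the full list
#' is bit-identical across runs given the same seed.
#'
#' @param seqs a [seq_set()].
#' @param model a `subst_model`.
#' @param n number of replicates (default 100).
#' @param seed master integer seed.
#' @return A list of `n` perturbed [seq_set()] objects.
#' @export
make_replicates <- function(seqs, model = remap_blosum(), n = 100L,
                            seed = NULL) {
  if (n < 1L) stop("n must be >= 1")
  seqs <- as_seq_set(seqs)
  subseeds <- with_seed(seed,
    sample.int(.Machine$integer.max, n, replace = FALSE))
  lapply(seq_len(n), function(k) perturb(seqs, model, seed = subseeds[k]))
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}
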