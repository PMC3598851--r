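#' Replace missing (zero) bit scores
#'
#' Every zero off-diagonal entry of the score matrix is replaced by
#' `s_min(A) / 2`, half the smallest non-zero bit score observed for that
#' query: strictly below every observed score, positive so the downstream
#' log stays finite, and rank-preserving. The hit sets are NOT enlarged —
#' repaired entries never count as hits for the overlap weighting.
#'
#' @param m a `raw_scores` object.
#' @return A `raw_scores` object with strictly positive score entries.
#' @export
fill_missing_scores <- function(m) {
  stopifnot(inherits(m, "raw_scores"))
  smin <- s_min(m)
  if (any(is.na(smin) | smin <= 0))
    stop("degenerate input: query with no non-zero scores: ",
         paste(m$ids[is.na(smin) | smin <= 0], collapse = ", "))
  zero <- m$bits == 0
  if (any(zero))
    m$bits[zero] <- (smin / 2)[row(m$bits)[zero]]
  m
}

#' Hit-profile overlap weight between two queries
#'
#' Weights the normalised bit score of a pair by the agreement of their hit
#' profiles. The default Dice form is `2 * n_AB / (n_A + n_B)`, where `n_A`
#' is the number of sequences with a non-zero score under query A and
#' `n_AB` the size of the intersection of the two hit sets; it equals 1
#' exactly at perfect overlap. `form = "max"` uses
#' `n_AB / max(n_A, n_B)` instead.
#'
#' @param m a `raw_scores` object.
#' @param A,B query ids.
#' @param form overlap weight form, `"dice"` (default) or `"max"`.
#' @return A weight in (0, 1]. Zero overlap is an error: with disjoint hit
#'   profiles the inference procedure cannot be completed.
#' @export
overlap_weight <- function(m, A, B, form = c("dice", "max")) {
  stopifnot(inherits(m, "raw_scores"))
  form <- match.arg(form)
  n_a <- sum(m$hits[A, ])
  n_b <- sum(m$hits[B, ])
  n_ab <- sum(m$hits[A, ] & m$hits[B, ])
  if (n_ab == 0L)
    stop("no overlap between the BLAST hits of '", A, "' and '", B,
         "': the inference procedure cannot be completed")
  switch(form,
    dice = 2 * n_ab / (n_a + n_b),
    max  = n_ab / max(n_a, n_b))
}

overlap_weight_matrix <- function(m, form = c("dice", "max")) {
  form <- match.arg(form)
  h <- m$hits * 1
  n_ab <- h %*% t(h)          # |hits(A) intersect hits(B)|
  n_a <- rowSums(m$hits)
  off <- upper.tri(n_ab) | lower.tri(n_ab)
  if (any(n_ab[off] == 0)) {
    bad <- which(n_ab == 0 & off, arr.ind = TRUE)[1L, ]
    stop("no overlap between the BLAST hits of '", m$ids[bad[1L]],
         "' and '", m$ids[bad[2L]],
         "': the inference procedure cannot be completed")
  }
  W <- switch(form,
    dice = 2 * n_ab / outer(n_a, n_a, `+`),
    max  = n_ab / outer(n_a, n_a, pmax))
  dimnames(W) <- list(m$ids, m$ids)
  W
}

#' Symmetric similarity matrix from raw scores
#'
#' Each score is normalised by the query's maximum observed bit score,
#' `shat(A,B) = s(A,B) / s_max(A)`, weighted by the hit-profile overlap
#' `w(A,B)` (see [overlap_weight()]), and symmetrised as the mean of the two
#' directions:
#' `S(A,B) = (w(A,B) * shat(A,B) + w(B,A) * shat(B,A)) / 2`.
#' A mutually top-scoring pair with perfectly overlapping hit profiles gets
#' `S = 1`.
#'
#' @param m a `raw_scores` object; zero entries are repaired first via
#'   [fill_missing_scores()] if any remain.
#' @param form overlap weight form, see [overlap_weight()].
#' @return A symmetric numeric matrix of class `sim_matrix` with entries in
#'   (0, 1].
#' @export
similarity <- function(m, form = c("dice", "max")) {
  stopifnot(inherits(m, "raw_scores"))
  form <- match.arg(form)
  if (any(m$bits[upper.tri(m$bits) | lower.tri(m$bits)] == 0))
    m <- fill_missing_scores(m)
  shat <- m$bits / s_max(m)[row(m$bits)]
  W <- overlap_weight_matrix(m, form)
  ws <- W * shat
  S <- (ws + t(ws)) / 2
  dimnames(S) <- list(m$ids, m$ids)
  if (any(S <= 0) || any(S > 1 + 1e-12))
    stop("internal error: similarity outside (0, 1]")
  S[S > 1] <- 1
  class(S) <- c("sim_matrix", class(S))
  S
}

#' Negative-log transform of similarities into distances
#'
#' `d(A,B) = -log S(A,B)` (natural log), with an exactly zero diagonal.
#' A distance of 0 means the pair is mutually top-scoring with perfect hit
#' overlap. The log base only rescales all distances uniformly and cannot
#' change the inferred topology.
#'
#' @param sm a `sim_matrix` from [similarity()].
#' @return A symmetric, zero-diagonal, finite, non-negative distance matrix.
#' @export
to_distance <- function(sm) {
  if (any(sm <= 0 | sm > 1))
    stop("internal error: similarities must lie in (0, 1]")
  d <- -log(unclass(sm))
  diag(d) <- 0
  d[d <= 0] <- 0   # clears rounding below zero and IEEE negative zero
  d
}

#' One-call distance matrix from sequences or raw scores
#'
#' Convenience wrapper: scores (if given sequences), repairs missing scores,
#' builds the similarity matrix and applies the negative-log transform.
#'
#' @param x a [seq_set()] or a `raw_scores` object.
#' @param params an [aligner_params()] (used only when `x` is a sequence set).
#' @param form overlap weight form, see [overlap_weight()].
#' @return A symmetric distance matrix with sequence ids as dimnames.
#' @export
blast_distances <- function(x, params = aligner_params(),
                            form = c("dice", "max")) {
  m <- if (inherits(x, "raw_scores")) x else
    compute_scores_internal(as_seq_set(x), params)
  to_distance(similarity(fill_missing_scores(m), match.arg(form)))
}

#' Read/write a square PHYLIP distance matrix
#'
#' Relaxed-name square PHYLIP format: a count line, then one row per taxon
#' (`name d1 d2 ...`, whitespace-separated, names up to the first
#' whitespace), for interoperability with external minimum-evolution
#' programs.
#'
#' @param d symmetric numeric matrix with taxon ids as dimnames.
#' @param path file path.
#' @return `write_phylip_dist` returns `path` invisibly; `read_phylip_dist`
#'   returns the matrix.
#' @export
write_phylip_dist <- function(d, path) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), !is.null(rownames(d)))
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i)
               paste(c(rownames(d)[i],
                       formatC(d[i, ], format = "g", digits = 10)),
                     collapse = "  "),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || length(lines) != n + 1L)
    stop("malformed PHYLIP distance file: expected ", n, " rows")
  ids <- character(n)
  d <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(f) != n + 1L)
      stop("malformed PHYLIP distance row ", i)
    ids[i] <- f[1L]
    d[i, ] <- as.numeric(f[-1L])
  }
  dimnames(d) <- list(ids, ids)
  d
}
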