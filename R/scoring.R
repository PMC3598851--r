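#' Aligner and bit-score parameters
#'
#' Parameters for the internal local-alignment engine. Raw Smith-Waterman
#' scores under `matrix` with affine gap penalties are converted to bit
#' scores with the Karlin-Altschul transform
#' `bits = (lambda * raw - ln K) / ln 2`. The defaults are the standard
#' gapped blastp regime for BLOSUM62 with gap open 11 / extend 1
#' (lambda = 0.267, K = 0.041). An ordered pair counts as a hit when its bit
#' score reaches `hit_threshold`; self-hits are always recorded.
#'
#' @param matrix substitution matrix name resolvable by Biostrings
#'   (default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param lambda,K gapped Karlin-Altschul parameters for the scoring system.
#' @param hit_threshold minimum bit score for a non-self pair to count as a
#'   hit (default 15 bits). With an exhaustive aligner every pair has some
#'   score, so the threshold reproduces the hit/no-hit structure of a
#'   database search.
#' @return A list of class `aligner_params`.
#' @export
aligner_params <- function(matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1, lambda = 0.267, K = 0.041,
                           hit_threshold = 15) {
  stopifnot(gap_open >= 0, gap_extend >= 0, lambda > 0, K > 0,
            hit_threshold >= 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K,
                 hit_threshold = hit_threshold),
            class = "aligner_params")
}

#' Convert a raw local-alignment score to bits
#' @param raw raw alignment score(s).
#' @param params an [aligner_params()].
#' @return Bit score(s).
#' @export
bit_score <- function(raw, params = aligner_params()) {
  (params$lambda * raw - log(params$K)) / log(2)
}

new_raw_scores <- function(bits, hits, ids) {
  dimnames(bits) <- dimnames(hits) <- list(ids, ids)
  structure(list(ids = ids, bits = bits, hits = hits),
            class = "raw_scores")
}

#' @export
print.raw_scores <- function(x, ...) {
  n <- length(x$ids)
  cat("Raw bit-score matrix:", n, "sequences,",
      sum(x$hits) - n, "non-self hits of", n * (n - 1L), "ordered pairs\n")
  invisible(x)
}

#' Per-query score extrema and hit counts
#'
#' `s_min`/`s_max` are the minimum non-zero and maximum bit scores observed
#' for each query over its hit set (self-hit included); `n_hits` is the hit
#' count per query.
#'
#' @param m a `raw_scores` object.
#' @return A named numeric (or integer) vector indexed by query id.
#' @export
s_min <- function(m) {
  apply_rows(m, function(b, h) if (any(h)) min(b[h]) else NA_real_)
}

#' @rdname s_min
#' @export
s_max <- function(m) {
  apply_rows(m, function(b, h) if (any(h)) max(b[h]) else NA_real_)
}

#' @rdname s_min
#' @export
n_hits <- function(m) {
  setNames(rowSums(m$hits), m$ids)
}

apply_rows <- function(m, f) {
  out <- vapply(seq_along(m$ids),
                function(i) f(m$bits[i, ], m$hits[i, ]), numeric(1))
  setNames(out, m$ids)
}

#' Compute all-vs-all bit scores with the internal alignment engine
#'
#' Scores every ordered pair of sequences by Smith-Waterman local alignment
#' (exhaustive, so scores approximate but do not equal heuristic blastp
#' output) and converts raw scores to bits. Entries whose bit score falls
#' below `params$hit_threshold` are recorded as zero (no hit); the self-score
#' is always recorded and always a hit.
#'
#' @param seqs a [seq_set()].
#' @param params an [aligner_params()].
#' @return A `raw_scores` object: bit-score matrix (queries in rows), hit
#'   indicator matrix, and the sequence ids.
#' @export
compute_scores_internal <- function(seqs, params = aligner_params()) {
  seqs <- as_seq_set(seqs)
  n <- length(seqs)
  ids <- names(seqs)
  aa <- Biostrings::AAStringSet(unclass(seqs))
  raw <- matrix(0, n, n)
  # raw SW score is symmetric in its arguments: fill the upper triangle only
  for (i in seq_len(n)) {
    raw[i, i:n] <- Biostrings::pairwiseAlignment(
      pattern = aa[i:n], subject = aa[[i]], type = "local",
      substitutionMatrix = params$matrix,
      gapOpening = params$gap_open, gapExtension = params$gap_extend,
      scoreOnly = TRUE)
    raw[i:n, i] <- raw[i, i:n]
  }
  bits <- bit_score(raw, params)
  hits <- bits >= params$hit_threshold
  diag(hits) <- TRUE
  bits[!hits] <- 0
  if (any(diag(bits) <= 0))
    stop("internal error: non-positive self bit score for ",
         paste(ids[diag(bits) <= 0], collapse = ", "))
  new_raw_scores(bits, hits, ids)
}

#' Parse blastp tabular output into a raw score matrix
#'
#' Reads an outfmt-6-like file (query id, subject id, bit score; extra
#' columns ignored), keeping the best bit score per ordered pair. Pairs
#' absent from the file are zero (no hit). Asymmetry between `(A,B)` and
#' `(B,A)` is preserved.
#'
#' @param path path to the tabular file.
#' @param ids character vector of all sequence ids the matrix must cover.
#' @return A `raw_scores` object.
#' @export
parse_blast_tabular <- function(path, ids) {
  if (!file.exists(path)) stop("file not found: ", path)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate ids")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("no data rows in ", path)
  n <- length(ids)
  bits <- matrix(0, n, n, dimnames = list(ids, ids))
  for (ln in seq_along(lines)) {
    f <- strsplit(trimws(lines[ln]), "[\t ]+")[[1]]
    if (length(f) < 3L)
      stop("malformed line ", ln, ": fewer than 3 columns")
    # blastp -outfmt 6 puts the bit score in the last column; a minimal
    # 3-column file puts it third -- both resolve to the last field when
    # only qseqid/sseqid/bitscore are present, so take column 3 for minimal
    # files and the final column for full outfmt 6 (12 fields)
    sc <- suppressWarnings(as.numeric(
      if (length(f) >= 12L) f[length(f)] else f[3L]))
    if (is.na(sc) || sc < 0)
      stop("malformed line ", ln, ": bit score '",
           if (length(f) >= 12L) f[length(f)] else f[3L],
           "' is not a non-negative number")
    if (!f[1L] %in% ids) stop("unknown query id '", f[1L], "' on line ", ln)
    if (!f[2L] %in% ids) stop("unknown subject id '", f[2L], "' on line ", ln)
    bits[f[1L], f[2L]] <- max(bits[f[1L], f[2L]], sc)
  }
  if (any(diag(bits) <= 0))
    stop("no self-hit recorded for: ",
         paste(ids[diag(bits) <= 0], collapse = ", "))
  hits <- bits > 0
  new_raw_scores(bits, hits, ids)
}
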