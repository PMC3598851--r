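#' Construct a protein sequence set
#'
#' A sequence set is the package's container for an unaligned protein family:
#' a named character vector of residue strings with class `"seq_set"`.
#' Gap characters (`-`, `.`) are stripped so aligned input can be used as an
#' unaligned family; ids must be unique and non-empty; residues are restricted
#' to the 20 standard amino-acid letters plus the tolerated ambiguity codes
#' B, Z, X and U.
#'
#' Ids containing characters unsafe in Newick labels (whitespace, parentheses,
#' colons, commas, semicolons, quotes) are rewritten with underscores; the
#' original-to-sanitised mapping is kept in the `"id_map"` attribute and a
#' warning is raised.
#'
#' @param residues character vector of residue strings.
#' @param ids character vector of ids; defaults to `names(residues)`.
#' @return An object of class `seq_set`.
#' @export
seq_set <- function(residues, ids = names(residues)) {
  if (length(residues) == 0L)
    stop("sequence set is empty")
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    stop("every sequence needs a non-empty id")
  ids <- as.character(ids)
  residues <- toupper(gsub("[-.]", "", as.character(residues)))
  if (any(!nzchar(residues)))
    stop("zero-length sequence after gap stripping: ",
         paste(ids[!nzchar(residues)], collapse = ", "))
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ok <- paste0("^[", paste(c(.STD_AA, .AMBIG_AA), collapse = ""), "]+$")
  bad <- !grepl(ok, residues)
  if (any(bad))
    stop("non-amino-acid characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  clean <- gsub("[][\\s():;,'\"]+", "_", ids, perl = TRUE)
  id_map <- NULL
  if (!identical(clean, ids)) {
    id_map <- data.frame(original = ids, sanitised = clean,
                         stringsAsFactors = FALSE)
    warning("sanitised ", sum(clean != ids),
            " id(s) containing Newick-unsafe characters")
    if (anyDuplicated(clean))
      stop("id sanitisation produced duplicate ids")
    ids <- clean
  }
  structure(setNames(residues, ids), class = "seq_set", id_map = id_map)
}

#' @export
print.seq_set <- function(x, ...) {
  cat("Protein sequence set:", length(x), "sequences, lengths",
      min(nchar(x)), "-", max(nchar(x)), "\n")
  show <- head(seq_along(x), 6L)
  for (i in show)
    cat(sprintf("  %-20s %s%s\n", names(x)[i],
                substr(x[[i]], 1L, 50L),
                if (nchar(x[[i]]) > 50L) "..." else ""))
  if (length(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' @export
`[.seq_set` <- function(x, i) {
  seq_set(unclass(x)[i])
}

#' Read a protein FASTA file
#'
#' Records are read in file order; gap characters are stripped on ingest so
#' that aligned families can be used directly. The id is the header up to the
#' first whitespace. Duplicate ids, empty files and residues outside the
#' 20 standard letters plus B/Z/X/U are errors.
#'
#' @param path path to a FASTA file (wrapped or unwrapped).
#' @return A [seq_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aa <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("cannot parse FASTA '", path, "': ",
                             conditionMessage(e)))
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(aa))
  seq_set(as.character(aa), ids)
}

#' Write a sequence set to FASTA
#'
#' @param seqs a [seq_set()].
#' @param path output path.
#' @param width line-wrap width in residues (default 80).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  seqs <- as_seq_set(seqs)
  con <- tryCatch(suppressWarnings(file(path, "w")),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing"))
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

as_seq_set <- function(x) {
  if (inherits(x, "seq_set")) return(x)
  if (is.character(x) && !is.null(names(x))) return(seq_set(x))
  stop("expected a seq_set or a named character vector")
}

#' @keywords internal
check_min_taxa <- function(seqs, n = 4L) {
  if (length(seqs) < n)
    stop("fewer than ", n, " sequences: tree inference needs ", n,
         " or more")
  invisible(seqs)
}
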