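#' Read protein sequences from FASTA
#'
#' Thin wrapper over Biostrings with validation: records must be
#' non-empty and use the 20 standard one-letter codes (plus X for unknown
#' residues). Lower-case input is upper-cased.
#'
#' @param path FASTA file.
#' @return data.frame of class `fasta_records` with columns `id`
#'   (first word of the header), `description` (full header), `sequence`,
#'   `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validate_fasta_text(path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  seqs <- toupper(as.character(set))
  headers <- names(set)
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L) {
      stop("empty sequence in record '", headers[i], "'")
    }
  }
  out <- data.frame(
    id = vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L),
    description = headers,
    sequence = unname(seqs),
    length = nchar(seqs),
    stringsAsFactors = FALSE
  )
  class(out) <- c("fasta_records", "data.frame")
  out
}

# Biostrings drops unknown letters silently; validate the raw text first
# so illegal residues are reported with their 1-based position in the
# record.
validate_fasta_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  record <- NULL
  offset <- 0L
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      record <- sub("^>", "", ln)
      offset <- 0L
      next
    }
    if (is.null(record) && nzchar(trimws(ln))) {
      stop("not FASTA: sequence text before the first '>' header")
    }
    chunk <- toupper(gsub("[\\s*]", "", ln, perl = TRUE))
    bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWYX]", chunk)
    if (bad > 0L) {
      stop("illegal residue character '", substr(chunk, bad, bad),
           "' at position ", offset + bad, " of record '", record, "'")
    }
    offset <- offset + nchar(chunk)
  }
  invisible(TRUE)
}

#' Find a sequence motif
#'
#' Searches a one-letter amino-acid sequence for a motif pattern written
#' with residue letters and `X` as a single-residue wildcard (e.g. the
#' acyltransferase catalytic motif `HXXXXD`). Overlapping matches are
#' reported; positions are 1-based, matching biological residue-numbering
#' convention.
#'
#' @param sequence one-letter amino-acid string (or a single-row
#'   `fasta_records`).
#' @param pattern motif pattern, residue letters plus `X` wildcards.
#' @return integer vector of 1-based match start positions (possibly
#'   empty).
#' @export
find_motif <- function(sequence, pattern) {
  if (inherits(sequence, "fasta_records")) {
    stopifnot(nrow(sequence) == 1L)
    sequence <- sequence$sequence
  }
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!is.character(pattern) || length(pattern) != 1L || nchar(pattern) == 0L) {
    stop("pattern must be a non-empty string")
  }
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", pattern)) {
    stop("pattern may use amino-acid letters and X wildcards only")
  }
  rx <- gsub("X", ".", pattern, fixed = TRUE)
  hits <- gregexpr(paste0("(?=", rx, ")"), toupper(sequence),
                   perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' Motif matches across a set of records
#'
#' @param records a `fasta_records` data.frame.
#' @param pattern motif pattern as in [find_motif()].
#' @return data.frame with `id`, `position` (1-based start) and `match`
#'   (the matched subsequence), one row per hit.
#' @export
motif_table <- function(records, pattern) {
  stopifnot(inherits(records, "fasta_records"))
  rows <- lapply(seq_len(nrow(records)), function(i) {
    pos <- find_motif(records$sequence[i], pattern)
    if (length(pos) == 0L) return(NULL)
    data.frame(id = records$id[i], position = pos,
               match = substr(rep(records$sequence[i], length(pos)), pos,
                              pos + nchar(pattern) - 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(id = character(0), position = integer(0),
                      match = character(0))
  }
  out
}
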