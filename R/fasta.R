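#' Protein sequence records
#'
#' A `protein_sequence` is a light container for a single protein chain:
#' an identifier, its one-letter residue string (optionally including the
#' N-terminal mitochondrial target peptide), and the 1-based index of the
#' first mature residue. Clinical variant positions for NDUFV1 are reported
#' on the precursor, while structure files number from the mature N-terminus;
#' keeping `mature_start` explicit on every sequence is what lets the
#' numbering converters stay honest.
#'
#' @param id accession or label, e.g. `"P49821"`.
#' @param residues one-letter amino-acid string; the 20 standard letters plus
#'   `"X"` are allowed.
#' @param mature_start 1-based position of the first mature residue
#'   (1 if the sequence carries no presequence).
#' @return An object of class `protein_sequence`.
#' @export
protein_sequence <- function(id, residues, mature_start = 1L) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(as.character(residues))
  bad <- gsub(paste0("[", AA_ALPHABET, "]"), "", residues)
  if (nzchar(bad)) {
    stop("illegal residue character(s) '", bad, "' in sequence '", id, "'")
  }
  mature_start <- as.integer(mature_start)
  if (is.na(mature_start) || mature_start < 1L || mature_start > nchar(residues)) {
    stop("mature_start must lie in [1, sequence length] for '", id, "'")
  }
  structure(
    list(id = id, residues = residues, mature_start = mature_start),
    class = "protein_sequence"
  )
}

AA_ALPHABET <- "ACDEFGHIKLMNPQRSTVWYX"

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s: %d aa (mature from %d)\n",
              x$id, nchar(x$residues), x$mature_start))
  invisible(x)
}

#' @export
length.protein_sequence <- function(x) nchar(x$residues)

#' Read protein sequences from a FASTA file
#'
#' Parses through [Biostrings::readAAStringSet()] and validates each record
#' against the one-letter amino-acid alphabet (plus `X`). Record order and
#' header ids are preserved; the id is the first whitespace-delimited token
#' of each header.
#'
#' @param path FASTA file path.
#' @param mature_start 1-based first mature residue, recycled across records.
#' @return A list of [protein_sequence()] objects (empty list for an empty
#'   file).
#' @export
read_fasta <- function(path, mature_start = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(list())
  first <- readLines(path, n = 1L)
  if (!startsWith(first, ">")) {
    stop("malformed FASTA (line 1 does not start with '>'): ", path)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  mature_start <- rep_len(as.integer(mature_start), length(seqs))
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    res <- toupper(gsub("[\\*\\s]", "", seqs[[i]], perl = TRUE))
    bad <- gsub(paste0("[", AA_ALPHABET, "]"), "", res)
    if (nzchar(bad)) {
      stop("illegal residue character(s) '", bad, "' in record ", i,
           " ('", ids[[i]], "') of ", path)
    }
    out[[i]] <- protein_sequence(ids[[i]], res, mature_start[[i]])
  }
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs a list of [protein_sequence()] objects.
#' @param path output file path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (inherits(seqs, "protein_sequence")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$id), con)
    n <- nchar(s$residues)
    starts <- seq(1L, n, by = width)
    writeLines(substring(s$residues, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}
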