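#' Global pairwise alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment with BLOSUM62 scoring and affine gap
#' penalties (a gap of length L costs `gap_open + L * gap_extend`), computed
#' with [Biostrings::pairwiseAlignment()]. Identity is the fraction of
#' gap-free columns whose residues are identical; similarity additionally
#' admits pairs with a positive substitution-matrix score — the usual
#' "positives" convention.
#'
#' @param a,b [protein_sequence()] objects (both non-empty).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param matrix substitution matrix name available in \pkg{Biostrings}
#'   (default `"BLOSUM62"`).
#' @return A `pairwise_alignment` list: `id_a`, `id_b`, gapped `aligned_a` /
#'   `aligned_b`, `score`, `identity_fraction`, `similarity_fraction`.
#' @export
align_pair <- function(a, b, gap_open = 10, gap_extend = 1,
                       matrix = "BLOSUM62") {
  stopifnot(inherits(a, "protein_sequence"), inherits(b, "protein_sequence"))
  if (nchar(a$residues) == 0L || nchar(b$residues) == 0L) {
    stop("both sequences must be non-empty")
  }
  submat <- get_submatrix(matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$residues), Biostrings::AAString(b$residues),
    substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global"
  )
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  frac <- alignment_fractions(al_a, al_b, submat)
  structure(
    list(id_a = a$id, id_b = b$id,
         aligned_a = al_a, aligned_b = al_b,
         score = Biostrings::score(pa),
         identity_fraction = frac$identity,
         similarity_fraction = frac$similarity),
    class = "pairwise_alignment"
  )
}

get_submatrix <- function(matrix) {
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  get(matrix, envir = e)
}

alignment_fractions <- function(al_a, al_b, submat) {
  ca <- strsplit(al_a, "")[[1]]
  cb <- strsplit(al_b, "")[[1]]
  both <- ca != "-" & cb != "-"
  n <- sum(both)
  if (n == 0L) return(list(identity = NA_real_, similarity = NA_real_))
  ident <- ca[both] == cb[both]
  ok <- ca[both] %in% rownames(submat) & cb[both] %in% colnames(submat)
  pos <- logical(n)
  pos[ok] <- submat[cbind(ca[both][ok], cb[both][ok])] > 0
  list(identity = sum(ident) / n, similarity = sum(ident | pos) / n)
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s vs %s: score %.1f, identity %.1f%%, similarity %.1f%%\n",
              x$id_a, x$id_b, x$score,
              100 * x$identity_fraction, 100 * x$similarity_fraction))
  invisible(x)
}

#' Residue-number correspondence between two sequences
#'
#' Builds an explicit position map from the gap-free columns of a global
#' alignment. Each side carries a numbering-scheme label; positions are
#' renumbered relative to each sequence's `mature_start` when the scheme is a
#' mature one, so precursor-vs-mature bookkeeping is always explicit. Columns
#' where either side is a gap are absent from the map; positions upstream of
#' a mature start (inside the target peptide) are dropped for mature schemes.
#'
#' @param aln a `pairwise_alignment` from [align_pair()].
#' @param scheme_a,scheme_b free-text scheme labels, e.g.
#'   `"human-precursor"`, `"bovine-mature-structure"`.
#' @param mature_start_a,mature_start_b 1-based first mature residue of each
#'   input sequence; only consulted when the corresponding scheme label
#'   contains `"mature"`.
#' @return A `residue_map` with integer vectors `pos_a`, `pos_b` (strictly
#'   increasing) and the two scheme labels.
#' @export
build_residue_map <- function(aln, scheme_a, scheme_b,
                              mature_start_a = 1L, mature_start_b = 1L) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  ia <- cumsum(ca != "-")
  ib <- cumsum(cb != "-")
  both <- ca != "-" & cb != "-"
  pos_a <- ia[both]
  pos_b <- ib[both]
  if (grepl("mature", scheme_a)) pos_a <- pos_a - as.integer(mature_start_a) + 1L
  if (grepl("mature", scheme_b)) pos_b <- pos_b - as.integer(mature_start_b) + 1L
  keep <- pos_a >= 1L & pos_b >= 1L
  residue_map(pos_a[keep], pos_b[keep], scheme_a, scheme_b)
}

#' Construct a residue map from explicit position pairs
#'
#' @param pos_a,pos_b equal-length strictly increasing integer vectors.
#' @param scheme_a,scheme_b numbering-scheme labels.
#' @return A `residue_map` object.
#' @export
residue_map <- function(pos_a, pos_b, scheme_a, scheme_b) {
  pos_a <- as.integer(pos_a); pos_b <- as.integer(pos_b)
  stopifnot(length(pos_a) == length(pos_b))
  if (length(pos_a) > 1L &&
      (any(diff(pos_a) <= 0L) || any(diff(pos_b) <= 0L))) {
    stop("mapped positions must be strictly increasing in both schemes")
  }
  structure(
    list(pos_a = pos_a, pos_b = pos_b,
         scheme_a = scheme_a, scheme_b = scheme_b),
    class = "residue_map"
  )
}

#' Constant-offset residue map
#'
#' Convenience constructor for two numbering schemes that differ by a fixed
#' offset across a contiguous range, such as the human NDUFV1 precursor and
#' the bovine 51-kDa mature structure numbering, which differ by exactly 20
#' residues (the cleaved mitochondrial target peptide) at every reference
#' position.
#'
#' @param from,to inclusive range of scheme-a positions covered.
#' @param offset `pos_b = pos_a - offset`.
#' @param scheme_a,scheme_b numbering-scheme labels.
#' @return A `residue_map`.
#' @export
offset_residue_map <- function(from, to, offset,
                               scheme_a = "human-precursor",
                               scheme_b = "bovine-mature-structure") {
  pos_a <- seq.int(from, to)
  residue_map(pos_a, pos_a - as.integer(offset), scheme_a, scheme_b)
}

#' Packaged human-precursor to bovine-mature-structure map
#'
#' The bundled reference table shows every human precursor position paired
#' with a bovine structure position exactly 20 residues lower, the length of
#' the human target peptide; this fallback map applies that constant offset
#' across the mature region and is used when full sequences are not
#' supplied.
#'
#' @param length_precursor length of the human precursor (default 464).
#' @return A `residue_map` covering precursor positions 21..`length_precursor`.
#' @export
human_bovine_map <- function(length_precursor = 464L) {
  offset_residue_map(21L, length_precursor, offset = 20L)
}

#' Look up a partner position in a residue map
#'
#' @param map a `residue_map`.
#' @param pos query position (in scheme a for direction `"a2b"`, scheme b for
#'   `"b2a"`).
#' @param direction `"a2b"` or `"b2a"`.
#' @return The partner position as an integer, or `NA_integer_` when the
#'   query residue is aligned to a gap (unmapped).
#' @export
map_position <- function(map, pos, direction = c("a2b", "b2a")) {
  stopifnot(inherits(map, "residue_map"))
  direction <- match.arg(direction)
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L) stop("position must be a positive integer")
  from <- if (direction == "a2b") map$pos_a else map$pos_b
  to <- if (direction == "a2b") map$pos_b else map$pos_a
  i <- match(pos, from)
  if (is.na(i)) NA_integer_ else to[[i]]
}

#' @export
print.residue_map <- function(x, ...) {
  cat(sprintf("<residue_map> %s -> %s: %d mapped positions\n",
              x$scheme_a, x$scheme_b, length(x$pos_a)))
  invisible(x)
}

#' Write a residue map as a two-column TSV
#'
#' The header names the two numbering schemes.
#'
#' @param map a `residue_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_residue_map <- function(map, path) {
  df <- data.frame(a = map$pos_a, b = map$pos_b)
  names(df) <- c(map$scheme_a, map$scheme_b)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
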