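CLADE_LEVELS <- c("chordata", "metazoa", "eukaryota", "all")
CLADE_VOCAB <- c("chordata", "metazoa", "eukaryota", "other")

#' Read a multiple sequence alignment
#'
#' Accepts aligned FASTA (via \pkg{Biostrings}) or single- or multi-block
#' Stockholm. All rows must have equal aligned length.
#'
#' @param path alignment file; Stockholm is detected from the `# STOCKHOLM`
#'   magic line, anything else is treated as FASTA.
#' @return A named character vector of equal-length gapped sequences.
#' @export
read_msa <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  rows <- if (grepl("^# STOCKHOLM", first)) {
    read_stockholm(path)
  } else {
    set <- Biostrings::readBStringSet(path)
    stats::setNames(toupper(as.character(set)), sub("\\s.*$", "", names(set)))
  }
  rows <- gsub("\\.", "-", rows)
  if (length(rows) == 0L) stop("alignment is empty: ", path)
  if (length(unique(nchar(rows))) != 1L) {
    stop("ragged alignment: rows differ in length (", path, ")")
  }
  rows
}

# Minimal Stockholm reader: sequence lines are "<id> <gapped seq>", possibly
# split over several blocks; markup (#=..) and terminator lines are ignored.
read_stockholm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & !grepl("^//", lines) & nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L) stop("malformed Stockholm sequence line: ", ln)
    out[[parts[1]]] <- paste0(out[[parts[1]]] %||% "", toupper(parts[2]))
  }
  unlist(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a clade-annotation table
#'
#' Two-column TSV (`id`, `clade`) assigning each alignment row to one of the
#' nested taxonomic classes `chordata`, `metazoa`, `eukaryota` or `other`.
#' The label records the *innermost* class a species belongs to; membership
#' at broader levels is cumulative (every chordate is also a metazoan, and
#' so on).
#'
#' @param path TSV path with header.
#' @return A `clade_table`: named character vector id -> clade label.
#' @export
read_clade_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("clade table needs columns id, clade: ", path)
  clade_table(stats::setNames(tolower(df[[2]]), df[[1]]))
}

#' @rdname read_clade_table
#' @param x named character vector id -> clade label.
#' @export
clade_table <- function(x) {
  bad <- setdiff(unique(x), CLADE_VOCAB)
  if (length(bad)) {
    stop("unknown clade label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(CLADE_VOCAB, collapse = "/"), ")")
  }
  if (anyDuplicated(names(x))) stop("duplicate sequence ids in clade table")
  structure(x, class = "clade_table")
}

check_msa_clades <- function(msa, clades) {
  missing <- setdiff(names(msa), names(clades))
  if (length(missing)) {
    stop("sequence id(s) absent from clade table: ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Alignment column holding a given reference-sequence position
#'
#' @param msa alignment from [read_msa()].
#' @param ref_id id of the reference row.
#' @param pos 1-based position in the *ungapped* reference sequence.
#' @return 1-based alignment column index.
#' @export
column_for_reference_position <- function(msa, ref_id, pos) {
  if (!ref_id %in% names(msa)) stop("reference id '", ref_id, "' not in MSA")
  chars <- strsplit(msa[[ref_id]], "")[[1]]
  res_idx <- cumsum(chars != "-")
  n <- res_idx[length(res_idx)]
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L || pos > n) {
    stop("position ", pos, " outside ungapped reference length ", n)
  }
  match(pos, res_idx * (chars != "-"))
}

#' Per-clade conserved fractions at one alignment column
#'
#' For each nested level (chordata; metazoa including chordates; eukaryota
#' including all of the above; all rows), the fraction of member rows whose
#' character at the column equals the reference residue. Gaps and `X` count
#' as mismatches. A level with no member rows is returned as `NA`
#' (not evaluable).
#'
#' @param msa alignment from [read_msa()].
#' @param column 1-based alignment column.
#' @param clades a `clade_table` covering every MSA row.
#' @param ref_residue the reference residue (single upper-case letter).
#' @return Named numeric vector of length 4
#'   (`chordata`, `metazoa`, `eukaryota`, `all`), values in `[0, 1]` or `NA`.
#' @export
conservation_fractions <- function(msa, column, clades, ref_residue) {
  check_msa_clades(msa, clades)
  column <- as.integer(column)
  width <- nchar(msa[[1]])
  if (is.na(column) || column < 1L || column > width) {
    stop("column ", column, " outside alignment width ", width)
  }
  chars <- toupper(substr(msa, column, column))
  lab <- unclass(clades)[names(msa)]
  match_ref <- chars == toupper(ref_residue) & !chars %in% c("-", "X", ".")
  member <- list(
    chordata = lab == "chordata",
    metazoa = lab %in% c("chordata", "metazoa"),
    eukaryota = lab %in% c("chordata", "metazoa", "eukaryota"),
    all = rep(TRUE, length(lab))
  )
  vapply(member, function(m) {
    if (!any(m)) NA_real_ else sum(match_ref & m) / sum(m)
  }, numeric(1))
}

#' Conservation-call configuration
#'
#' @param threshold conserved-fraction cutoff; a clade qualifies when its
#'   fraction is strictly greater than this (default 0.95, implementing a
#'   ">95%" rule).
#' @return A `conservation_config` list.
#' @export
conservation_config <- function(threshold = 0.95) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly between 0 and 1")
  }
  structure(list(threshold = threshold), class = "conservation_config")
}

#' Classify a column by its most general conserved clade
#'
#' The call is the broadest nested level (`all` > `eukaryota` > `metazoa` >
#' `chordata`) whose conserved fraction strictly exceeds the threshold, or
#' `"none"` when no level qualifies. `NA` fractions (empty clades) never
#' qualify.
#'
#' @param fractions named vector from [conservation_fractions()].
#' @param cfg a [conservation_config()].
#' @return One of `"none"`, `"chordata"`, `"metazoa"`, `"eukaryota"`,
#'   `"all"`.
#' @export
classify_conservation <- function(fractions, cfg = conservation_config()) {
  stopifnot(all(CLADE_LEVELS %in% names(fractions)))
  for (lvl in rev(CLADE_LEVELS)) {
    f <- fractions[[lvl]]
    if (!is.na(f) && f > cfg$threshold) return(lvl)
  }
  "none"
}

#' Full conservation profile of a reference sequence
#'
#' Applies [conservation_fractions()] and [classify_conservation()] to every
#' ungapped position of the reference row.
#'
#' @param msa alignment from [read_msa()].
#' @param ref_id reference row id.
#' @param clades a `clade_table`.
#' @param cfg a [conservation_config()].
#' @return Data frame: `position`, `ref_residue`, the four fractions, `call`.
#' @export
conservation_profile <- function(msa, ref_id, clades,
                                 cfg = conservation_config()) {
  check_msa_clades(msa, clades)
  if (!ref_id %in% names(msa)) stop("reference id '", ref_id, "' not in MSA")
  chars <- strsplit(msa[[ref_id]], "")[[1]]
  cols <- which(chars != "-")
  res <- lapply(seq_along(cols), function(i) {
    fr <- conservation_fractions(msa, cols[i], clades, chars[cols[i]])
    data.frame(position = i, ref_residue = chars[cols[i]],
               f_chordata = fr[["chordata"]], f_metazoa = fr[["metazoa"]],
               f_eukaryota = fr[["eukaryota"]], f_all = fr[["all"]],
               call = classify_conservation(fr, cfg))
  })
  do.call(rbind, res)
}
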