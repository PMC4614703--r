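#' Parse a protein variant string
#'
#' Accepts the clinical single-letter notation `<ref><position><alt>`, e.g.
#' `"R88G"`, with positions in human precursor numbering by default. A
#' trailing `X` (stop gain, e.g. `"R59X"`) parses but is flagged as
#' unsupported for scoring, since premature terminations are outside the
#' missense scoring scheme.
#'
#' @param text variant string.
#' @param scheme numbering-scheme label attached to the position.
#' @return A `variant`: `ref_aa`, `position`, `alt_aa`, `scheme`,
#'   `scoreable`.
#' @export
parse_variant <- function(text, scheme = "human-precursor") {
  text <- trimws(text)
  m <- regmatches(text, regexec("^([A-Y])([0-9]+)([A-Y*])$", text))[[1]]
  if (length(m) != 4L) {
    stop("malformed variant '", text,
         "': expected <ref><position><alt>, e.g. R88G")
  }
  ref <- m[2]; pos <- as.integer(m[3]); alt <- m[4]
  aa <- strsplit(AA_ALPHABET, "")[[1]]
  if (!ref %in% aa) stop("unknown reference amino acid '", ref, "' in ", text)
  stop_gain <- alt %in% c("X", "*")
  if (!stop_gain && !alt %in% aa) {
    stop("unknown alternate amino acid '", alt, "' in ", text)
  }
  if (!stop_gain && ref == alt) {
    stop("reference and alternate residues are identical in ", text)
  }
  if (pos < 1L) stop("position must be >= 1 in ", text)
  structure(
    list(ref_aa = ref, position = pos, alt_aa = alt, scheme = scheme,
         scoreable = !stop_gain),
    class = "variant"
  )
}

#' @export
format.variant <- function(x, ...) {
  paste0(x$ref_aa, x$position, x$alt_aa)
}

#' @export
print.variant <- function(x, ...) {
  cat(sprintf("<variant> %s (%s%s)\n", format(x), x$scheme,
              if (x$scoreable) "" else "; stop gain, not scoreable"))
  invisible(x)
}

#' Score a variant from the packaged reference table or live resources
#'
#' Orchestrates numbering conversion, distance lookup/computation,
#' conservation lookup/classification and scoring for a single variant.
#' Two resource modes:
#'
#' * **packaged table** (default): distances and conservation come from the
#'   bundled reference table of the 19 clinically reported variants;
#' * **live**: supply a `structure_model`, a residue map from the variant's
#'   numbering scheme to the structure numbering, and an MSA with a clade
#'   table; distances and the conservation call are then computed.
#'
#' @param v a `variant` (or a string passed to [parse_variant()]).
#' @param resources list; either `list(table = reference_table())` (or
#'   empty, which uses the packaged table) or
#'   `list(structure =, structure_map =, msa =, clades =, ref_id =)`.
#' @param cfg a [score_config()].
#' @param cons_cfg a [conservation_config()] (live mode).
#' @return A `variant_report`: the variant, structure residue, yeast
#'   mutation label (packaged mode), distances, conservation call, a
#'   `score_breakdown` (or `NULL` with a `reason`), and per-field
#'   `provenance` ("packaged-table" or "computed").
#' @export
score_variant <- function(v, resources = list(), cfg = score_config(),
                          cons_cfg = conservation_config()) {
  if (is.character(v)) v <- parse_variant(v)
  stopifnot(inherits(v, "variant"))
  if (!v$scoreable) {
    return(variant_report(v, reason = "stop gain: outside the missense scoring scheme"))
  }
  if (!is.null(resources$structure)) {
    score_variant_live(v, resources, cfg, cons_cfg)
  } else {
    score_variant_packaged(v, resources$table %||% reference_table(), cfg)
  }
}

score_variant_packaged <- function(v, tab, cfg) {
  if (nrow(tab) == 0L) stop("reference table is empty")
  i <- match(format(v), tab$variant)
  if (is.na(i)) {
    return(variant_report(v, reason = paste0("variant ", format(v),
                                             " not in the packaged reference table")))
  }
  row <- tab[i, ]
  if (substr(row$variant, 1, 1) != v$ref_aa) {
    stop("reference residue mismatch for ", format(v))
  }
  bd <- total_score(row$d_fmn, row$d_fes, row$conservation, cfg,
                    label = format(v))
  variant_report(v,
                 structure_residue = row$structure_residue,
                 yeast_mutation = row$yeast_mutation,
                 d_fmn = row$d_fmn, d_fes = row$d_fes,
                 conservation = normalize_conservation(row$conservation),
                 score = bd, provenance = "packaged-table")
}

score_variant_live <- function(v, res, cfg, cons_cfg) {
  map <- res$structure_map
  pos_struct <- if (is.null(map)) v$position else map_position(map, v$position)
  if (is.na(pos_struct)) {
    return(variant_report(v, reason = paste0("position ", v$position,
                                             " unmapped in the structure sequence")))
  }
  if (!is.null(res$ref_seq)) {
    found <- substr(res$ref_seq$residues, v$position, v$position)
    if (found != v$ref_aa) {
      stop("reference residue mismatch at position ", v$position,
           ": variant says ", v$ref_aa, ", sequence has ", found)
    }
  }
  d_fmn <- min_distance_to_ligand(res$structure, pos_struct,
                                  res$sel_fmn %||% ligand_selector("FMN"))
  d_fes <- min_distance_to_ligand(res$structure, pos_struct,
                                  res$sel_fes %||% ligand_selector("SF4"))
  call <- "none"
  if (!is.null(res$msa)) {
    col <- column_for_reference_position(res$msa, res$ref_id, v$position)
    fr <- conservation_fractions(res$msa, col, res$clades, v$ref_aa)
    call <- classify_conservation(fr, cons_cfg)
  }
  bd <- total_score(d_fmn, d_fes, call, cfg, label = format(v))
  variant_report(v, structure_residue = pos_struct,
                 d_fmn = d_fmn, d_fes = d_fes, conservation = call,
                 score = bd, provenance = "computed")
}

variant_report <- function(v, structure_residue = NA, yeast_mutation = NA,
                           d_fmn = NA_real_, d_fes = NA_real_,
                           conservation = NA_character_, score = NULL,
                           reason = NA_character_,
                           provenance = NA_character_) {
  structure(
    list(variant = v, structure_residue = structure_residue,
         yeast_mutation = yeast_mutation, d_fmn = d_fmn, d_fes = d_fes,
         conservation = conservation, score = score, reason = reason,
         provenance = provenance),
    class = "variant_report"
  )
}

#' @export
print.variant_report <- function(x, ...) {
  cat(sprintf("<variant_report> %s\n", format(x$variant)))
  if (is.null(x$score)) {
    cat("  no score: ", x$reason, "\n", sep = "")
  } else {
    cat(sprintf("  d_FMN %.1f A, d_FeS %.1f A, conservation %s [%s]\n",
                x$d_fmn, x$d_fes, x$conservation, x$provenance))
    cat(sprintf("  score %d (%s)\n", x$score$total, x$score$class))
  }
  invisible(x)
}

#' @export
as.data.frame.variant_report <- function(x, ...) {
  data.frame(
    variant = format(x$variant),
    structure_residue = as.character(x$structure_residue),
    yeast_mutation = as.character(x$yeast_mutation),
    d_fmn = x$d_fmn, d_fes = x$d_fes,
    conservation = x$conservation,
    total = if (is.null(x$score)) NA_integer_ else x$score$total,
    class = if (is.null(x$score)) NA_character_ else x$score$class,
    reason = x$reason, provenance = x$provenance,
    stringsAsFactors = FALSE
  )
}

#' Score several variants into one report table
#'
#' @param variants character vector of variant strings or list of
#'   `variant`s.
#' @inheritParams score_variant
#' @return Data frame, one row per variant, stable column order (suitable
#'   for deterministic TSV export).
#' @export
score_variants <- function(variants, resources = list(),
                           cfg = score_config(),
                           cons_cfg = conservation_config()) {
  rows <- lapply(variants, function(v)
    as.data.frame(score_variant(v, resources, cfg, cons_cfg)))
  do.call(rbind, rows)
}

#' Re-derive the published scores from the packaged table
#'
#' Recomputes the total score and class for all 19 reference variants from
#' the table's distance and conservation columns and compares them with the
#' printed values. Totals must match exactly; a class mismatch is reported.
#' The table is known to carry one internally inconsistent class label
#' (R147W, printed "mild" at 4 points where the stated boundaries give
#' "none"); that row is reported as a warning rather than a failure.
#'
#' @param tab reference table (default: the packaged one).
#' @param cfg a [score_config()].
#' @param quiet suppress the per-row message lines.
#' @return A `table_validation` list: comparison data frame, counts of
#'   total/class mismatches, and `ok` (no total mismatches).
#' @export
validate_reference_scores <- function(tab = reference_table(),
                                      cfg = score_config(), quiet = FALSE) {
  if (is.null(tab) || nrow(tab) == 0L) stop("reference table is empty")
  recomputed <- mapply(function(d1, d2, cons, lab) {
    bd <- total_score(d1, d2, cons, cfg, label = lab)
    c(total = bd$total, class = bd$class)
  }, tab$d_fmn, tab$d_fes, tab$conservation, tab$variant)
  cmp <- data.frame(
    variant = tab$variant,
    printed_total = tab$printed_score,
    recomputed_total = as.integer(recomputed["total", ]),
    printed_class = tab$printed_class,
    recomputed_class = recomputed["class", ],
    stringsAsFactors = FALSE
  )
  cmp$total_match <- cmp$printed_total == cmp$recomputed_total
  cmp$class_match <- cmp$printed_class == cmp$recomputed_class
  known <- !cmp$class_match & cmp$variant == "R147W" &
    cmp$printed_class == "mild" & cmp$recomputed_class == "none"
  if (any(known)) {
    warning("known published-label discrepancy: R147W printed 'mild' at 4 ",
            "points where the class boundaries give 'none'", call. = FALSE)
  }
  unexplained <- sum(!cmp$class_match & !known)
  if (!quiet) {
    message(sum(cmp$total_match), "/", nrow(cmp), " totals match; ",
            sum(cmp$class_match | known), "/", nrow(cmp),
            " classes match or are known discrepancies")
  }
  structure(
    list(comparison = cmp,
         n_total_mismatch = sum(!cmp$total_match),
         n_class_mismatch = unexplained,
         ok = all(cmp$total_match)),
    class = "table_validation"
  )
}

#' @export
print.table_validation <- function(x, ...) {
  cat(sprintf("<table_validation> %s: %d total mismatches, %d unexplained class mismatches\n",
              if (x$ok) "PASS" else "FAIL",
              x$n_total_mismatch, x$n_class_mismatch))
  invisible(x)
}

#' Write a variant report table as TSV or JSON
#'
#' @param report data frame from [score_variants()].
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    jsonlite::write_json(report, path, dataframe = "rows", na = "string",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
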