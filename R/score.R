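#' Scoring configuration for the disruptive-potential score
#'
#' The score sums three binned components: points for the C-alpha distance
#' to the flavin, points for the distance to the FeS cluster N3, and points
#' for the conservation call. Defaults:
#'
#' * distance bins: `<5` A -> 8, `[5,10)` -> 6, `[10,15)` -> 4,
#'   `[15,20]` -> 2, `>20` -> 0;
#' * conservation: none -> 0, chordata -> 2, metazoa -> 4, eukaryota -> 6,
#'   all -> 8;
#' * class boundaries on the total: `<=5` none, `6-10` mild, `11-15`
#'   impaired, `>=16` strongly impaired.
#'
#' The published ranges leave the exact bin edges ambiguous (5/10/15/20 A
#' appear in two ranges each, and totals 5 and 16 sit between classes); the
#' closure above is the unique one consistent with the reference table,
#' where 10.0 A scores 4 points, 19.8 A scores 2 points, and total 16 is
#' always "strongly impaired". With even point values the ambiguous odd
#' totals are unreachable anyway.
#'
#' @param distance_breaks upper edges of the distance bins (A), ascending.
#' @param distance_points points per bin, one more entry than
#'   `distance_breaks` (last entry = beyond the final edge).
#' @param conservation_points named points for each conservation call.
#' @param class_breaks upper edges of the total-score classes.
#' @param class_labels labels, one more entry than `class_breaks`.
#' @return A `score_config` list.
#' @export
score_config <- function(distance_breaks = c(5, 10, 15, 20),
                         distance_points = c(8, 6, 4, 2, 0),
                         conservation_points = c(none = 0, chordata = 2,
                                                 metazoa = 4, eukaryota = 6,
                                                 all = 8),
                         class_breaks = c(5, 10, 15),
                         class_labels = c("none", "mild", "impaired",
                                          "strongly impaired")) {
  stopifnot(length(distance_points) == length(distance_breaks) + 1L,
            !is.unsorted(distance_breaks, strictly = TRUE),
            length(class_labels) == length(class_breaks) + 1L,
            !is.unsorted(class_breaks, strictly = TRUE))
  structure(
    list(distance_breaks = distance_breaks,
         distance_points = distance_points,
         conservation_points = conservation_points,
         class_breaks = class_breaks,
         class_labels = class_labels),
    class = "score_config"
  )
}

#' Points for a cofactor distance
#'
#' Bin edges are right-open except that the final finite edge is inclusive:
#' with defaults, exactly 20.0 A still earns 2 points because only strictly
#' greater distances fall in the outermost (0-point) bin.
#'
#' @param d distance in Angstrom (vectorised, `>= 0`).
#' @param cfg a [score_config()].
#' @return Integer points per distance.
#' @export
distance_points <- function(d, cfg = score_config()) {
  if (any(!is.finite(d) | d < 0)) stop("distances must be finite and >= 0")
  idx <- findInterval(d, cfg$distance_breaks, left.open = FALSE) + 1L
  # findInterval puts d == last break into the outer bin; pull it back in
  idx[d <= cfg$distance_breaks[length(cfg$distance_breaks)] &
        idx > length(cfg$distance_breaks)] <- length(cfg$distance_breaks)
  as.integer(cfg$distance_points[idx])
}

#' Points for a conservation call
#'
#' Accepts the internal vocabulary (`none`, `chordata`, `metazoa`,
#' `eukaryota`, `all`) as well as the plural spellings used in printed
#' tables (`Chordates`, `Metazoans`, `Eukaryotes`, `All`, `None`).
#'
#' @param call conservation call(s).
#' @param cfg a [score_config()].
#' @return Integer points per call.
#' @export
conservation_points <- function(call, cfg = score_config()) {
  call <- normalize_conservation(call)
  pts <- cfg$conservation_points[call]
  if (any(is.na(pts))) {
    stop("unknown conservation call: ",
         paste(unique(call[is.na(pts)]), collapse = ", "))
  }
  as.integer(unname(pts))
}

#' Normalize conservation labels to the internal vocabulary
#'
#' @param call character vector of calls in either spelling.
#' @return Character vector over `none`/`chordata`/`metazoa`/`eukaryota`/`all`.
#' @export
normalize_conservation <- function(call) {
  lut <- c(none = "none", chordata = "chordata", chordates = "chordata",
           metazoa = "metazoa", metazoans = "metazoa",
           eukaryota = "eukaryota", eukaryotes = "eukaryota",
           all = "all", `all species` = "all")
  out <- lut[tolower(trimws(as.character(call)))]
  if (any(is.na(out))) {
    stop("unknown conservation label: ",
         paste(unique(call[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Predicted-effect class for a total score
#'
#' @param total total score(s), `0 <= total <= 24` with default points.
#' @param cfg a [score_config()].
#' @return Character class per total.
#' @export
classify_score <- function(total, cfg = score_config()) {
  max_total <- 2 * max(cfg$distance_points) + max(cfg$conservation_points)
  if (any(!is.finite(total) | total < 0 | total > max_total)) {
    stop("total score out of range [0, ", max_total, "]")
  }
  cfg$class_labels[findInterval(total, cfg$class_breaks, left.open = TRUE) + 1L]
}

#' Disruptive-potential score of one variant position
#'
#' Sums the two distance components and the conservation component and
#' attaches the predicted-effect class.
#'
#' @param d_fmn,d_fes C-alpha distances to the flavin and the FeS cluster
#'   (Angstrom).
#' @param call conservation call (either vocabulary).
#' @param cfg a [score_config()].
#' @param label optional variant label carried into the result.
#' @return A `score_breakdown`: `label`, `points_fmn`, `points_fes`,
#'   `points_conservation`, `total`, `class`.
#' @export
total_score <- function(d_fmn, d_fes, call, cfg = score_config(),
                        label = NA_character_) {
  p_fmn <- distance_points(d_fmn, cfg)
  p_fes <- distance_points(d_fes, cfg)
  p_con <- conservation_points(call, cfg)
  tot <- p_fmn + p_fes + p_con
  structure(
    list(label = label, points_fmn = p_fmn, points_fes = p_fes,
         points_conservation = p_con, total = tot,
         class = classify_score(tot, cfg)),
    class = "score_breakdown"
  )
}

#' @export
print.score_breakdown <- function(x, ...) {
  lab <- if (is.na(x$label)) "" else paste0(x$label, ": ")
  cat(sprintf("<score_breakdown> %sFMN %d + FeS %d + conservation %d = %d (%s)\n",
              lab, x$points_fmn, x$points_fes, x$points_conservation,
              x$total, x$class))
  invisible(x)
}

#' @export
as.data.frame.score_breakdown <- function(x, ...) {
  data.frame(label = x$label, points_fmn = x$points_fmn,
             points_fes = x$points_fes,
             points_conservation = x$points_conservation,
             total = x$total, class = x$class)
}
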