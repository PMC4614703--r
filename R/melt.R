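#' Default thermal protocol temperature grid
#'
#' One fluorescence reading per 1.5 degree C step starting at 20 degrees C,
#' mirroring an instrument protocol that holds at 20 degrees C and then
#' raises the block temperature by 1.5 degrees C every 30 s.
#'
#' @param t_max top of the ramp in degrees C (default 95).
#' @return Numeric vector of temperatures.
#' @export
melt_temperature_grid <- function(t_max = 95) {
  seq(20, t_max, by = 1.5)
}

# Four-parameter logistic: fluorescence rises from `baseline` by `amplitude`
# as bound flavin dissociates; the steepest slope sits at the midpoint.
logistic4 <- function(temp, baseline, amplitude, midpoint, width) {
  baseline + amplitude / (1 + exp(-(temp - midpoint) / width))
}

#' Simulate a ThermoFMN flavin-dissociation melt curve
#'
#' Evaluates a four-parameter logistic on the thermal-protocol grid and adds
#' i.i.d. Gaussian noise. The default midpoint of 51.9 degrees C is the
#' wild-type flavin dissociation temperature of intact complex I; the
#' amplitude is proportional to the amount of complex-bound flavin.
#'
#' @param t_dissoc dissociation (midpoint) temperature, degrees C.
#' @param amplitude total fluorescence change (arbitrary units, `>= 0`).
#' @param baseline pre-transition fluorescence.
#' @param width logistic width, degrees C (`> 0`).
#' @param noise_sd standard deviation of additive Gaussian noise (`>= 0`).
#' @param seed integer seed; the same seed reproduces the same curve.
#' @param t_max top of the temperature ramp.
#' @return A `melt_curve`: `temperature`, `fluorescence`, and the generating
#'   parameters in `meta`.
#' @export
simulate_melt_curve <- function(t_dissoc = 51.9, amplitude = 1000,
                                baseline = 100, width = 2,
                                noise_sd = 0, seed = 1L, t_max = 95) {
  if (width <= 0) stop("width must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  temp <- melt_temperature_grid(t_max)
  signal <- logistic4(temp, baseline, amplitude, t_dissoc, width)
  if (noise_sd > 0) {
    rng <- local({ set.seed(as.integer(seed)); stats::rnorm(length(temp), 0, noise_sd) })
    signal <- signal + rng
  }
  melt_curve(temp, signal,
             meta = list(t_dissoc = t_dissoc, amplitude = amplitude,
                         baseline = baseline, width = width,
                         noise_sd = noise_sd, seed = seed))
}

#' Construct a melt curve from temperature/fluorescence series
#'
#' @param temperature strictly increasing temperatures (degrees C), length
#'   `>= 8`.
#' @param fluorescence matching fluorescence readings.
#' @param meta optional protocol metadata list.
#' @return A `melt_curve` object.
#' @export
melt_curve <- function(temperature, fluorescence, meta = list()) {
  temperature <- as.numeric(temperature)
  fluorescence <- as.numeric(fluorescence)
  if (length(temperature) != length(fluorescence)) {
    stop("temperature and fluorescence series differ in length")
  }
  if (length(temperature) < 8L) stop("melt curve needs at least 8 readings")
  if (any(diff(temperature) <= 0)) stop("temperatures must be strictly increasing")
  structure(list(temperature = temperature, fluorescence = fluorescence,
                 meta = meta), class = "melt_curve")
}

#' Read a melt curve or kinetic trace from delimited text
#'
#' Two-column delimited file with a header (temperature or time, signal).
#'
#' @param path file path; delimiter auto-detected from the header line
#'   (tab or comma).
#' @return A `melt_curve`.
#' @export
read_melt_curve <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE)
  melt_curve(df[[1]], df[[2]], meta = list(source = basename(path)))
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("<melt_curve> %d readings, %.1f-%.1f degrees C\n",
              length(x$temperature), min(x$temperature), max(x$temperature)))
  invisible(x)
}

#' Fit a sigmoid to a melt curve
#'
#' Least-squares fit of the four-parameter logistic. For a logistic the
#' steepest-slope temperature coincides with the midpoint, so the fitted
#' midpoint is reported as the characteristic dissociation temperature and
#' the fitted amplitude as the total intensity change (proportional to
#' bound flavin). Starting values are taken from the curve extremes and the
#' peak of a smoothed finite-difference derivative, which makes the fit
#' deterministic. Non-convergence (including curves with no transition) is
#' flagged on the result rather than raised.
#'
#' @param curve a `melt_curve`.
#' @return A `melt_fit`: `baseline`, `amplitude`, `t_dissoc`, `width`,
#'   `residual_norm`, `converged`.
#' @export
fit_melt_curve <- function(curve) {
  stopifnot(inherits(curve, "melt_curve"))
  temp <- curve$temperature
  y <- curve$fluorescence
  rng <- range(y)
  start <- list(baseline = rng[1], amplitude = diff(rng),
                midpoint = midpoint_guess(temp, y),
                width = diff(range(temp)) / 20)
  fit <- tryCatch(
    stats::nls(y ~ logistic4(temp, baseline, amplitude, midpoint, width),
               start = start,
               lower = c(baseline = -Inf, amplitude = 0,
                         midpoint = min(temp), width = 1e-3),
               upper = c(baseline = Inf, amplitude = Inf,
                         midpoint = max(temp), width = diff(range(temp))),
               algorithm = "port",
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(list(baseline = rng[1], amplitude = 0,
                          t_dissoc = NA_real_, width = NA_real_,
                          residual_norm = sqrt(sum((y - mean(y))^2)),
                          converged = FALSE),
                     class = "melt_fit"))
  }
  cf <- stats::coef(fit)
  # an amplitude indistinguishable from noise means no transition was seen
  flat <- cf[["amplitude"]] <= 4 * stats::sd(stats::resid(fit))
  structure(
    list(baseline = cf[["baseline"]], amplitude = cf[["amplitude"]],
         t_dissoc = cf[["midpoint"]], width = cf[["width"]],
         residual_norm = sqrt(sum(stats::resid(fit)^2)),
         converged = !flat),
    class = "melt_fit"
  )
}

midpoint_guess <- function(temp, y) {
  dy <- diff(y) / diff(temp)
  if (length(dy) >= 3L) {
    dy <- stats::filter(dy, rep(1 / 3, 3), sides = 2)
  }
  mids <- (temp[-1] + temp[-length(temp)]) / 2
  i <- which.max(abs(dy))
  if (length(i) == 0L || is.na(dy[i])) stats::median(temp) else mids[i]
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("<melt_fit> Td %.2f degrees C, amplitude %.1f, width %.2f (%s)\n",
              x$t_dissoc, x$amplitude, x$width,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Flavin content of a variant relative to wild type
#'
#' The fitted total intensity change is proportional to the amount of
#' complex-bound flavin, so the amplitude ratio estimates the variant's
#' flavin occupancy relative to wild type.
#'
#' @param fit_variant,fit_wt `melt_fit` objects.
#' @return Numeric ratio (variant amplitude / wild-type amplitude).
#' @export
relative_flavin_content <- function(fit_variant, fit_wt) {
  stopifnot(inherits(fit_variant, "melt_fit"), inherits(fit_wt, "melt_fit"))
  if (!is.finite(fit_wt$amplitude) || fit_wt$amplitude <= 0) {
    stop("wild-type amplitude must be positive")
  }
  fit_variant$amplitude / fit_wt$amplitude
}

#' Assay parameters for absorbance-slope to rate conversion
#'
#' @param epsilon extinction coefficient, per-mM per-cm.
#' @param path_length_cm optical path length, cm.
#' @param protein_mg_ml protein concentration, mg/ml.
#' @param sign direction of the absorbance change (+1 or -1); e.g. NADH
#'   consumption gives a negative slope at 340-380 nm.
#' @return An `assay_params` list.
#' @export
assay_params <- function(epsilon, path_length_cm = 1, protein_mg_ml = 1,
                         sign = 1) {
  if (epsilon <= 0 || path_length_cm <= 0 || protein_mg_ml <= 0) {
    stop("epsilon, path length and protein concentration must be positive")
  }
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  structure(list(epsilon = epsilon, path_length_cm = path_length_cm,
                 protein_mg_ml = protein_mg_ml, sign = sign),
            class = "assay_params")
}

#' Specific activity from an absorbance slope
#'
#' Beer-Lambert conversion: an absorbance slope in A/min over a path of
#' `l` cm with extinction coefficient `epsilon` (per-mM per-cm) corresponds
#' to a concentration change of `slope / (epsilon * l)` mM/min =
#' umol/ml/min; dividing by the protein concentration (mg/ml) gives the
#' specific activity in umol/min/mg.
#'
#' @param abs_slope absorbance change per minute (vectorised).
#' @param p an [assay_params()].
#' @return Specific activity, umol/min/mg.
#' @export
rate_from_trace <- function(abs_slope, p) {
  stopifnot(inherits(p, "assay_params"))
  p$sign * abs_slope / (p$epsilon * p$path_length_cm * p$protein_mg_ml)
}
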