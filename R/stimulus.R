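# Pulse parameterization and the deliverable stimulus grid.
#
# All stimuli are charge-balanced, biphasic, anodic-first current pulse
# trains delivered at 120 Hz for 5 s. The cathodic phase is fixed at 100 us;
# the "pulse type" is the duration ratio (anodic width / cathodic width),
# one of 1, 2, 5, 10, 20, indexed 1..5. Charge balance plus the stimulator's
# 1 uA resolution on the long anodic phase force the cathodic amplitude to
# be an integer multiple of the duration ratio.

DURATION_RATIOS <- c(1L, 2L, 5L, 10L, 20L)

#' Default stimulus-grid configuration
#'
#' Amplitudes run `amplitude_lo`..`amplitude_hi` in `amplitude_step` uA steps
#' for duration ratios 1, 2, 5 and 10. For ratio 20 the 1 uA anodic-phase
#' resolution restricts deliverable amplitudes to multiples of 20 uA; those
#' are taken from `ratio20_window` (default: the main window extended by
#' 20 uA at the top), which yields six amplitudes and a 46-point grid for
#' the default 20-110 uA window.
#'
#' @param amplitude_lo,amplitude_hi Cathodic amplitude window in uA.
#' @param amplitude_step Amplitude increment in uA for ratios 1, 2, 5, 10.
#' @param ratios Duration ratios to include.
#' @param ratio20_window Window (uA) from which multiples of 20 are taken
#'   for the ratio-20 type.
#' @return A list of class `stim_config`.
#' @export
stim_config <- function(amplitude_lo = 20, amplitude_hi = 110,
                        amplitude_step = 10, ratios = DURATION_RATIOS,
                        ratio20_window = c(amplitude_lo, amplitude_hi + 20)) {
  stopifnot(amplitude_lo > 0, amplitude_hi >= amplitude_lo,
            amplitude_step > 0, all(ratios %in% DURATION_RATIOS))
  structure(list(amplitude_lo = amplitude_lo, amplitude_hi = amplitude_hi,
                 amplitude_step = amplitude_step, ratios = as.integer(ratios),
                 ratio20_window = ratio20_window),
            class = "stim_config")
}

#' Construct one charge-balanced anodic-first pulse setting
#'
#' The anodic amplitude is `cathodic_amplitude / duration_ratio` and the
#' anodic width `duration_ratio * 100` us, so the two phase charges are
#' equal exactly. The stimulator resolves current in whole uA, so the
#' cathodic amplitude must be divisible by the duration ratio.
#'
#' @param cathodic_amplitude Cathodic phase amplitude in uA (positive,
#'   divisible by `duration_ratio`).
#' @param duration_ratio Anodic/cathodic phase-duration ratio; one of
#'   1, 2, 5, 10, 20.
#' @return An object of class `pulse_params`.
#' @examples
#' p <- make_pulse(100, 5)
#' p$anodic_amplitude_uA   # 20
#' p$anodic_width_us       # 500
#' @export
make_pulse <- function(cathodic_amplitude, duration_ratio) {
  if (length(duration_ratio) != 1 || !(duration_ratio %in% DURATION_RATIOS)) {
    stop(focalstim_error("invalid_ratio", sprintf(
      "duration_ratio must be one of %s (got %s)",
      paste(DURATION_RATIOS, collapse = ", "), format(duration_ratio))))
  }
  if (length(cathodic_amplitude) != 1 || !is.finite(cathodic_amplitude) ||
      cathodic_amplitude <= 0) {
    stop("cathodic_amplitude must be a positive scalar (uA)")
  }
  if (abs(cathodic_amplitude - round(cathodic_amplitude)) > 1e-9 ||
      round(cathodic_amplitude) %% duration_ratio != 0) {
    stop(focalstim_error("resolution_violation", sprintf(
      "cathodic amplitude %g uA is not divisible by duration ratio %d (anodic phase would not be an integer number of uA)",
      cathodic_amplitude, duration_ratio)))
  }
  a <- as.integer(round(cathodic_amplitude))
  r <- as.integer(duration_ratio)
  structure(list(
    cathodic_amplitude_uA = a,
    duration_ratio = r,
    type_index = match(r, DURATION_RATIOS),
    anodic_amplitude_uA = a %/% r,
    cathodic_width_us = 100L,
    anodic_width_us = r * 100L,
    interphase_gap_us = 5L,
    frequency_hz = 120L,
    train_duration_s = 5L,
    polarity = "anodic-first"
  ), class = "pulse_params")
}

#' @export
print.pulse_params <- function(x, ...) {
  cat(sprintf(
    "<pulse_params> type %d (ratio %d): cathodic %d uA x %d us / anodic %d uA x %d us, %d Hz, %d s\n",
    x$type_index, x$duration_ratio, x$cathodic_amplitude_uA,
    x$cathodic_width_us, x$anodic_amplitude_uA, x$anodic_width_us,
    x$frequency_hz, x$train_duration_s))
  invisible(x)
}

#' Deliverable cathodic amplitudes for one duration ratio
#'
#' @keywords internal
deliverable_amplitudes <- function(duration_ratio, config) {
  r <- as.integer(duration_ratio)
  if (r == 20L) {
    w <- config$ratio20_window
    amps <- seq(ceiling(w[1] / 20) * 20, floor(w[2] / 20) * 20, by = 20)
  } else {
    amps <- seq(config$amplitude_lo, config$amplitude_hi,
                by = config$amplitude_step)
    amps <- amps[amps %% r == 0]
  }
  amps[amps > 0]
}

#' Enumerate the experimental stimulus grid
#'
#' Ratio-major (type index ascending), amplitude ascending within a type.
#' The default configuration yields the standard 46 pulse-parameter
#' combinations: ten amplitudes each for ratios 1, 2, 5 and 10, and the six
#' multiples of 20 uA for ratio 20.
#'
#' @param config A [stim_config()].
#' @return An object of class `stim_grid`: list with `pulses` (list of
#'   [make_pulse()] results) and the configuration.
#' @export
build_grid <- function(config = stim_config()) {
  stopifnot(inherits(config, "stim_config"))
  if (config$amplitude_hi < config$amplitude_lo)
    stop("empty amplitude window")
  pulses <- list()
  for (r in config$ratios) {
    for (a in deliverable_amplitudes(r, config)) {
      pulses[[length(pulses) + 1L]] <- make_pulse(a, r)
    }
  }
  key <- vapply(pulses, function(p)
    sprintf("%d:%d", p$type_index, p$cathodic_amplitude_uA), character(1))
  stopifnot(!anyDuplicated(key))
  structure(list(pulses = pulses, config = config,
                 amplitude_window = c(config$amplitude_lo, config$amplitude_hi)),
            class = "stim_grid")
}

#' @export
length.stim_grid <- function(x) length(x$pulses)

#' @export
print.stim_grid <- function(x, ...) {
  cat(sprintf("<stim_grid> %d pulse combinations, amplitudes %g-%g uA, ratios %s\n",
              length(x), x$config$amplitude_lo, x$config$amplitude_hi,
              paste(x$config$ratios, collapse = "/")))
  invisible(x)
}

#' @export
as.data.frame.stim_grid <- function(x, ...) {
  do.call(rbind, lapply(x$pulses, function(p) data.frame(
    type_index = p$type_index,
    duration_ratio = p$duration_ratio,
    cathodic_amplitude_uA = p$cathodic_amplitude_uA,
    anodic_amplitude_uA = p$anodic_amplitude_uA,
    anodic_width_us = p$anodic_width_us)))
}

#' Round a continuous optimizer point to a deliverable stimulus
#'
#' The optimizer works on a continuous (amplitude, type) box; the stimulator
#' delivers only integer-uA amplitudes divisible by the chosen duration
#' ratio. The type coordinate rounds to the nearest type index; the
#' amplitude to the nearest deliverable amplitude for that type (clamped to
#' the configured window).
#'
#' @param a Continuous cathodic amplitude (uA).
#' @param t Continuous type coordinate in `[1, 5]`.
#' @param config A [stim_config()].
#' @return A `pulse_params` object.
#' @export
round_to_deliverable <- function(a, t, config = stim_config()) {
  ti <- as.integer(min(max(round(t), 1L), length(DURATION_RATIOS)))
  r <- DURATION_RATIOS[ti]
  amps <- deliverable_amplitudes(r, config)
  # full deliverable set for this ratio: every multiple of r inside the
  # window, not only the coarse grid amplitudes
  lo <- min(amps); hi <- max(amps)
  a_cl <- min(max(a, lo), hi)
  a_round <- round(a_cl / r) * r
  a_round <- min(max(a_round, lo), hi)
  make_pulse(a_round, r)
}

#' Typed error constructor
#' @keywords internal
focalstim_error <- function(type, message) {
  structure(class = c(paste0("focalstim_", type), "error", "condition"),
            list(message = message, call = sys.call(-1)))
}
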