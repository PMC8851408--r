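# Synthetic retina: heterogeneous regions with known ground-truth response
# surfaces, rendered as calcium-fluorescence recordings.
#
# Each region carries smooth latent surfaces A*(a, t) (activation area,
# um^2) and E*(a, t) (eccentricity) over the amplitude x type box, a
# per-type activation threshold below which there is no response, an axon
# orientation along which elongated responses stretch, and imaging-noise
# levels. Rendering draws a solid elliptical activity footprint (a soma
# blob that elongates into an axonal streak as E* grows) over a noisy
# baseline so that the imaging module recovers (A*, E*).

#' Heterogeneity configuration for synthetic regions
#'
#' Ranges from which per-region latent parameters are drawn. Defaults are
#' chosen to reproduce the qualitative behavior of epiretinal responses:
#' (i) every region responds somewhere inside the default 20-110 uA
#' window; (ii) the dynamic range is narrow — activation area ramps from
#' threshold to well beyond twice the electrode area within a few tens of
#' uA, so desirable small responses occupy only a thin band slightly above
#' threshold; (iii) at high amplitude most responses are large and, with
#' axonal recruitment, increasingly elongated; (iv) across an ensemble all
#' five response classes occur and every region can attain class 1 or 2,
#' while many regions (elongated everywhere) top out at class 2.
#'
#' @param image_side Image side in pixels.
#' @param pixel_size_um Pixel size (um/pixel).
#' @param electrode_diameter_um Disk electrode diameter (um).
#' @param baseline_level Mean baseline fluorescence (camera counts).
#' @param baseline_mult_sd Multiplicative SD of the static baseline pattern.
#' @param frame_noise_sd Additive per-frame noise SD (counts).
#' @param response_dff Peak fractional fluorescence gain inside the active
#'   footprint (well above the 0.15 threshold).
#' @param threshold_range Range of the per-region base activation threshold
#'   (uA).
#' @param threshold_type_slope_range Systematic per-type-index threshold
#'   increase (uA): longer balancing phases change pulse efficacy in a
#'   consistent direction rather than at random.
#' @param threshold_type_jitter Half-width of the residual per-type
#'   threshold jitter (uA).
#' @param area_min_range Range of the threshold-response area (um^2): the
#'   first supra-threshold response recruits a cluster of somata over the
#'   electrode, not an arbitrarily small patch.
#' @param area_max_range Range of the saturating maximum activation area
#'   (um^2).
#' @param area_tau_range Range of the amplitude constant (uA) of the
#'   saturating area ramp.
#' @param ecc_base_range Range of near-threshold eccentricity at type 1.
#' @param ecc_type_slope_range Per-type-index decrease of eccentricity up
#'   to the region's roundest type (asymmetric high-ratio pulses tend to
#'   be more focal).
#' @param ecc_type_rise_range Per-type-index increase beyond the roundest
#'   type: which duration ratio is most focal varies from region to
#'   region, so responses do not follow one clean type trend.
#' @param t_opt_choices Candidate roundest types (one drawn per region).
#' @param ecc_amp_slope_range Per-uA increase of eccentricity above
#'   threshold (axonal recruitment at high amplitude).
#' @param soma_jitter_um SD of the footprint-center offset from the
#'   electrode center (um).
#' @return List of class `region_hyper`.
#' @export
region_hyper <- function(image_side = 192L, pixel_size_um = 4,
                         electrode_diameter_um = 200,
                         baseline_level = 100, baseline_mult_sd = 0.03,
                         frame_noise_sd = 8, response_dff = 0.6,
                         threshold_range = c(25, 55),
                         threshold_type_slope_range = c(0, 2),
                         threshold_type_jitter = 2,
                         area_min_range = c(1.0e4, 1.5e4),
                         area_max_range = c(1.0e5, 1.3e5),
                         area_tau_range = c(24, 32),
                         ecc_base_range = c(0.50, 0.90),
                         ecc_type_slope_range = c(0.02, 0.12),
                         ecc_type_rise_range = c(0.03, 0.12),
                         t_opt_choices = 3:5,
                         ecc_amp_slope_range = c(0.0005, 0.003),
                         soma_jitter_um = 20) {
  structure(as.list(environment()), class = "region_hyper")
}

#' Sample one synthetic retinal region
#'
#' Deterministic for a fixed seed: all latent parameters are drawn from a
#' private RNG stream so repeated calls give identical surfaces.
#'
#' @param seed Integer region seed.
#' @param hyper A [region_hyper()] configuration.
#' @return A `region_ground_truth` object.
#' @export
sample_region <- function(seed, hyper = region_hyper()) {
  stopifnot(inherits(hyper, "region_hyper"))
  rng <- local_rng(seed)
  runif2 <- function(r) rng$runif(1, r[1], r[2])
  n_types <- length(DURATION_RATIOS)
  th_base <- runif2(hyper$threshold_range)
  th_slope <- runif2(hyper$threshold_type_slope_range)
  thresholds <- th_base + th_slope * (seq_len(n_types) - 1) +
    rng$runif(n_types, -hyper$threshold_type_jitter,
              hyper$threshold_type_jitter)
  structure(list(
    region_id = sprintf("region-%06d", as.integer(seed)),
    seed = as.integer(seed),
    hyper = hyper,
    thresholds_uA = thresholds,
    area_min_um2 = runif2(hyper$area_min_range),
    area_max_um2 = runif2(hyper$area_max_range) *
      (1 + 0.1 * rng$runif(n_types, -1, 1)),     # mild per-type scaling
    area_tau_uA = runif2(hyper$area_tau_range),
    ecc_base = runif2(hyper$ecc_base_range),
    ecc_type_slope = runif2(hyper$ecc_type_slope_range),
    ecc_type_rise = runif2(hyper$ecc_type_rise_range),
    ecc_t_opt = if (length(hyper$t_opt_choices) == 1) hyper$t_opt_choices
                else hyper$t_opt_choices[rng$sample(length(hyper$t_opt_choices), 1)],
    ecc_amp_slope = runif2(hyper$ecc_amp_slope_range),
    axon_orientation_deg = rng$runif(1, 0, 180),
    soma_offset_um = rng$rnorm(2, 0, hyper$soma_jitter_um)
  ), class = "region_ground_truth")
}

#' @export
print.region_ground_truth <- function(x, ...) {
  cat(sprintf("<region_ground_truth> %s: thresholds %s uA, max area %.0f um^2, axon %.0f deg\n",
              x$region_id, paste(round(x$thresholds_uA), collapse = "/"),
              max(x$area_max_um2), x$axon_orientation_deg))
  invisible(x)
}

#' Noiseless latent response of a region to a pulse
#'
#' Below the per-type activation threshold the response is (0, 0). At
#' threshold the area jumps to the region's threshold-response size (a
#' soma cluster) and then follows the saturating ramp
#' `A_min + (A_max - A_min) * (1 - exp(-(a - th) / tau))`
#' (non-decreasing in amplitude), and
#' the eccentricity a clamped piecewise-linear trend in type — falling
#' toward the region's roundest type and rising again beyond it — plus a
#' linear increase with amplitude above threshold (axonal recruitment).
#'
#' @param region A `region_ground_truth`.
#' @param pulse A `pulse_params`, or a numeric amplitude combined with `t`.
#' @param t Type coordinate (used when `pulse` is numeric); may be
#'   fractional, in which case the per-type parameters are linearly
#'   interpolated.
#' @return List with `area_um2` and `eccentricity`.
#' @export
ground_truth_response <- function(region, pulse, t = NULL) {
  if (inherits(pulse, "pulse_params")) {
    a <- pulse$cathodic_amplitude_uA
    t <- pulse$type_index
  } else {
    a <- pulse
    stopifnot(!is.null(t))
  }
  t <- min(max(t, 1), length(DURATION_RATIOS))
  interp <- function(v) stats::approx(seq_along(v), v, xout = t, rule = 2)$y
  th <- interp(region$thresholds_uA)
  if (a <= th) return(list(area_um2 = 0, eccentricity = 0))
  amax <- interp(region$area_max_um2)
  amin <- region$area_min_um2
  area <- amin + (amax - amin) * (1 - exp(-(a - th) / region$area_tau_uA))
  t_opt <- region$ecc_t_opt
  ecc <- region$ecc_base - region$ecc_type_slope * (min(t, t_opt) - 1) +
    region$ecc_type_rise * max(0, t - t_opt) +
    region$ecc_amp_slope * (a - th)
  ecc <- min(max(ecc, 0.02), 0.90)
  list(area_um2 = area, eccentricity = ecc)
}

#' Render the two averaged-window images for a stimulus (fast path)
#'
#' Draws the baseline and stimulation-window mean images directly, with
#' noise scaled to match the mean of 10 raw frames. Used by the closed loop
#' and ensemble evaluation where full frame stacks are not needed.
#'
#' @param region A `region_ground_truth`.
#' @param pulse A `pulse_params`.
#' @param seed Render seed.
#' @param noiseless If TRUE, suppress all noise sources.
#' @return List with `baseline_img`, `stim_img`, `pixel_size_um`,
#'   `electrode_center_px`, `electrode_diameter_um`, `stimulus`.
#' @export
render_activity_images <- function(region, pulse, seed = 0,
                                   noiseless = FALSE) {
  h <- region$hyper
  rng <- local_rng(seed * 7 + 13)
  side <- h$image_side
  f0 <- baseline_field(region, rng, noiseless)
  gain <- footprint_gain(region, pulse)
  nsd <- if (noiseless) 0 else h$frame_noise_sd / sqrt(10)
  baseline_img <- pmax(f0 + rng$rnorm(side * side, 0, nsd), 0)
  stim_img <- pmax(f0 * (1 + gain) + rng$rnorm(side * side, 0, nsd), 0)
  dim(baseline_img) <- dim(stim_img) <- c(side, side)
  list(baseline_img = baseline_img, stim_img = stim_img,
       pixel_size_um = h$pixel_size_um,
       electrode_center_px = c(side, side) / 2,
       electrode_diameter_um = h$electrode_diameter_um,
       stimulus = pulse)
}

#' Render a full fluorescence recording for a stimulus
#'
#' 100 frames at 10 frames/s: 5 s of baseline followed by 5 s of
#' stimulation during which pixels inside the activity footprint brighten
#' with a short calcium-onset time constant. The footprint is a solid
#' ellipse with latent area A*(a, t) and eccentricity E*(a, t), centered
#' near the electrode and oriented along the region's axon direction: for
#' small E* it is a round soma blob, for large E* an axonal streak.
#'
#' @inheritParams render_activity_images
#' @return A `fluorescence_recording`: list with `frames`
#'   (side x side x 100 array), timing metadata, geometry and the stimulus.
#' @export
render_recording <- function(region, pulse, seed = 0, noiseless = FALSE) {
  h <- region$hyper
  rng <- local_rng(seed * 7 + 13)
  side <- h$image_side
  frame_rate <- 10L
  pre_s <- 5L
  stim_s <- 5L
  n_frames <- frame_rate * (pre_s + stim_s)
  f0 <- baseline_field(region, rng, noiseless)
  gain <- footprint_gain(region, pulse)
  nsd <- if (noiseless) 0 else h$frame_noise_sd
  frames <- array(0, dim = c(side, side, n_frames))
  onset_tau_s <- 0.3
  for (k in seq_len(n_frames)) {
    t_since <- (k - pre_s * frame_rate - 0.5) / frame_rate
    s <- if (t_since > 0) 1 - exp(-t_since / onset_tau_s) else 0
    frames[, , k] <- pmax(f0 * (1 + gain * s) +
                            rng$rnorm(side * side, 0, nsd), 0)
  }
  structure(list(frames = frames, frame_rate_hz = frame_rate,
                 pre_stim_duration_s = pre_s, stim_duration_s = stim_s,
                 pixel_size_um = h$pixel_size_um,
                 electrode_center_px = c(side, side) / 2,
                 electrode_diameter_um = h$electrode_diameter_um,
                 stimulus = pulse),
            class = "fluorescence_recording")
}

# Static baseline fluorescence field (multiplicative pattern on the mean
# level); part of the region's identity, drawn from the render stream so
# stacks are bit-reproducible per (region, seed).
baseline_field <- function(region, rng, noiseless) {
  h <- region$hyper
  side <- h$image_side
  mult <- if (noiseless) 0 else h$baseline_mult_sd
  f0 <- h$baseline_level * (1 + rng$rnorm(side * side, 0, mult))
  f0 <- pmax(f0, h$baseline_level * 0.1)
  dim(f0) <- c(side, side)
  f0
}

# Fractional fluorescence gain map for a pulse: solid ellipse with latent
# (A*, E*), oriented along the axon direction.
footprint_gain <- function(region, pulse) {
  h <- region$hyper
  side <- h$image_side
  gt <- ground_truth_response(region, pulse)
  gain <- matrix(0, side, side)
  if (gt$area_um2 <= 0) return(gain)
  ratio <- sqrt(1 - gt$eccentricity^2)            # semi_minor / semi_major
  a_px <- sqrt(gt$area_um2 / (pi * ratio)) / h$pixel_size_um
  b_px <- a_px * ratio
  ctr <- c(side, side) / 2 + region$soma_offset_um / h$pixel_size_um
  mask <- draw_ellipse_mask(side, center = ctr, semi_axes = c(a_px, b_px),
                            orientation_deg = region$axon_orientation_deg)
  gain[mask] <- h$response_dff
  gain
}

#' Write / read a recording as multi-page TIFF plus JSON sidecar
#'
#' Intensities are stored as 16-bit TIFF pages scaled by `intensity_scale`
#' counts per unit; all timing, geometry and stimulus metadata go to a
#' `.json` sidecar next to the TIFF.
#'
#' @param rec A `fluorescence_recording`.
#' @param path Path to the `.tif` file (sidecar at `<path>.json`).
#' @return `path`, invisibly (for `write_recording`); the recording for
#'   `read_recording`.
#' @export
write_recording <- function(rec, path) {
  scale <- 65535 / max(rec$frames, 1)
  pages <- lapply(seq_len(dim(rec$frames)[3]),
                  function(k) rec$frames[, , k] * scale / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta <- rec[setdiff(names(rec), "frames")]
  meta$intensity_scale <- scale
  meta$stimulus <- unclass(meta$stimulus)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) frames[, , k] <- pages[[k]] * 65535
  frames <- frames / meta$intensity_scale
  stim <- meta$stimulus
  rec <- list(frames = frames, frame_rate_hz = meta$frame_rate_hz,
              pre_stim_duration_s = meta$pre_stim_duration_s,
              stim_duration_s = meta$stim_duration_s,
              pixel_size_um = meta$pixel_size_um,
              electrode_center_px = meta$electrode_center_px,
              electrode_diameter_um = meta$electrode_diameter_um,
              stimulus = structure(stim, class = "pulse_params"))
  structure(rec, class = "fluorescence_recording")
}

#' Electrode area in um^2 for a region's geometry
#' @param region A `region_ground_truth` (or a `region_hyper`).
#' @return Scalar area of the stimulating disk electrode.
#' @export
electrode_area_um2 <- function(region) {
  h <- if (inherits(region, "region_hyper")) region else region$hyper
  pi * (h$electrode_diameter_um / 2)^2
}

# Private RNG stream: isolates simulator draws from the global RNG state.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- NULL
  with_stream <- function(fn) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(old)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, envir = globalenv())
      })
      if (is.null(env$state)) set.seed(as.integer(as.double(seed) %% 2147483647))
      else assign(".Random.seed", env$state, envir = globalenv())
      fn(...)
    }
  }
  list(runif = with_stream(stats::runif), rnorm = with_stream(stats::rnorm),
       sample = with_stream(base::sample))
}
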