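# Shared fixtures: all synthetic, built in code.

default_grid <- build_grid()

# one small responsive region + its full-grid trial set, reused across tests
fixture_region <- sample_region(5)

fixture_trials <- function(region = fixture_region, grid = default_grid,
                           seed = 42, noiseless = FALSE) {
  lapply(grid$pulses, function(p) {
    imgs <- render_activity_images(region, p, seed = seed,
                                   noiseless = noiseless)
    list(pulse = p,
         shape = fit_response_shape(suppressWarnings(
           compute_activity_map(imgs))))
  })
}

# constant-intensity recording (every pixel `level` in all frames)
constant_recording <- function(level = 100, side = 16) {
  structure(list(frames = array(level, dim = c(side, side, 100)),
                 frame_rate_hz = 10L, pre_stim_duration_s = 5L,
                 stim_duration_s = 5L, pixel_size_um = 4,
                 electrode_center_px = c(side, side) / 2,
                 electrode_diameter_um = 200,
                 stimulus = make_pulse(100, 1)),
            class = "fluorescence_recording")
}

# recording whose stimulus-window pixels are baseline * (1 + gain) inside
# a given mask
modulated_recording <- function(gain_map, baseline = 100, side = nrow(gain_map)) {
  frames <- array(baseline, dim = c(side, side, 100))
  for (k in 51:100) frames[, , k] <- baseline * (1 + gain_map)
  structure(list(frames = frames, frame_rate_hz = 10L,
                 pre_stim_duration_s = 5L, stim_duration_s = 5L,
                 pixel_size_um = 4, electrode_center_px = c(side, side) / 2,
                 electrode_diameter_um = 200,
                 stimulus = make_pulse(100, 1)),
            class = "fluorescence_recording")
}
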