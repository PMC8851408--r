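# Per-region surrogate models and the shape objective.
#
# Two independent feedforward nets (inputs: pulse amplitude and type index,
# one hidden layer of 10 tanh units, linear output) learn normalized
# activation area A(a, t) and eccentricity E(a, t) from the responsive
# trials of a region. The objective to minimize is
#     f(a, t) = |A(a, t) - C| + E(a, t)
# where C is the electrode area in the same normalized units; its minimum
# (0) is a response exactly the size of the electrode and perfectly round.

N_HIDDEN <- 10L

#' Build the regression table for surrogate training
#'
#' Trials whose response carries no meaningful activity (fewer than 5
#' active pixels; the class-0 pathway) are excluded from modeling. Areas
#' are normalized by the maximum observed activation area of the region, so
#' the largest responsive trial has `area_normalized = 1` exactly.
#'
#' @param trials List of `list(pulse = <pulse_params>,
#'   shape = <response_shape>)` records.
#' @return A data.frame with columns `amplitude_uA`, `type_index`,
#'   `area_normalized`, `eccentricity`; attribute `area_max_um2` holds the
#'   normalization constant.
#' @export
prepare_training_set <- function(trials) {
  keep <- Filter(function(tr) tr$shape$n_active_pixels >= 5L, trials)
  if (length(keep) < 3L) {
    stop(focalstim_error("insufficient_data", sprintf(
      "only %d responsive trials after excluding no-response stimuli (need >= 3)",
      length(keep))))
  }
  area <- vapply(keep, function(tr) tr$shape$area_um2, numeric(1))
  area_max <- max(area)
  out <- data.frame(
    amplitude_uA = vapply(keep, function(tr)
      as.numeric(tr$pulse$cathodic_amplitude_uA), numeric(1)),
    type_index = vapply(keep, function(tr)
      as.numeric(tr$pulse$type_index), numeric(1)),
    area_normalized = area / area_max,
    eccentricity = vapply(keep, function(tr) tr$shape$eccentricity,
                          numeric(1)))
  attr(out, "area_max_um2") <- area_max
  out
}

# ---- 2-10-1 tanh net internals ------------------------------------------
# Weight vector layout: for each hidden unit j: (b_j, w_j1, w_j2); then the
# output layer (b_out, v_1..v_10). Inputs are min-max scaled to [0, 1].

net_n_weights <- function(n_hidden = N_HIDDEN) 3L * n_hidden + n_hidden + 1L

net_hidden_z <- function(W, X) {
  cbind(1, X) %*% W            # W rows: bias, w1, w2 -> one BLAS product
}

net_forward <- function(wts, X, n_hidden = N_HIDDEN) {
  W <- matrix(wts[seq_len(3 * n_hidden)], nrow = 3)   # rows: b, w1, w2
  vb <- wts[3 * n_hidden + 1]
  v <- wts[(3 * n_hidden + 2):length(wts)]
  H <- tanh(net_hidden_z(W, X))
  drop(vb + H %*% v)
}

# Jacobian of predictions w.r.t. weights: n x n_weights.
net_jacobian <- function(wts, X, n_hidden = N_HIDDEN) {
  W <- matrix(wts[seq_len(3 * n_hidden)], nrow = 3)
  v <- wts[(3 * n_hidden + 2):length(wts)]
  H <- tanh(net_hidden_z(W, X))
  D <- (1 - H^2)
  n <- nrow(X)
  J <- matrix(0, n, length(wts))
  for (j in seq_len(n_hidden)) {
    col <- (j - 1) * 3
    Dv <- D[, j] * v[j]
    J[, col + 1] <- Dv
    J[, col + 2] <- Dv * X[, 1]
    J[, col + 3] <- Dv * X[, 2]
  }
  J[, 3 * n_hidden + 1] <- 1
  J[, (3 * n_hidden + 2):length(wts)] <- H
  J
}

# Gradient of the net output w.r.t. the (scaled) inputs at points X: n x 2.
net_input_grad <- function(wts, X, n_hidden = N_HIDDEN) {
  W <- matrix(wts[seq_len(3 * n_hidden)], nrow = 3)
  v <- wts[(3 * n_hidden + 2):length(wts)]
  D <- (1 - tanh(net_hidden_z(W, X))^2)
  cbind(drop(D %*% (v * W[2, ])), drop(D %*% (v * W[3, ])))
}

# Fit one net with Levenberg-Marquardt. The L2 weight decay on non-bias
# weights keeps the 41-parameter fit well-posed on 3-46 data points and
# damps high-frequency ripples between training inputs that would litter
# the objective surface with spurious local minima; reaching `maxiter`
# with a tiny residual is routine here, so that warning is not propagated.
fit_net <- function(X, y, init, l2 = 3e-3, maxiter = 100L) {
  n_h <- N_HIDDEN
  pen_mask <- rep(c(0, 1, 1), n_h)                 # hidden: biases free
  pen_mask <- c(pen_mask, 0, rep(1, n_h))          # output bias free
  sqrt_l2 <- sqrt(l2)
  resid_fn <- function(w) {
    c(net_forward(w, X) - y, sqrt_l2 * pen_mask * w)
  }
  jac_fn <- function(w) {
    rbind(net_jacobian(w, X), diag(sqrt_l2 * pen_mask))
  }
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = init, fn = resid_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(maxiter = maxiter, ptol = 1e-10,
                                         ftol = 1e-10)))
  list(wts = unname(coef(fit)), info = fit$info,
       deviance = fit$deviance)
}

# Split row indices into train/validation/test. Fractions respect the
# 60-80% / 10-20% / 10-20% scheme, adapting to the number of points: tiny
# tables keep one row each for validation and test.
split_rows <- function(n, rng) {
  idx <- rng$sample(n)
  if (n <= 4L) {
    list(train = idx, val = integer(0), test = integer(0))
  } else if (n < 10L) {
    list(train = idx[seq_len(n - 2L)], val = idx[n - 1L], test = idx[n])
  } else {
    n_val <- max(1L, round(0.15 * n))
    n_test <- max(1L, round(0.15 * n))
    list(train = idx[seq_len(n - n_val - n_test)],
         val = idx[(n - n_val - n_test + 1L):(n - n_test)],
         test = idx[(n - n_test + 1L):n])
  }
}

#' Train the area and eccentricity surrogate nets for a region
#'
#' Each net has one hidden layer of 10 hyperbolic-tangent units and a
#' linear output, and is fitted with Levenberg-Marquardt least squares.
#' Rows are split into training (60-80%), validation (10-20%) and test
#' (10-20%) subsets, the exact fractions adapting to the table size; two
#' seeded initializations are fitted and the one with the lower validation
#' error kept (training error breaks ties and decides when the table is
#' too small for a validation row). Deterministic for a fixed seed.
#'
#' @param table Output of [prepare_training_set()].
#' @param seed Training seed.
#' @param box Optimization box as
#'   `list(amplitude = c(lo, hi), type = c(1, 5))`; used for input scaling.
#' @param electrode_area_um2 Electrode area, used for the normalized
#'   objective constant `C`.
#' @return A `surrogate_pair` with prediction closures, weights, scaling
#'   constants, split indices and per-split mean squared errors.
#' @export
train_surrogates <- function(table, seed = 1,
                             box = list(amplitude = c(20, 110),
                                        type = c(1, 5)),
                             electrode_area_um2 = pi * 100^2) {
  stopifnot(nrow(table) >= 3)
  rng <- local_rng(derive_seed(seed, 211))
  X <- scale_inputs(table$amplitude_uA, table$type_index, box)
  split <- split_rows(nrow(table), rng)
  fit_target <- function(y) {
    score_split <- if (length(split$val)) split$val else split$train
    best <- NULL
    for (attempt in 1:2) {
      init <- rng$rnorm(net_n_weights(), 0, 0.5)
      fit <- fit_net(X[split$train, , drop = FALSE], y[split$train], init)
      mse_score <- mean((net_forward(fit$wts, X[score_split, , drop = FALSE]) -
                           y[score_split])^2)
      if (is.null(best) || mse_score < best$score) {
        best <- fit
        best$score <- mse_score
      }
    }
    best$mse <- vapply(split, function(ix) {
      if (!length(ix)) return(NA_real_)
      mean((net_forward(best$wts, X[ix, , drop = FALSE]) - y[ix])^2)
    }, numeric(1))
    best
  }
  area_fit <- fit_target(table$area_normalized)
  ecc_fit <- fit_target(table$eccentricity)
  area_max <- attr(table, "area_max_um2")
  structure(list(
    area_wts = area_fit$wts, ecc_wts = ecc_fit$wts,
    box = box, seed = seed,
    split = split,
    metrics = list(area_mse = area_fit$mse, ecc_mse = ecc_fit$mse),
    region_area_max_um2 = area_max,
    C = electrode_area_um2 / area_max,
    electrode_area_um2 = electrode_area_um2,
    n_points = nrow(table)
  ), class = "surrogate_pair")
}

#' @export
print.surrogate_pair <- function(x, ...) {
  cat(sprintf(
    "<surrogate_pair> %d points, C = %.3f; test MSE area %.4f / ecc %.4f\n",
    x$n_points, x$C, x$metrics$area_mse[["test"]],
    x$metrics$ecc_mse[["test"]]))
  invisible(x)
}

scale_inputs <- function(a, t, box) {
  cbind((a - box$amplitude[1]) / diff(box$amplitude),
        (t - box$type[1]) / diff(box$type))
}

#' Surrogate predictions at (amplitude, type)
#'
#' `surrogate_area` returns the predicted normalized activation area;
#' `surrogate_ecc` the predicted eccentricity, clamped to `[0, 1]` (its
#' physical range, which also keeps the objective nonnegative).
#'
#' @param pair A `surrogate_pair`.
#' @param a Amplitude (uA), vectorized.
#' @param t Type coordinate, vectorized.
#' @return Numeric vector of predictions.
#' @export
surrogate_area <- function(pair, a, t) {
  net_forward(pair$area_wts, scale_inputs(a, t, pair$box))
}

#' @rdname surrogate_area
#' @export
surrogate_ecc <- function(pair, a, t) {
  clamp(net_forward(pair$ecc_wts, scale_inputs(a, t, pair$box)), 0, 1)
}

#' The response-shape objective f(a, t) = |A(a, t) - C| + E(a, t)
#'
#' @inheritParams surrogate_area
#' @param C Normalized electrode area; defaults to the pair's constant.
#' @return Objective values (vectorized, nonnegative).
#' @export
objective <- function(pair, a, t, C = pair$C) {
  abs(surrogate_area(pair, a, t) - C) + surrogate_ecc(pair, a, t)
}

#' Analytic gradient of the objective in (amplitude, type)
#'
#' Exact differentiation of the tanh nets; the absolute value contributes
#' `sign(A - C) * dA`, and the eccentricity clamp zeroes its gradient
#' outside `(0, 1)`.
#'
#' @inheritParams objective
#' @return A length-2 gradient (single point) or n x 2 matrix.
#' @export
objective_gradient <- function(pair, a, t, C = pair$C) {
  X <- scale_inputs(a, t, pair$box)
  A <- net_forward(pair$area_wts, X)
  E_raw <- net_forward(pair$ecc_wts, X)
  gA <- net_input_grad(pair$area_wts, X)
  gE <- net_input_grad(pair$ecc_wts, X)
  gE[E_raw < 0 | E_raw > 1, ] <- 0
  g_scaled <- sign(A - C) * gA + gE
  g <- cbind(g_scaled[, 1] / diff(pair$box$amplitude),
             g_scaled[, 2] / diff(pair$box$type))
  if (nrow(g) == 1) drop(g) else g
}

#' Dense objective map over the (amplitude, type) box
#'
#' Evaluates the surrogate objective on a grid at 2 uA amplitude and 1
#' type-index resolution (defaults), for visualization and as the
#' brute-force oracle for the continuous optimizer.
#'
#' @inheritParams objective
#' @param amplitude_step Amplitude resolution (uA).
#' @param type_step Type resolution.
#' @return An `objective_surface`: list with `values` (amplitude x type
#'   matrix), `amplitudes`, `types`, `C`, and the argmin (`min_value`,
#'   `min_a`, `min_t`).
#' @export
objective_map <- function(pair, amplitude_step = 2, type_step = 1,
                          C = pair$C) {
  amps <- seq(pair$box$amplitude[1], pair$box$amplitude[2],
              by = amplitude_step)
  types <- seq(pair$box$type[1], pair$box$type[2], by = type_step)
  g <- expand.grid(a = amps, t = types)
  vals <- matrix(objective(pair, g$a, g$t, C = C),
                 nrow = length(amps), ncol = length(types))
  k <- arrayInd(which.min(vals), dim(vals))
  structure(list(values = vals, amplitudes = amps, types = types, C = C,
                 min_value = min(vals), min_a = amps[k[1]],
                 min_t = types[k[2]]),
            class = "objective_surface")
}

#' Heatmap of an objective surface
#'
#' @param x An `objective_surface`.
#' @param ... Passed to [graphics::image()].
#' @export
plot_objective_map <- function(x, ...) {
  graphics::image(x$amplitudes, x$types, x$values,
                  xlab = "pulse amplitude (uA)", ylab = "pulse type",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  graphics::points(x$min_a, x$min_t, pch = 4, col = "white", lwd = 2)
}

#' Serialize / restore surrogate weights
#'
#' Portable JSON archive with weights, scaling box and normalization
#' constants.
#'
#' @param pair A `surrogate_pair`.
#' @param path Output path (`.json`).
#' @export
write_surrogates <- function(pair, path) {
  jsonlite::write_json(unclass(pair)[c("area_wts", "ecc_wts", "box",
                                       "region_area_max_um2", "C",
                                       "electrode_area_um2", "n_points",
                                       "seed")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_surrogates
#' @export
read_surrogates <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$box <- lapply(obj$box, as.numeric)
  structure(obj, class = "surrogate_pair")
}
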