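# Five-class response-shape classification.
#
# Classes: 0 no meaningful activity; 1 round & small; 2 elongated & small;
# 3 round & large; 4 elongated & large. "Small" means the fitted activation
# area is below twice the electrode area (responses larger than that
# overlap neighboring electrodes at the array pitch); "round" means
# eccentricity below 0.5 (the midpoint of its range). Boundary convention:
# equality goes to the elongated / large side. Masks with fewer than 5
# active pixels count as no meaningful activity, mirroring the manual
# relabeling of sparse one-or-two-cell images.

CLASS0_MIN_PIXELS <- 5L

#' Rule-based response-shape class
#'
#' @param shape A `response_shape` (from [fit_response_shape()]), or a
#'   numeric eccentricity when `area_um2`/`n_active_pixels` are given
#'   directly.
#' @param electrode_area_um2 Electrode disk area (um^2).
#' @param area_um2,n_active_pixels Direct inputs used when `shape` is
#'   numeric (latent-surface labeling).
#' @return Integer class label in 0..4.
#' @export
rule_label <- function(shape, electrode_area_um2 = pi * 100^2,
                       area_um2 = NULL, n_active_pixels = NULL) {
  if (inherits(shape, "response_shape")) {
    ecc <- shape$eccentricity
    area_um2 <- shape$area_um2
    n_active_pixels <- shape$n_active_pixels
  } else {
    ecc <- shape
    stopifnot(!is.null(area_um2), !is.null(n_active_pixels))
  }
  if (n_active_pixels < CLASS0_MIN_PIXELS) return(0L)
  large <- area_um2 >= 2 * electrode_area_um2
  elongated <- ecc >= 0.5
  if (!large && !elongated) 1L
  else if (!large && elongated) 2L
  else if (large && !elongated) 3L
  else 4L
}

#' Rule class of a latent (noiseless) region response
#'
#' Labels the ground-truth surface value directly, using the latent area to
#' derive an active-pixel count at the region's pixel size.
#'
#' @param region A `region_ground_truth`.
#' @param a Amplitude (uA).
#' @param t Type coordinate.
#' @return Integer class label in 0..4.
#' @export
latent_class <- function(region, a, t) {
  gt <- ground_truth_response(region, a, t = t)
  px_area <- region$hyper$pixel_size_um^2
  rule_label(gt$eccentricity, electrode_area_um2 = electrode_area_um2(region),
             area_um2 = gt$area_um2,
             n_active_pixels = floor(gt$area_um2 / px_area))
}

#' Augment a labeled image set
#'
#' Adds transformed copies of images in the configured classes: the three
#' orthogonal rotations, horizontal/vertical flips, and noisy variants
#' (Gaussian plus salt-and-pepper). Rotations and flips leave the
#' rule label unchanged (the shape descriptors are rotation-invariant);
#' labels are carried over unchanged for all copies.
#'
#' @param images List of numeric matrices in `[0, 1]`.
#' @param labels Integer class labels, one per image.
#' @param classes Classes to augment (default 1, 2 and 3).
#' @param rotations Number of orthogonal rotations per image (max 3).
#' @param flips Number of flips per image (max 2).
#' @param noise_copies Number of noisy copies per image.
#' @param gaussian_sd SD of the additive Gaussian noise.
#' @param salt_pepper_frac Fraction of pixels set to 0 or 1 in
#'   salt-and-pepper copies.
#' @param seed RNG seed for the noise draws.
#' @return List with augmented `images` and `labels` (originals first).
#' @export
augment_images <- function(images, labels, classes = c(1L, 2L, 3L),
                           rotations = 3L, flips = 2L, noise_copies = 2L,
                           gaussian_sd = 0.05, salt_pepper_frac = 0.02,
                           seed = 0) {
  stopifnot(length(images) == length(labels), rotations <= 3, flips <= 2)
  rng <- local_rng(derive_seed(seed, 77))
  rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE][, , drop = FALSE]
  out_img <- as.list(images)
  out_lab <- as.integer(labels)
  for (i in seq_along(images)) {
    if (!(labels[i] %in% classes)) next
    img <- images[[i]]
    r <- img
    if (rotations >= 1) { r <- rot90(img); out_img <- c(out_img, list(r)) }
    if (rotations >= 2) { r <- rot90(r); out_img <- c(out_img, list(r)) }
    if (rotations >= 3) { r <- rot90(r); out_img <- c(out_img, list(r)) }
    if (flips >= 1) out_img <- c(out_img, list(img[nrow(img):1, ]))
    if (flips >= 2) out_img <- c(out_img, list(img[, ncol(img):1]))
    for (k in seq_len(noise_copies)) {
      if (k %% 2L == 1L) {
        noisy <- clamp(img + matrix(rng$rnorm(length(img), 0, gaussian_sd),
                                    nrow(img)), 0, 1)
      } else {
        noisy <- img
        n_sp <- round(salt_pepper_frac * length(img))
        if (n_sp > 0) {
          pos <- rng$sample(length(img), n_sp)
          noisy[pos] <- rng$sample(c(0, 1), n_sp, replace = TRUE)
        }
      }
      out_img <- c(out_img, list(noisy))
    }
    n_new <- min(rotations, 3) + min(flips, 2) + noise_copies
    out_lab <- c(out_lab, rep(as.integer(labels[i]), n_new))
  }
  list(images = out_img, labels = out_lab)
}

#' Normalize an activity map for the CNN
#'
#' Optionally center-crops the delta-F/F map (responses are centered on
#' the electrode; cropping preserves spatial resolution for the
#' class-boundary-sized footprints), block-mean downsamples it to the
#' network input side, and rescales so the nominal response gain maps
#' to 1.
#'
#' @param dff Delta-F/F matrix (or an `activity_map`).
#' @param side Target side (pixels).
#' @param gain Fractional gain mapped to intensity 1 (default 0.5).
#' @param max_factor Cap on the downsampling factor; larger maps are
#'   center-cropped to `side * max_factor` first.
#' @return `side` x `side` matrix in `[0, 1]`.
#' @export
prepare_cnn_input <- function(dff, side, gain = 0.5, max_factor = 4L) {
  if (inherits(dff, "activity_map")) dff <- dff$dff
  dff[is.na(dff)] <- 0
  n <- nrow(dff)
  if (n > side * max_factor) {
    half <- side * max_factor %/% 2L
    ctr <- n %/% 2L
    sel <- (ctr - half + 1L):(ctr + half)
    dff <- dff[sel, sel]
    n <- nrow(dff)
  }
  factor <- n %/% side
  stopifnot(factor >= 1, n == side * factor)
  clamp(downsample_mean(dff, factor) / gain, 0, 1)
}

#' Generate a balanced rule-labeled training corpus
#'
#' Draws synthetic regions and stimuli, renders their (noisy) activity
#' images, labels each by the explicit area/eccentricity rules at full
#' resolution, and keeps examples until every class holds `n / 5` images
#' (downsampled to the CNN input side).
#'
#' Images whose descriptors fall within the boundary margins are excluded:
#' a response with eccentricity at 0.49 versus 0.51, or area just either
#' side of twice the electrode area, belongs to different rule classes but
#' is visually indistinguishable, so such images carry no learnable class
#' signal. The margins operationalize the restriction of the training set
#' to visually distinguishable categories; set both to 0 for a raw
#' rule-labeled corpus.
#'
#' @param n Total corpus size (multiple of 5).
#' @param config A `cnn_config` (for the input side).
#' @param hyper A [region_hyper()].
#' @param seed Corpus seed.
#' @param margin_ecc Exclusion half-width around the eccentricity
#'   boundary 0.5.
#' @param margin_area Relative exclusion half-width around the area
#'   boundary (twice the electrode area).
#' @param max_attempts Safety cap on candidate draws.
#' @return List with `images` (list of matrices), `labels` (0..4), and
#'   `shapes` (the fitted descriptors).
#' @export
make_corpus <- function(n = 2000L, config = cnn_config_desk(),
                        hyper = region_hyper(), seed = 1,
                        margin_ecc = 0.10, margin_area = 0.20,
                        max_attempts = 60L * n) {
  stopifnot(n %% 5 == 0)
  per_class <- n %/% 5L
  rng <- local_rng(derive_seed(seed, 31))
  counts <- integer(5)
  images <- vector("list", n)
  labels <- integer(n)
  shapes <- vector("list", n)
  filled <- 0L
  attempt <- 0L
  elec_area <- electrode_area_um2(hyper)
  while (filled < n && attempt < max_attempts) {
    attempt <- attempt + 1L
    region <- sample_region(derive_seed(seed, 5, attempt %% 997L),
                            hyper = hyper)
    # propose amplitudes relative to the region threshold so all five
    # classes appear at useful rates: sub-threshold draws supply class 0,
    # the thin band just above threshold the small classes, and high
    # amplitudes the large classes
    t <- rng$sample(5L, 1)
    th <- region$thresholds_uA[t]
    u <- rng$runif(1)
    a <- if (u < 0.25) rng$runif(1, 5, max(th - 1, 6))
         else if (u < 0.70) th + rng$runif(1, 0, 25)
         else rng$runif(1, th + 25, 135)
    pulse_a <- DURATION_RATIOS[t] * round(a / DURATION_RATIOS[t])
    if (pulse_a <= 0) next
    pulse <- make_pulse(pulse_a, DURATION_RATIOS[t])
    # cheap latent pre-filter: skip rendering when this draw cannot fill a
    # bucket (the rendered rule label almost always equals the latent one
    # away from the excluded boundary margins)
    lat <- latent_class(region, pulse_a, t)
    if (counts[lat + 1L] >= per_class) next
    imgs <- render_activity_images(region, pulse,
                                   seed = derive_seed(seed, 9, attempt))
    map <- compute_activity_map(imgs)
    shape <- fit_response_shape(map)
    lab <- rule_label(shape, electrode_area_um2 = elec_area)
    if (lab > 0L) {
      if (abs(shape$eccentricity - 0.5) < margin_ecc) next
      if (abs(shape$area_um2 / (2 * elec_area) - 1) < margin_area) next
    }
    if (counts[lab + 1L] >= per_class) next
    counts[lab + 1L] <- counts[lab + 1L] + 1L
    filled <- filled + 1L
    images[[filled]] <- prepare_cnn_input(map, config$input_side,
                                          max_factor = config$max_downsample)
    labels[filled] <- lab
    shapes[[filled]] <- shape
  }
  if (filled < n) {
    stop(sprintf(
      "corpus generation exhausted %d attempts with class counts %s",
      attempt, paste(counts, collapse = "/")))
  }
  list(images = images, labels = labels, shapes = shapes)
}

#' Train the response-shape CNN
#'
#' Splits the corpus 90-10 into train and test, then 90-10 of the training
#' portion into train and validation; trains with Adam, categorical
#' cross-entropy, dropout and L2 decay for the configured number of epochs;
#' reports the confusion matrix and per-class recall on the held-out test
#' split. Deterministic for a fixed seed.
#'
#' @param corpus List with `images` and `labels` (see [make_corpus()]).
#' @param config A [cnn_config()].
#' @param seed Training seed.
#' @param verbose Print per-epoch progress.
#' @return A `cnn_model`: parameters, config, history, `confusion`
#'   (true x predicted), `class_recall`, split indices.
#' @export
train_cnn <- function(corpus, config = cnn_config_desk(), seed = 1,
                      verbose = FALSE) {
  labels <- as.integer(corpus$labels)
  present <- sort(unique(labels))
  expected <- 0:(config$n_classes - 1L)
  if (!all(expected %in% present)) {
    stop(sprintf("corpus is missing class(es): %s",
                 paste(setdiff(expected, present), collapse = ", ")))
  }
  n <- length(labels)
  side <- config$input_side
  X <- t(vapply(corpus$images, function(im) {
    stopifnot(nrow(im) == side, ncol(im) == side)
    as.vector(im)
  }, numeric(side * side)))
  rng <- local_rng(derive_seed(seed, 404))
  idx <- rng$sample(n)
  n_test <- max(1L, round(config$test_frac * n))
  test_idx <- idx[seq_len(n_test)]
  rest <- idx[-seq_len(n_test)]
  n_val <- max(1L, round(config$val_frac * length(rest)))
  val_idx <- rest[seq_len(n_val)]
  train_idx <- rest[-seq_len(n_val)]

  params <- cnn_init(config, rng)
  state <- list(t = 0L, m = list(), v = list())
  B <- config$batch_size
  plan_full <- cnn_plan(config, B)
  plans <- list()
  Y_all <- diag(config$n_classes)[labels + 1L, , drop = FALSE]
  keep <- 1 - config$dropout
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_accuracy = numeric(0))
  predict_classes <- function(ix) {
    out <- integer(length(ix))
    for (start in seq(1, length(ix), by = 256)) {
      sub <- ix[start:min(start + 255, length(ix))]
      p <- cnn_predict_probs(list(params = params, config = config),
                             X[sub, , drop = FALSE])
      out[start:(start + length(sub) - 1L)] <- max.col(p) - 1L
    }
    out
  }
  for (epoch in seq_len(config$epochs)) {
    ord <- rng$sample(length(train_idx))
    sh <- train_idx[ord]
    losses <- numeric(0)
    for (start in seq(1, length(sh), by = B)) {
      batch <- sh[start:min(start + B - 1L, length(sh))]
      bsz <- length(batch)
      plan <- if (bsz == B) plan_full else {
        key <- as.character(bsz)
        if (is.null(plans[[key]])) plans[[key]] <- cnn_plan(config, bsz)
        plans[[key]]
      }
      drop_masks <- NULL
      if (config$dropout > 0) {
        drop_masks <- lapply(config$dense_units, function(w)
          matrix((rng$runif(bsz * w) < keep) / keep, bsz, w))
      }
      fwd <- cnn_forward(params, config, plan, X[batch, , drop = FALSE],
                         train = TRUE, drop_masks = drop_masks)
      Yb <- Y_all[batch, , drop = FALSE]
      losses <- c(losses, cnn_loss(params, config, fwd$probs, Yb))
      grads <- cnn_backward(params, config, plan, fwd, Yb)
      upd <- adam_step(params, grads, state, config)
      params <- upd$params
      state <- upd$state
    }
    val_acc <- mean(predict_classes(val_idx) == labels[val_idx])
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_accuracy = val_acc))
    if (verbose) {
      message(sprintf("epoch %2d  loss %.4f  val acc %.3f",
                      epoch, mean(losses), val_acc))
    }
  }
  pred_test <- predict_classes(test_idx)
  truth <- factor(labels[test_idx], levels = expected)
  pred <- factor(pred_test, levels = expected)
  confusion <- table(truth = truth, predicted = pred)
  recall <- diag(confusion) / pmax(rowSums(confusion), 1)
  structure(list(params = params, config = config, history = history,
                 confusion = confusion, class_recall = recall,
                 split = list(train = train_idx, val = val_idx,
                              test = test_idx),
                 seed = seed),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> %s epochs, test recall %s\n",
              x$config$epochs,
              paste(sprintf("%.2f", x$class_recall), collapse = "/")))
  invisible(x)
}

#' Classify an activity map
#'
#' Runs the CNN on the (downsampled, normalized) delta-F/F map and returns
#' the argmax class, alongside the rule label of the fitted shape for
#' cross-checking. With `model = NULL` the rule label alone is returned as
#' the class (the loop stays runnable without a training step).
#'
#' @param map An `activity_map`.
#' @param model A `cnn_model` or NULL.
#' @param electrode_area_um2 Electrode disk area (um^2) for the rules.
#' @return List with `class`, `cnn_class` (NA without a model),
#'   `rule_class`, `probs`.
#' @export
classify_response <- function(map, model = NULL,
                              electrode_area_um2 = pi * 100^2) {
  shape <- fit_response_shape(map)
  rule <- rule_label(shape, electrode_area_um2 = electrode_area_um2)
  if (is.null(model)) {
    return(list(class = rule, cnn_class = NA_integer_, rule_class = rule,
                probs = NULL))
  }
  x <- prepare_cnn_input(map, model$config$input_side,
                         max_factor = model$config$max_downsample %||% 4L)
  p <- cnn_predict_probs(model, matrix(as.vector(x), nrow = 1))
  cls <- max.col(p) - 1L
  list(class = cls, cnn_class = cls, rule_class = rule, probs = drop(p))
}
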