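# Response-shape classification: rules, augmentation, CNN machinery.

elec <- pi * 100^2

test_that("rule labeler reproduces the printed class rules", {
  mk <- function(ecc, area, npx = 100L)
    rule_label(ecc, electrode_area_um2 = elec, area_um2 = area,
               n_active_pixels = npx)
  expect_equal(mk(0.3, 1.5 * elec), 1L)
  expect_equal(mk(0.7, 1.5 * elec), 2L)
  expect_equal(mk(0.3, 3 * elec), 3L)
  expect_equal(mk(0.7, 3 * elec), 4L)
  expect_equal(mk(0.7, 3 * elec, npx = 0L), 0L)
  expect_equal(mk(0.2, 0.5 * elec, npx = 4L), 0L)   # sparse-activity floor
})

test_that("rule labeler is total and assigns equality to the larger side", {
  # exact boundaries: ecc = 0.5 counts as elongated, area = 2x as large
  expect_equal(rule_label(0.5, elec, area_um2 = elec, n_active_pixels = 50L),
               2L)
  expect_equal(rule_label(0.2, elec, area_um2 = 2 * elec,
                          n_active_pixels = 50L), 3L)
  expect_equal(rule_label(0.5, elec, area_um2 = 2 * elec,
                          n_active_pixels = 50L), 4L)
  set.seed(2)
  for (i in 1:100) {
    lab <- rule_label(runif(1), elec, area_um2 = runif(1, 0, 4 * elec),
                      n_active_pixels = sample(0:500, 1))
    expect_true(lab %in% 0:4)
  }
})

test_that("augmentation multiplies only the configured classes", {
  imgs <- replicate(12, matrix(runif(64), 8, 8), simplify = FALSE)
  labs <- rep(c(1L, 4L), each = 6)
  out <- augment_images(imgs, labs, classes = c(1, 2, 3),
                        rotations = 3, flips = 2, noise_copies = 2)
  # class 1: 6 originals + 6 * 7 copies; class 4 untouched
  expect_equal(sum(out$labels == 1L), 6L + 6L * 7L)
  expect_equal(sum(out$labels == 4L), 6L)
  expect_equal(length(out$images), length(out$labels))

  empty <- augment_images(list(), integer(0))
  expect_length(empty$images, 0)
})

test_that("rotations and flips preserve the rule label", {
  mask <- draw_ellipse_mask(64, c(30, 40), c(18, 6), 25)
  img <- mask * 1
  base_shape <- fit_response_shape(mask, 4)
  base_lab <- rule_label(base_shape, elec)
  out <- augment_images(list(img), base_lab, classes = base_lab,
                        rotations = 3, flips = 2, noise_copies = 0)
  for (k in seq_along(out$images)) {
    sh <- fit_response_shape(out$images[[k]] > 0.5, 4)
    expect_equal(rule_label(sh, elec), base_lab)
  }
})

test_that("CNN forward/backward gradients match finite differences", {
  cfg <- cnn_config(input_side = 10L, conv_filters = c(3L, 4L),
                    dense_units = c(6L), n_classes = 5L, dropout = 0,
                    l2 = 1e-3, batch_size = 4L)
  rng <- focalstim:::local_rng(42)
  params <- focalstim:::cnn_init(cfg, rng)
  plan <- focalstim:::cnn_plan(cfg, 4L)
  set.seed(7)
  X <- matrix(runif(400), 4, 100)
  Y <- diag(5)[c(1, 3, 2, 5), ]
  fwd <- focalstim:::cnn_forward(params, cfg, plan, X)
  grads <- focalstim:::cnn_backward(params, cfg, plan, fwd, Y)
  loss_at <- function(p) {
    f <- focalstim:::cnn_forward(p, cfg, plan, X)
    focalstim:::cnn_loss(p, cfg, f$probs, Y)
  }
  h <- 1e-5
  for (grp in c("conv_W", "conv_b", "dense_W", "dense_b")) {
    for (l in seq_along(params[[grp]])) {
      w <- params[[grp]][[l]]
      for (k in sample(length(w), min(5, length(w)))) {
        p1 <- params; p1[[grp]][[l]][k] <- w[k] + h
        p2 <- params; p2[[grp]][[l]][k] <- w[k] - h
        expect_equal(grads[[grp]][[l]][k],
                     (loss_at(p1) - loss_at(p2)) / (2 * h),
                     tolerance = 1e-4)
      }
    }
  }
})

test_that("train_cnn demands all classes and learns a separable toy set", {
  # toy corpus: blank (class 0) vs full-intensity square (class 3), padded
  # with tiny stand-ins for the other classes
  mk_img <- function(fill) {
    m <- matrix(0, 16, 16)
    if (fill == "square") m[5:12, 5:12] <- 1
    if (fill == "bar") m[8, 2:15] <- 1
    if (fill == "dot") m[7:9, 7:9] <- 1
    if (fill == "big") m[2:15, 2:15] <- 1
    m
  }
  kinds <- c("blank", "dot", "bar", "square", "big")
  set.seed(31)
  images <- list(); labels <- integer(0)
  for (cl in 0:4) {
    for (i in 1:40) {
      img <- mk_img(kinds[cl + 1])
      img <- pmin(pmax(img + matrix(rnorm(256, 0, 0.03), 16, 16), 0), 1)
      images <- c(images, list(img)); labels <- c(labels, cl)
    }
  }
  cfg <- cnn_config(input_side = 16L, conv_filters = c(4L, 8L),
                    dense_units = c(16L), epochs = 20L, batch_size = 16L,
                    dropout = 0.1, l2 = 1e-4)
  expect_error(train_cnn(list(images = images[labels != 2],
                              labels = labels[labels != 2]), cfg, seed = 1),
               "missing class")
  m <- train_cnn(list(images = images, labels = labels), cfg, seed = 1)
  expect_gte(mean(diag(m$confusion)) / mean(rowSums(m$confusion)), 0.9)
})

test_that("CNN training is reproducible for a fixed seed", {
  set.seed(1)
  images <- replicate(60, matrix(runif(256), 16, 16), simplify = FALSE)
  labels <- rep(0:4, 12)
  cfg <- cnn_config(input_side = 16L, conv_filters = c(3L, 4L),
                    dense_units = c(8L), epochs = 2L, batch_size = 8L)
  m1 <- train_cnn(list(images = images, labels = labels), cfg, seed = 9)
  m2 <- train_cnn(list(images = images, labels = labels), cfg, seed = 9)
  expect_identical(m1$confusion, m2$confusion)
  expect_identical(m1$params$conv_W, m2$params$conv_W)
})

test_that("prepare_cnn_input crops, downsamples and normalizes", {
  dff <- matrix(0, 192, 192)
  dff[90:102, 90:102] <- 0.6
  x <- prepare_cnn_input(dff, 48, max_factor = 3)
  expect_equal(dim(x), c(48, 48))
  expect_true(all(x >= 0 & x <= 1))
  expect_gt(max(x), 0.9)         # central response survives the crop
  expect_equal(sum(x > 0.5), sum(dff > 0.3) / 9, tolerance = 10)
})

test_that("classify_response without a model falls back to the rule label", {
  reg <- sample_region(5)
  p <- make_pulse(100, 5)
  map <- compute_activity_map(render_activity_images(reg, p, seed = 1))
  out <- classify_response(map, model = NULL)
  expect_equal(out$class, out$rule_class)
  expect_true(is.na(out$cnn_class))
})
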