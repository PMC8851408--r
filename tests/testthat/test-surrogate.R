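# Surrogate training and the objective.

test_that("prepare_training_set excludes no-response trials and normalizes", {
  mk_trial <- function(a, t, area, ecc, npx) {
    list(pulse = make_pulse(a, c(1, 2, 5, 10, 20)[t]),
         shape = structure(list(area_um2 = area, eccentricity = ecc,
                                n_active_pixels = as.integer(npx)),
                           class = "response_shape"))
  }
  trials <- list(mk_trial(50, 1, 3e4, 0.4, 200),
                 mk_trial(60, 2, 6e4, 0.5, 400),
                 mk_trial(70, 3, 0, 0, 0),        # class-0: excluded
                 mk_trial(80, 4, 4.5e4, 0.6, 300),
                 mk_trial(100, 5, 1.5e4, 0.3, 90))
  tab <- prepare_training_set(trials)
  expect_equal(nrow(tab), 4L)
  expect_equal(max(tab$area_normalized), 1)
  expect_equal(attr(tab, "area_max_um2"), 6e4)
  expect_equal(tab$area_normalized[tab$amplitude_uA == 50], 0.5)

  expect_error(prepare_training_set(list()),
               class = "focalstim_insufficient_data")
  expect_error(prepare_training_set(trials[3]),
               class = "focalstim_insufficient_data")
})

test_that("net weight Jacobian matches finite differences", {
  nf <- focalstim:::net_forward
  nj <- focalstim:::net_jacobian
  set.seed(4)
  X <- matrix(runif(26), 13, 2)
  w <- rnorm(focalstim:::net_n_weights(), 0, 0.5)
  J <- nj(w, X)
  h <- 1e-6
  for (k in sample(length(w), 12)) {
    e <- rep(0, length(w)); e[k] <- h
    expect_equal(J[, k], (nf(w + e, X) - nf(w - e, X)) / (2 * h),
                 tolerance = 1e-5)
  }
})

test_that("noiseless smooth-surface table is recovered with low test MSE", {
  trials <- fixture_trials(noiseless = TRUE)
  tab <- prepare_training_set(trials)
  pair <- train_surrogates(tab, seed = 2)
  expect_lte(pair$metrics$area_mse[["test"]], 0.05)
  expect_true(all(is.finite(objective(pair, seq(20, 110, 10), rep(3, 10)))))
})

test_that("constant-output tables are fitted to the constant", {
  tab <- data.frame(amplitude_uA = seq(20, 110, 10),
                    type_index = rep(1:5, 2),
                    area_normalized = rep(1, 10),
                    eccentricity = rep(0.37, 10))
  attr(tab, "area_max_um2") <- 5e4
  pair <- train_surrogates(tab, seed = 1)
  a <- runif(20, 20, 110); t <- runif(20, 1, 5)
  expect_equal(surrogate_area(pair, a, t), rep(1, 20), tolerance = 1e-3)
  expect_equal(surrogate_ecc(pair, a, t), rep(0.37, 20), tolerance = 1e-3)
})

test_that("a 5-point table trains with at least 3 training rows", {
  trials <- fixture_trials()[c(3, 12, 25, 33, 42)]
  tab <- prepare_training_set(trials)
  pair <- train_surrogates(tab, seed = 3)
  expect_gte(length(pair$split$train), 3L)
  expect_true(all(is.finite(c(pair$area_wts, pair$ecc_wts))))
})

test_that("training is deterministic for a fixed seed", {
  tab <- prepare_training_set(fixture_trials())
  p1 <- train_surrogates(tab, seed = 11)
  p2 <- train_surrogates(tab, seed = 11)
  expect_identical(p1$area_wts, p2$area_wts)
  expect_identical(p1$ecc_wts, p2$ecc_wts)
  expect_identical(objective_map(p1)$values, objective_map(p2)$values)
})

test_that("objective is |A - C| + E and nonnegative", {
  tab <- prepare_training_set(fixture_trials())
  pair <- train_surrogates(tab, seed = 5)
  set.seed(9)
  for (i in 1:50) {
    a <- runif(1, 20, 110); t <- runif(1, 1, 5); C <- runif(1, 0, 1)
    A <- surrogate_area(pair, a, t); E <- surrogate_ecc(pair, a, t)
    f <- objective(pair, a, t, C = C)
    expect_equal(f, abs(A - C) + E, tolerance = 1e-12)
    expect_gte(f, E)
    expect_gte(f, 0)
  }
})

test_that("objective gradient matches finite differences", {
  tab <- prepare_training_set(fixture_trials())
  pair <- train_surrogates(tab, seed = 5)
  h <- 1e-5
  set.seed(10)
  for (i in 1:10) {
    a <- runif(1, 25, 105); t <- runif(1, 1.2, 4.8)
    g <- objective_gradient(pair, a, t)
    gn <- c((objective(pair, a + h, t) - objective(pair, a - h, t)) / (2 * h),
            (objective(pair, a, t + h) - objective(pair, a, t - h)) / (2 * h))
    expect_equal(g, gn, tolerance = 1e-4)
  }
})

test_that("objective map has the documented shape and a nonnegative minimum", {
  tab <- prepare_training_set(fixture_trials())
  pair <- train_surrogates(tab, seed = 5)
  om <- objective_map(pair)
  expect_equal(dim(om$values), c((110 - 20) / 2 + 1, 5))
  expect_gte(om$min_value, 0)
  k <- which(om$values == om$min_value, arr.ind = TRUE)[1, ]
  expect_equal(om$amplitudes[k[1]], om$min_a)
  expect_equal(om$types[k[2]], om$min_t)
  # map minimum equals brute force over the same grid
  brute <- min(outer(om$amplitudes, om$types,
                     Vectorize(function(a, t) objective(pair, a, t))))
  expect_equal(om$min_value, brute)
})

test_that("surrogate archives survive a JSON round trip", {
  tab <- prepare_training_set(fixture_trials())
  pair <- train_surrogates(tab, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_surrogates(pair, path)
  back <- read_surrogates(path)
  a <- c(25, 60, 95); t <- c(1.5, 3, 4.5)
  expect_equal(surrogate_area(back, a, t), surrogate_area(pair, a, t))
  expect_equal(objective(back, a, t), objective(pair, a, t))
})

test_that("held-out MSE improves as the training sample grows", {
  # noiseless tables subsampled at the schedule sizes; median over seeds
  sizes <- c(5L, 10L, 20L, 46L)
  trials_all <- fixture_trials(noiseless = TRUE)
  med <- sapply(sizes, function(n) {
    mses <- sapply(1:8, function(s) {
      idx <- if (n == 46L) seq_along(trials_all) else {
        set.seed(derive_seed(s, n)); sort(sample(46, n))
      }
      tab <- tryCatch(prepare_training_set(trials_all[idx]),
                      focalstim_insufficient_data = function(e) NULL)
      if (is.null(tab)) return(NA_real_)
      pair <- train_surrogates(tab, seed = s)
      # held-out probe: latent surface at off-sample grid points
      probe <- prepare_training_set(trials_all)
      mean((surrogate_area(pair, probe$amplitude_uA, probe$type_index) *
              attr(tab, "area_max_um2") / attr(probe, "area_max_um2") -
              probe$area_normalized)^2)
    })
    median(mses, na.rm = TRUE)
  })
  expect_lt(med[4], med[1])          # 46-point fit beats 5-point fit
  expect_true(all(diff(med) <= 0.02))  # no large degradation along the way
})
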