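test_that("same-class kNN matches a brute-force distance sort", {
  # anchor at the origin with same-class points at known distances
  lay <- toy_layout(1L, 2L)
  x <- rbind(c(0, 0), c(1, 0), c(0, 2), c(3, 0), c(10, 10))
  ds <- toy_dataset(x, c("a", "a", "a", "a", "b"),
                    layout = lay)
  expect_identical(k_nearest_same_class(ds, 1L, 2L), c(2L, 3L))
  # k larger than class size - 1 caps at all other members
  expect_identical(k_nearest_same_class(ds, 1L, 10L), c(2L, 3L, 4L))
  # tie broken toward the lower index
  ds2 <- toy_dataset(rbind(c(0, 0), c(0, 1), c(1, 0)),
                     c("a", "a", "a"), layout = lay)
  expect_identical(k_nearest_same_class(ds2, 1L, 2L), c(2L, 3L))
  # singleton class is a hard error
  expect_error(k_nearest_same_class(ds, 5L, 1L), "single member")
})

test_that("kNN agrees with the oracle on random data", {
  ds <- random_dataset(n_per_class = 8L, n_classes = 3L, p = 12L, seed = 3L)
  for (anchor in seq_len(n_trials(ds)))
    expect_identical(k_nearest_same_class(ds, anchor, 3L),
                     knn_oracle(ds, anchor, 3L))
})

test_that("affine combination hits its endpoints and extrapolates exactly", {
  xi <- c(0, 0); xj <- c(1, 2)
  expect_identical(interp_extrap_sample(xi, xj, 0), xi)
  expect_identical(interp_extrap_sample(xi, xj, 1), xj)
  expect_identical(interp_extrap_sample(xi, xj, 2), c(2, 4))
  expect_error(interp_extrap_sample(1:2, 1:3, 0.5), "lengths")
})

test_that("interp-extrap samples are collinear with their parents", {
  ds <- random_dataset(n_per_class = 7L, n_classes = 3L, p = 240L)
  cfg <- augment_config("interp_extrap", n_synthetic = 500L,
                        c1 = -2, c2 = 3, seed = 9L)
  synth <- augment_interp_extrap(ds, cfg)
  expect_equal(n_trials(synth), 500L)
  expect_true(all(synth$is_synthetic))
  prov <- attr(synth, "provenance")
  res <- vapply(seq_len(500L), function(i)
    collinearity_residual(synth$features[i, ],
                          feature_row(ds, prov$anchor_id[i]),
                          feature_row(ds, prov$partner_id[i])),
    numeric(1))
  expect_lt(max(res), 1e-9)
  # labels equal the shared parent label
  expect_identical(as.character(synth$labels),
                   as.character(ds$labels[match(prov$anchor_id,
                                                ds$trial_id)]))
})

test_that("bounds inside [0,1] keep samples in the parent envelope", {
  ds <- random_dataset(n_per_class = 6L, n_classes = 2L, p = 60L)
  cfg <- augment_config("interp_extrap", n_synthetic = 300L,
                        c1 = 0, c2 = 1, seed = 2L)
  synth <- augment_interp_extrap(ds, cfg)
  prov <- attr(synth, "provenance")
  ok <- vapply(seq_len(300L), function(i) {
    xi <- feature_row(ds, prov$anchor_id[i])
    xj <- feature_row(ds, prov$partner_id[i])
    all(synth$features[i, ] >= pmin(xi, xj) - 1e-12) &&
      all(synth$features[i, ] <= pmax(xi, xj) + 1e-12)
  }, logical(1))
  expect_true(all(ok))
})

test_that("smote is bit-identical to interp-extrap with (0,1) bounds", {
  ds <- random_dataset(n_per_class = 6L, n_classes = 3L, p = 30L)
  s1 <- augment_smote(ds, 200L, k = 3L, seed = 17L)
  cfg <- augment_config("interp_extrap", n_synthetic = 200L, k = 3L,
                        c1 = 0, c2 = 1, seed = 17L)
  s2 <- augment_interp_extrap(ds, cfg)
  expect_identical(s1$features, s2$features)
  expect_identical(s1$labels, s2$labels)
  expect_identical(attr(s1, "provenance"), attr(s2, "provenance"))
})

test_that("smote alpha recovered by projection always lies in [0, 1]", {
  ds <- random_dataset(n_per_class = 5L, n_classes = 3L, p = 45L)
  synth <- augment_smote(ds, 400L, seed = 23L)
  prov <- attr(synth, "provenance")
  a <- vapply(seq_len(400L), function(i)
    recover_alpha(synth$features[i, ],
                  feature_row(ds, prov$anchor_id[i]),
                  feature_row(ds, prov$partner_id[i])),
    numeric(1))
  expect_true(all(a >= -1e-9 & a <= 1 + 1e-9))
  expect_equal(a, prov$alpha, tolerance = 1e-9)
})

test_that("cv parameter maps to bounds centred on 0.5", {
  expect_equal(cv_to_bounds(0.5), c(c1 = 0, c2 = 1))
  expect_equal(cv_to_bounds(2.5), c(c1 = -2, c2 = 3))
  expect_equal(cv_to_bounds(0.02), c(c1 = 0.48, c2 = 0.52))
  expect_error(cv_to_bounds(0), "positive")
  expect_error(cv_to_bounds(-1), "positive")
})

test_that("gaussian augmentation recovers its noise moments", {
  lay <- toy_layout(1L, 240L)
  parent <- toy_dataset(rbind(rnorm(240), rnorm(240)), c("a", "a"),
                        layout = lay)
  sigma <- 0.05
  synth <- augment_gaussian(parent, 4000L, sigma = sigma, seed = 31L)
  prov <- attr(synth, "provenance")
  dev <- synth$features - parent$features[prov$anchor_id, , drop = FALSE]
  sds <- apply(dev, 2L, sd)
  expect_gt(mean(sds >= 0.9 * sigma & sds <= 1.1 * sigma), 0.99)
  expect_lt(max(abs(colMeans(dev))), 4 * sigma / sqrt(4000))
  # sigma = 0 copies parents verbatim
  s0 <- augment_gaussian(parent, 10L, sigma = 0, seed = 1L)
  p0 <- attr(s0, "provenance")
  expect_equal(unname(s0$features),
               unname(parent$features[p0$anchor_id, , drop = FALSE]))
})

test_that("stretching keeps length, limits to identity and preserves monotonicity", {
  x <- cumsum(runif(80))
  y <- stretch_series(x, 0.1)
  expect_length(y, 80L)
  # reduced-prefix rule: round(80 / 1.1) = 73 retained samples
  expect_equal(y[80], x[73])
  expect_equal(y[1], x[1])
  # alpha -> 0 limit: m = n, identity
  expect_equal(stretch_series(x, 1e-9 + 1e-12), x, tolerance = 1e-6)
  # monotone input stays monotone (linear interpolation)
  set.seed(8)
  for (i in 1:10) {
    xm <- cumsum(abs(rnorm(40)))
    expect_true(!is.unsorted(stretch_series(xm, runif(1, 0.05, 0.9))))
  }
  expect_error(stretch_series(x, 1.2), "stretch_alpha")
  expect_error(stretch_series(x, 0), "stretch_alpha")
})

test_that("the literal prefix rule upsamples then truncates", {
  x <- seq(0, 1, length.out = 80)
  y <- stretch_series(x, 0.1, lengthen_prefix = TRUE)
  expect_length(y, 80L)
  # slower playback: values lag the original ramp
  expect_true(all(y <= x + 1e-12))
})

test_that("stretching respects sensor-segment boundaries", {
  # two sensors with disjoint value ranges: stretched segments never mix
  lay <- sensor_layout(c("A", "B"), 40L)
  seg1 <- seq(0, 1, length.out = 40)
  seg2 <- seq(100, 101, length.out = 40)
  ds <- enose_dataset(matrix(c(seg1, seg2), 1L), "a", lay)
  synth <- augment_stretch(ds, 5L, stretch_alpha = 0.3, seed = 4L)
  expect_true(all(synth$features[, 1:40] <= 1 + 1e-9))
  expect_true(all(synth$features[, 41:80] >= 100 - 1e-9))
})

test_that("noise-and-stretch emits matched pairs with preserved labels", {
  ds <- random_dataset(n_per_class = 4L, n_classes = 2L, p = 24L)
  synth <- augment_noise_and_stretch(ds, 100L, sigma = 0.05,
                                     stretch_alpha = 0.1, seed = 12L)
  expect_equal(n_trials(synth), 100L)
  prov <- attr(synth, "provenance")
  expect_equal(sum(prov$variant == "noise"), 50L)
  expect_equal(sum(prov$variant == "stretch"), 50L)
  expect_identical(as.character(synth$labels),
                   as.character(ds$labels[match(prov$anchor_id,
                                                ds$trial_id)]))
  expect_error(augment_noise_and_stretch(ds, 7L), "even")
})

test_that("every method preserves labels, counts, and determinism", {
  ds <- random_dataset(n_per_class = 5L, n_classes = 3L, p = 30L)
  configs <- list(
    augment_config("interp_extrap", n_synthetic = 60L, seed = 5L),
    augment_config("smote", n_synthetic = 60L, seed = 5L),
    augment_config("gaussian", n_synthetic = 60L, seed = 5L),
    augment_config("stretch", n_synthetic = 60L, seed = 5L),
    augment_config("gaussian_and_stretch", n_synthetic = 60L, seed = 5L))
  before <- ds$features
  for (cfg in configs) {
    s1 <- augment(ds, cfg)
    s2 <- augment(ds, cfg)
    expect_equal(n_trials(s1), 60L, info = cfg$method)
    expect_identical(s1$features, s2$features, info = cfg$method)
    expect_true(all(s1$is_synthetic), info = cfg$method)
    prov <- attr(s1, "provenance")
    expect_identical(as.character(s1$labels),
                     as.character(ds$labels[match(prov$anchor_id,
                                                  ds$trial_id)]),
                     info = cfg$method)
  }
  # originals never mutated
  expect_identical(ds$features, before)
})

test_that("augmentation refuses a singleton training class", {
  lay <- toy_layout(1L, 4L)
  ds <- toy_dataset(rbind(rnorm(4), rnorm(4), rnorm(4)),
                    c("a", "a", "b"), layout = lay)
  cfg <- augment_config("interp_extrap", n_synthetic = 5L, seed = 1L)
  expect_error(augment_interp_extrap(ds, cfg), "single training trial")
})
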