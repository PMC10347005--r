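#' Configuration for a data-augmentation method
#'
#' Bundles the method identifier with its parameters. Defaults follow the
#' benchmark settings used throughout the package: `k = 3` nearest
#' neighbours, extrapolation bounds `(c1, c2) = (-2, 3)`, Gaussian noise
#' `sigma = 0.05` V, stretch factor `stretch_alpha = 0.1`.
#'
#' @param method one of `"interp_extrap"`, `"smote"`, `"gaussian"`,
#'   `"stretch"`, `"gaussian_and_stretch"`.
#' @param n_synthetic number of synthetic trials to generate (N >= 0). For
#'   `"gaussian_and_stretch"` it must be even (N = 2T: one noise and one
#'   stretched trial per drawn parent).
#' @param k neighbour count for interpolation-based methods.
#' @param c1,c2 bounds of the uniform alpha interval; synthetic points are
#'   `x_i + alpha * (x_j - x_i)`. `c1 >= 0, c2 <= 1` is pure interpolation;
#'   bounds outside `[0, 1]` allow extrapolation beyond the parent segment.
#' @param sigma SD of the additive Gaussian noise, volts.
#' @param stretch_alpha stretch factor in (0, 1); larger values discard a
#'   longer tail before resampling, simulating a slower sensor response.
#' @param lengthen_prefix if `TRUE`, use the literal prefix-length rule
#'   `m = round(n * (1 + alpha))` (upsample then truncate) instead of the
#'   default reduced-prefix rule `m = round(n / (1 + alpha))`.
#' @param seed integer RNG seed.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(method = c("interp_extrap", "smote", "gaussian",
                                      "stretch", "gaussian_and_stretch"),
                           n_synthetic = 0L, k = 3L,
                           c1 = -2, c2 = 3, sigma = 0.05,
                           stretch_alpha = 0.1, lengthen_prefix = FALSE,
                           seed = 1L) {
  method <- match.arg(method)
  n_synthetic <- as.integer(n_synthetic)
  k <- as.integer(k)
  if (n_synthetic < 0L) stop_("n_synthetic must be >= 0")
  if (k < 1L) stop_("k must be >= 1")
  if (method == "interp_extrap" && !(c1 < c2))
    stop_("interp_extrap requires c1 < c2")
  if (sigma < 0) stop_("sigma must be >= 0")
  if (method %in% c("stretch", "gaussian_and_stretch") &&
      (stretch_alpha <= 0 || stretch_alpha >= 1))
    stop_("stretch_alpha must lie in (0, 1)")
  if (method == "gaussian_and_stretch" && n_synthetic %% 2L != 0L)
    stop_("gaussian_and_stretch produces pairs; n_synthetic must be even")
  structure(list(method = method, n_synthetic = n_synthetic, k = k,
                 c1 = c1, c2 = c2, sigma = sigma,
                 stretch_alpha = stretch_alpha, lengthen_prefix = lengthen_prefix,
                 seed = as.integer(seed)),
            class = "augment_config")
}

#' @export
print.augment_config <- function(x, ...) {
  cat(sprintf("<augment_config> method=%s N=%d", x$method, x$n_synthetic))
  extra <- switch(x$method,
    interp_extrap = sprintf(" k=%d alpha~U(%g, %g)", x$k, x$c1, x$c2),
    smote = sprintf(" k=%d alpha~U(0, 1)", x$k),
    gaussian = sprintf(" sigma=%g", x$sigma),
    stretch = sprintf(" stretch_alpha=%g", x$stretch_alpha),
    gaussian_and_stretch = sprintf(" sigma=%g stretch_alpha=%g",
                                   x$sigma, x$stretch_alpha))
  cat(extra, sprintf(" seed=%d\n", x$seed))
  invisible(x)
}

#' Map the half-width CV parameter to extrapolation bounds
#'
#' The alpha interval is parameterised by its half-width about 0.5:
#' `c1 = 0.5 - cv`, `c2 = 0.5 + cv`. `cv = 0.5` gives `(0, 1)` (pure
#' interpolation, the SMOTE regime); `cv = 2.5` gives `(-2, 3)`, the default
#' interpolation-extrapolation bounds.
#'
#' @param cv positive half-width.
#' @return numeric `c(c1, c2)`.
#' @export
cv_to_bounds <- function(cv) {
  if (!is.numeric(cv) || length(cv) != 1L || !is.finite(cv) || cv <= 0)
    stop_("cv must be a single positive number")
  c(c1 = 0.5 - cv, c2 = 0.5 + cv)
}

#' Same-class k-nearest neighbours of a trial
#'
#' Euclidean distance on the raw feature vectors; the anchor itself is
#' excluded and ties are broken toward the lower trial index so the result
#' is deterministic.
#'
#' @param dataset an `enose_dataset`.
#' @param anchor_index row index of the anchor trial.
#' @param k neighbours requested; capped at class size minus one.
#' @return integer vector of up to `k` trial indices, nearest first.
#' @export
k_nearest_same_class <- function(dataset, anchor_index, k) {
  stopifnot(inherits(dataset, "enose_dataset"))
  k <- as.integer(k)
  if (k < 1L) stop_("k must be >= 1")
  cl <- dataset$labels[anchor_index]
  members <- setdiff(which(dataset$labels == cl), anchor_index)
  if (length(members) == 0L)
    stop_(sprintf("class '%s' has a single member; no neighbour available",
                  as.character(cl)))
  d2 <- colSums((t(dataset$features[members, , drop = FALSE]) -
                   dataset$features[anchor_index, ])^2)
  members[order(d2, members)][seq_len(min(k, length(members)))]
}

#' Affine combination of two parent vectors
#'
#' `x_i + alpha * (x_j - x_i)`: `alpha` in `[0, 1]` interpolates on the
#' segment between the parents, `alpha` outside it extrapolates along the
#' same line.
#'
#' @param xi,xj numeric parent vectors of equal length.
#' @param alpha scalar mixing coefficient.
#' @return numeric vector.
#' @export
interp_extrap_sample <- function(xi, xj, alpha) {
  if (length(xi) != length(xj))
    stop_("parent vectors have different lengths")
  xi + alpha * (xj - xi)
}

# kNN table for all trials of a dataset (list of integer vectors); classes
# with a single member yield an error as soon as any trial needs a partner
same_class_knn_table <- function(train, k) {
  cc <- class_counts(train)
  singleton <- names(cc)[cc == 1L]
  if (length(singleton))
    stop_(sprintf(
      "class '%s' has a single training trial; interpolation needs >= 2",
      singleton[1L]))
  lapply(seq_len(n_trials(train)),
         function(i) k_nearest_same_class(train, i, k))
}

# shared sampler behind interp_extrap and smote: the two methods differ only
# in the alpha interval, so sharing the draw protocol makes the smote
# reduction exact
sample_interp_extrap <- function(train, n_synthetic, k, c1, c2, seed,
                                 tag = "synth") {
  stopifnot(inherits(train, "enose_dataset"))
  n <- n_trials(train)
  if (n == 0L) stop_("training set is empty")
  if (n_synthetic == 0L) return(empty_synthetic(train))
  knn <- same_class_knn_table(train, k)
  with_seed(seed, {
    anchors <- sample.int(n, n_synthetic, replace = TRUE)
    partners <- vapply(anchors, function(i) {
      nb <- knn[[i]]
      nb[sample.int(length(nb), 1L)]
    }, integer(1))
    alphas <- stats::runif(n_synthetic, c1, c2)
  })
  xi <- train$features[anchors, , drop = FALSE]
  xj <- train$features[partners, , drop = FALSE]
  synth <- xi + alphas * (xj - xi)
  out <- enose_dataset(synth, as.character(train$labels)[anchors],
                       train$layout,
                       trial_id = paste0(tag, "_", seq_len(n_synthetic)),
                       is_synthetic = rep(TRUE, n_synthetic),
                       classes = train$classes)
  attr(out, "provenance") <- data.frame(
    anchor_id = train$trial_id[anchors],
    partner_id = train$trial_id[partners],
    alpha = alphas, stringsAsFactors = FALSE)
  out
}

empty_synthetic <- function(train) {
  out <- enose_dataset(
    matrix(numeric(0), 0L, n_features(train$layout)),
    character(0), train$layout, trial_id = character(0),
    is_synthetic = logical(0), classes = train$classes)
  attr(out, "provenance") <- data.frame(anchor_id = character(0),
                                        partner_id = character(0),
                                        alpha = numeric(0),
                                        stringsAsFactors = FALSE)
  out
}

#' Interpolation-extrapolation augmentation
#'
#' The package's central augmenter. For each synthetic trial an anchor `x_i`
#' is drawn uniformly from the training set, a partner `x_j` uniformly from
#' the anchor's `k` same-class nearest neighbours, and
#' `x_new = x_i + alpha (x_j - x_i)` with `alpha ~ Uniform(c1, c2)`. Bounds
#' wider than `[0, 1]` generate points beyond the segment joining the
#' parents, increasing training-set variability; in the time domain this
#' produces both amplitude changes and lead/lag deformations of the voltage
#' curves. The synthetic label is the shared parent label.
#'
#' @param train training `enose_dataset` (never modified).
#' @param config an [augment_config()] with method `"interp_extrap"`.
#' @return an `enose_dataset` of `n_synthetic` trials flagged synthetic,
#'   with a `"provenance"` attribute recording parent ids and alpha draws.
#' @export
augment_interp_extrap <- function(train, config) {
  stopifnot(inherits(config, "augment_config"))
  sample_interp_extrap(train, config$n_synthetic, config$k,
                       config$c1, config$c2, config$seed, tag = "ie")
}

#' SMOTE augmentation
#'
#' Synthetic minority-oversampling in feature space: identical to
#' [augment_interp_extrap()] with the alpha interval fixed to `[0, 1]`, so
#' every synthetic point lies on the segment between its two same-class
#' parents. With the same seed the two functions produce bit-identical
#' output when the bounds agree.
#'
#' @param train training `enose_dataset`.
#' @param n_synthetic synthetic trials to generate.
#' @param k neighbour count (default 3).
#' @param seed integer RNG seed.
#' @return an `enose_dataset` of synthetic trials (see
#'   [augment_interp_extrap()]).
#' @export
augment_smote <- function(train, n_synthetic, k = 3L, seed = 1L) {
  sample_interp_extrap(train, as.integer(n_synthetic), as.integer(k),
                       0, 1, as.integer(seed), tag = "ie")
}

#' Gaussian-noise augmentation
#'
#' Each synthetic trial is a uniformly drawn parent plus i.i.d. zero-mean
#' Gaussian noise per feature component (`sigma` in volts).
#'
#' @param train training `enose_dataset`.
#' @param n_synthetic synthetic trials to generate.
#' @param sigma noise SD (>= 0); `sigma = 0` copies parents verbatim.
#' @param seed integer RNG seed.
#' @return an `enose_dataset` of synthetic trials with provenance.
#' @export
augment_gaussian <- function(train, n_synthetic, sigma = 0.05, seed = 1L) {
  stopifnot(inherits(train, "enose_dataset"))
  if (sigma < 0) stop_("sigma must be >= 0")
  n_synthetic <- as.integer(n_synthetic)
  n <- n_trials(train)
  if (n == 0L) stop_("training set is empty")
  if (n_synthetic == 0L) return(empty_synthetic(train))
  p <- n_features(train$layout)
  with_seed(seed, {
    parents <- sample.int(n, n_synthetic, replace = TRUE)
    eps <- matrix(stats::rnorm(n_synthetic * p, 0, sigma), n_synthetic, p)
  })
  synth <- train$features[parents, , drop = FALSE] + eps
  out <- enose_dataset(synth, as.character(train$labels)[parents],
                       train$layout,
                       trial_id = paste0("gn_", seq_len(n_synthetic)),
                       is_synthetic = rep(TRUE, n_synthetic),
                       classes = train$classes)
  attr(out, "provenance") <- data.frame(
    anchor_id = train$trial_id[parents],
    partner_id = NA_character_, alpha = NA_real_,
    stringsAsFactors = FALSE)
  out
}

#' Stretch a single time series to simulate a slower response
#'
#' Takes the first `m = round(n / (1 + stretch_alpha))` samples (`m < n`)
#' and linearly resamples them onto `n` equally spaced positions, so the
#' retained prefix is played back more slowly while the output keeps the
#' input length. With `lengthen_prefix = TRUE` the alternative prefix rule
#' `m = round(n * (1 + stretch_alpha))` is used: the series is upsampled to
#' `m` points and the first `n` are kept.
#'
#' @param x numeric series (one sensor segment), length >= 2.
#' @param stretch_alpha stretch factor in (0, 1).
#' @param lengthen_prefix use the literal prefix-length rule (default `FALSE`).
#' @return numeric vector of `length(x)`.
#' @export
stretch_series <- function(x, stretch_alpha, lengthen_prefix = FALSE) {
  n <- length(x)
  if (n < 2L) stop_("series must have length >= 2")
  if (stretch_alpha <= 0 || stretch_alpha >= 1)
    stop_("stretch_alpha must lie in (0, 1)")
  if (lengthen_prefix) {
    m <- round(n * (1 + stretch_alpha))
    up <- stats::approx(seq_len(n), x, xout = seq(1, n, length.out = m))$y
    return(up[seq_len(n)])
  }
  m <- round(n / (1 + stretch_alpha))
  stats::approx(seq_len(m), x[seq_len(m)],
                xout = seq(1, m, length.out = n))$y
}

# stretch every sensor segment of a concatenated feature vector
stretch_features <- function(features, layout, stretch_alpha,
                             lengthen_prefix = FALSE) {
  out <- features
  for (s in seq_along(layout$sensor_names)) {
    seg <- sensor_segment(layout, s)
    out[seg] <- stretch_series(features[seg], stretch_alpha, lengthen_prefix)
  }
  out
}

#' Gaussian-noise plus signal-stretching augmentation
#'
#' The combined baseline: `T = n_synthetic / 2` parents are drawn uniformly
#' and each yields two synthetic trials — one noise-perturbed copy and one
#' per-sensor-segment stretched copy — for `N = 2T` trials in total.
#' Stretching is applied separately within each sensor's segment of the
#' concatenated vector so channels are never mixed across a sensor boundary.
#'
#' @param train training `enose_dataset`.
#' @param n_synthetic total synthetic trials (even; `N = 2T`).
#' @param sigma Gaussian noise SD.
#' @param stretch_alpha stretch factor in (0, 1).
#' @param lengthen_prefix prefix rule flag, see [stretch_series()].
#' @param seed integer RNG seed.
#' @return an `enose_dataset`; provenance records each trial's parent and
#'   variant (`"noise"` or `"stretch"`).
#' @export
augment_noise_and_stretch <- function(train, n_synthetic, sigma = 0.05,
                                      stretch_alpha = 0.1,
                                      lengthen_prefix = FALSE, seed = 1L) {
  stopifnot(inherits(train, "enose_dataset"))
  n_synthetic <- as.integer(n_synthetic)
  if (n_synthetic %% 2L != 0L)
    stop_("n_synthetic must be even (one noise + one stretch per parent)")
  n <- n_trials(train)
  if (n == 0L) stop_("training set is empty")
  if (n_synthetic == 0L) return(empty_synthetic(train))
  T_ <- n_synthetic %/% 2L
  p <- n_features(train$layout)
  with_seed(seed, {
    parents <- sample.int(n, T_, replace = TRUE)
    eps <- matrix(stats::rnorm(T_ * p, 0, sigma), T_, p)
  })
  noise <- train$features[parents, , drop = FALSE] + eps
  stretched <- t(apply(train$features[parents, , drop = FALSE], 1,
                       stretch_features, layout = train$layout,
                       stretch_alpha = stretch_alpha,
                       lengthen_prefix = lengthen_prefix))
  out <- enose_dataset(rbind(noise, stretched),
                       rep(as.character(train$labels)[parents], 2L),
                       train$layout,
                       trial_id = c(paste0("gn_", seq_len(T_)),
                                    paste0("st_", seq_len(T_))),
                       is_synthetic = rep(TRUE, n_synthetic),
                       classes = train$classes)
  attr(out, "provenance") <- data.frame(
    anchor_id = rep(train$trial_id[parents], 2L),
    partner_id = NA_character_, alpha = NA_real_,
    variant = rep(c("noise", "stretch"), each = T_),
    stringsAsFactors = FALSE)
  out
}

#' Stretch-only augmentation
#'
#' Each synthetic trial is a uniformly drawn parent whose every sensor
#' segment is stretched by [stretch_series()].
#'
#' @inheritParams augment_noise_and_stretch
#' @return an `enose_dataset` of synthetic trials.
#' @export
augment_stretch <- function(train, n_synthetic, stretch_alpha = 0.1,
                            lengthen_prefix = FALSE, seed = 1L) {
  stopifnot(inherits(train, "enose_dataset"))
  n_synthetic <- as.integer(n_synthetic)
  n <- n_trials(train)
  if (n == 0L) stop_("training set is empty")
  if (n_synthetic == 0L) return(empty_synthetic(train))
  parents <- with_seed(seed, sample.int(n, n_synthetic, replace = TRUE))
  stretched <- t(apply(train$features[parents, , drop = FALSE], 1,
                       stretch_features, layout = train$layout,
                       stretch_alpha = stretch_alpha,
                       lengthen_prefix = lengthen_prefix))
  out <- enose_dataset(stretched, as.character(train$labels)[parents],
                       train$layout,
                       trial_id = paste0("st_", seq_len(n_synthetic)),
                       is_synthetic = rep(TRUE, n_synthetic),
                       classes = train$classes)
  attr(out, "provenance") <- data.frame(
    anchor_id = train$trial_id[parents],
    partner_id = NA_character_, alpha = NA_real_,
    stringsAsFactors = FALSE)
  out
}

#' Run any configured augmentation method
#'
#' Dispatches an [augment_config()] to the matching augmenter; the uniform
#' entry point used by the experiment harness.
#'
#' @param train training `enose_dataset`.
#' @param config an [augment_config()].
#' @return an `enose_dataset` of `config$n_synthetic` synthetic trials.
#' @export
augment <- function(train, config) {
  stopifnot(inherits(config, "augment_config"))
  switch(config$method,
    interp_extrap = augment_interp_extrap(train, config),
    smote = augment_smote(train, config$n_synthetic, config$k, config$seed),
    gaussian = augment_gaussian(train, config$n_synthetic, config$sigma,
                                config$seed),
    stretch = augment_stretch(train, config$n_synthetic,
                              config$stretch_alpha, config$lengthen_prefix,
                              config$seed),
    gaussian_and_stretch = augment_noise_and_stretch(
      train, config$n_synthetic, config$sigma, config$stretch_alpha,
      config$lengthen_prefix, config$seed))
}
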