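#' Sensor layout of an electronic-nose feature vector
#'
#' An e-nose trial concatenates, sensor by sensor, the rising-phase voltage
#' response of each gas sensor (sampled at 1 Hz). The layout records the
#' sensor order and the number of samples kept per sensor, fixing the total
#' feature length `n = S * samples_per_sensor`: 240 features for 3 sensors,
#' 400 for 5.
#'
#' @param sensor_names character vector of sensor labels, in concatenation
#'   order.
#' @param samples_per_sensor samples retained from each sensor's rise phase
#'   (default 80, i.e. 80 s at 1 Hz).
#' @return an object of class `sensor_layout`.
#' @export
sensor_layout <- function(sensor_names, samples_per_sensor = 80L) {
  sensor_names <- as.character(sensor_names)
  samples_per_sensor <- as.integer(samples_per_sensor)
  if (length(sensor_names) < 1L || anyDuplicated(sensor_names))
    stop_("sensor_names must be a non-empty vector of unique labels")
  if (is.na(samples_per_sensor) || samples_per_sensor < 2L)
    stop_("samples_per_sensor must be an integer >= 2")
  structure(list(sensor_names = sensor_names,
                 samples_per_sensor = samples_per_sensor),
            class = "sensor_layout")
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat(sprintf("<sensor_layout> %d sensor(s) x %d samples = %d features\n",
              length(x$sensor_names), x$samples_per_sensor, n_features(x)))
  cat("  sensors:", paste(x$sensor_names, collapse = ", "), "\n")
  invisible(x)
}

#' Total feature length implied by a layout
#' @param layout a `sensor_layout`.
#' @return integer, `S * samples_per_sensor`.
#' @export
n_features <- function(layout) {
  length(layout$sensor_names) * layout$samples_per_sensor
}

# index range of sensor s within the concatenated vector
sensor_segment <- function(layout, s) {
  m <- layout$samples_per_sensor
  ((s - 1L) * m + 1L):(s * m)
}

#' Assemble a feature vector from per-sensor series
#'
#' Concatenates one rising-response series per sensor, in layout order, into
#' the flat feature vector used by every downstream stage.
#'
#' @param per_sensor_series list of numeric vectors, one per sensor, each of
#'   length `layout$samples_per_sensor`.
#' @param layout a [sensor_layout()].
#' @return numeric vector of length `n_features(layout)`.
#' @export
assemble_features <- function(per_sensor_series, layout) {
  stopifnot(inherits(layout, "sensor_layout"))
  S <- length(layout$sensor_names)
  if (length(per_sensor_series) != S)
    stop_(sprintf("expected %d per-sensor series, got %d",
                  S, length(per_sensor_series)))
  for (s in seq_len(S)) {
    len <- length(per_sensor_series[[s]])
    if (len != layout$samples_per_sensor)
      stop_(sprintf(
        "sensor '%s': series has length %d, expected %d",
        layout$sensor_names[s], len, layout$samples_per_sensor))
  }
  unlist(per_sensor_series, use.names = FALSE)
}

#' Labelled collection of e-nose trials
#'
#' The dataset container used throughout the package: a trials-by-features
#' voltage matrix, one class label per trial, per-trial identifiers, a flag
#' marking synthetic (augmented) trials, and the shared [sensor_layout()].
#'
#' @param features numeric matrix, one row per trial, `n_features(layout)`
#'   columns.
#' @param labels class labels (coerced to factor); the class inventory is
#'   `levels(labels)` unless `classes` is given.
#' @param layout a [sensor_layout()].
#' @param trial_id character vector of unique trial identifiers (default
#'   `"t1"`, `"t2"`, ...).
#' @param is_synthetic logical flag per trial (default all `FALSE`).
#' @param classes optional explicit class inventory (ordered character
#'   vector); labels outside it are rejected.
#' @return an object of class `enose_dataset`.
#' @export
enose_dataset <- function(features, labels, layout,
                          trial_id = NULL, is_synthetic = NULL,
                          classes = NULL) {
  stopifnot(inherits(layout, "sensor_layout"))
  features <- as.matrix(features)
  if (!is.numeric(features))
    stop_("features must be numeric")
  n <- nrow(features)
  if (ncol(features) != n_features(layout))
    stop_(sprintf("features have %d columns; layout implies %d",
                  ncol(features), n_features(layout)))
  if (n > 0 && any(!is.finite(features)))
    stop_("features contain non-finite values")
  labels <- as.character(labels)
  if (length(labels) != n)
    stop_("labels length does not match number of trials")
  if (is.null(classes)) classes <- sort(unique(labels))
  classes <- as.character(classes)
  unknown <- setdiff(labels, classes)
  if (length(unknown))
    stop_("labels outside the class inventory: ",
          paste(unique(unknown), collapse = ", "))
  trial_id <- trial_id %||% paste0("t", seq_len(n))
  trial_id <- as.character(trial_id)
  if (length(trial_id) != n || anyDuplicated(trial_id))
    stop_("trial_id must be unique and match the number of trials")
  is_synthetic <- is_synthetic %||% rep(FALSE, n)
  is_synthetic <- as.logical(is_synthetic)
  if (length(is_synthetic) != n || anyNA(is_synthetic))
    stop_("is_synthetic must be logical, one value per trial")
  dimnames(features) <- list(trial_id, feature_names(layout))
  structure(list(features = features,
                 labels = factor(labels, levels = classes),
                 trial_id = trial_id,
                 is_synthetic = is_synthetic,
                 layout = layout,
                 classes = classes),
            class = "enose_dataset")
}

feature_names <- function(layout) paste0("f", seq_len(n_features(layout)) - 1L)

#' Number of trials in a dataset
#' @param dataset an `enose_dataset`.
#' @export
n_trials <- function(dataset) nrow(dataset$features)

#' Per-class trial counts
#' @param dataset an `enose_dataset`.
#' @return named integer vector over the full class inventory.
#' @export
class_counts <- function(dataset) table(dataset$labels)

#' @export
print.enose_dataset <- function(x, ...) {
  cat(sprintf("<enose_dataset> %d trial(s), %d features (%d sensor(s) x %d), %d class(es)\n",
              n_trials(x), n_features(x$layout),
              length(x$layout$sensor_names), x$layout$samples_per_sensor,
              length(x$classes)))
  if (n_trials(x)) {
    cc <- class_counts(x)
    cat("  per class:", paste(sprintf("%s=%d", names(cc), cc), collapse = " "), "\n")
    if (any(x$is_synthetic))
      cat(sprintf("  synthetic trials: %d\n", sum(x$is_synthetic)))
  }
  invisible(x)
}

#' @export
summary.enose_dataset <- function(object, ...) {
  print(object)
  if (n_trials(object)) {
    rng <- range(object$features)
    cat(sprintf("  feature range: [%.4g, %.4g] V\n", rng[1], rng[2]))
  }
  invisible(object)
}

#' Subset a dataset by trial indices
#' @param x an `enose_dataset`.
#' @param i integer or logical trial index.
#' @param ... unused.
#' @export
`[.enose_dataset` <- function(x, i, ...) {
  enose_dataset(x$features[i, , drop = FALSE],
                as.character(x$labels)[i],
                x$layout,
                trial_id = x$trial_id[i],
                is_synthetic = x$is_synthetic[i],
                classes = x$classes)
}

#' Concatenate datasets sharing a layout and class inventory
#' @param ... `enose_dataset` objects.
#' @return combined `enose_dataset`.
#' @export
bind_datasets <- function(...) {
  ds <- list(...)
  stopifnot(length(ds) >= 1L, all(vapply(ds, inherits, TRUE, "enose_dataset")))
  first <- ds[[1L]]
  for (d in ds[-1L]) {
    if (n_features(d$layout) != n_features(first$layout))
      stop_("datasets have incompatible layouts")
    if (!identical(d$classes, first$classes))
      stop_("datasets have different class inventories")
  }
  enose_dataset(do.call(rbind, lapply(ds, `[[`, "features")),
                unlist(lapply(ds, function(d) as.character(d$labels))),
                first$layout,
                trial_id = unlist(lapply(ds, `[[`, "trial_id")),
                is_synthetic = unlist(lapply(ds, `[[`, "is_synthetic")),
                classes = first$classes)
}

#' Stratified train/test split
#'
#' Randomly partitions each class into exactly `train_per_class` training and
#' `test_per_class` test trials (the standard protocol here is 7 train + 5
#' test from 12 trials per class). The partition is deterministic for a fixed
#' seed and the two parts are disjoint by construction; the experiment
#' harness splits once per experiment so that the same test set serves all
#' repeated trainings.
#'
#' @param dataset an `enose_dataset`.
#' @param train_per_class,test_per_class trials per class in each part.
#' @param seed integer RNG seed.
#' @return list with elements `train` and `test`, both `enose_dataset`.
#' @export
stratified_split <- function(dataset, train_per_class, test_per_class, seed) {
  stopifnot(inherits(dataset, "enose_dataset"))
  train_per_class <- as.integer(train_per_class)
  test_per_class <- as.integer(test_per_class)
  if (train_per_class < 0L || test_per_class < 0L)
    stop_("per-class counts must be non-negative")
  need <- train_per_class + test_per_class
  cc <- class_counts(dataset)
  short <- names(cc)[cc < need]
  if (length(short))
    stop_(sprintf("class '%s' has %d trial(s); %d required",
                  short[1L], cc[[short[1L]]], need))
  idx_train <- integer(0)
  idx_test <- integer(0)
  with_seed(seed, {
    for (cl in dataset$classes) {
      members <- which(dataset$labels == cl)
      picked <- sample(members, need)
      idx_train <- c(idx_train, picked[seq_len(train_per_class)])
      idx_test <- c(idx_test, picked[train_per_class + seq_len(test_per_class)])
    }
  })
  list(train = dataset[sort(idx_train)], test = dataset[sort(idx_test)])
}

#' Write a dataset to CSV (with a layout JSON sidecar)
#'
#' CSV columns: `trial_id,label,is_synthetic,f0,...,f{n-1}`, one trial per
#' row, UTF-8. The sensor layout is written next to the CSV as
#' `<path>.layout.json` so that a save/load round trip restores the dataset
#' exactly (labels) and to full printed precision (features).
#'
#' @param dataset an `enose_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "enose_dataset"))
  df <- data.frame(trial_id = dataset$trial_id,
                   label = as.character(dataset$labels),
                   is_synthetic = dataset$is_synthetic,
                   stringsAsFactors = FALSE)
  feat <- as.data.frame(dataset$features)
  names(feat) <- feature_names(dataset$layout)
  utils::write.csv(cbind(df, feat), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(
    list(sensor_names = dataset$layout$sensor_names,
         samples_per_sensor = dataset$layout$samples_per_sensor,
         classes = dataset$classes),
    layout_sidecar(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

layout_sidecar <- function(path) paste0(path, ".layout.json")

#' Read a dataset written by [save_dataset()]
#'
#' @param path CSV path; the layout sidecar `<path>.layout.json` must exist
#'   unless `layout` is supplied.
#' @param layout optional [sensor_layout()] overriding the sidecar.
#' @param classes optional class inventory overriding the sidecar.
#' @return an `enose_dataset`.
#' @export
load_dataset <- function(path, layout = NULL, classes = NULL) {
  if (!file.exists(path)) stop_("file not found: ", path)
  if (is.null(layout)) {
    sc <- layout_sidecar(path)
    if (!file.exists(sc))
      stop_("layout sidecar not found: ", sc,
            " (pass `layout` explicitly to override)")
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    layout <- sensor_layout(meta$sensor_names, meta$samples_per_sensor)
    classes <- classes %||% meta$classes
  }
  nf <- n_features(layout)
  nfields <- utils::count.fields(path, sep = ",", quote = "\"")
  if (is.null(nfields) || length(nfields) == 0L)
    stop_("no trials: file is empty")
  expected <- nf + 3L
  bad <- which(nfields != expected)
  if (length(bad))
    stop_(sprintf("row %d has %d fields, expected %d",
                  bad[1L], nfields[bad[1L]], expected))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop_("no trials: file has a header but no rows")
  feat <- suppressWarnings(
    matrix(as.numeric(as.matrix(df[, -(1:3), drop = FALSE])),
           nrow = nrow(df)))
  if (anyNA(feat)) {
    bad_row <- which(rowSums(is.na(feat)) > 0)[1L]
    stop_(sprintf("row %d contains a non-numeric feature cell", bad_row + 1L))
  }
  df$is_synthetic <- as.logical(df$is_synthetic)
  if (!is.null(classes)) {
    unknown <- setdiff(df$label, classes)
    if (length(unknown)) {
      bad_row <- which(df$label %in% unknown)[1L]
      stop_(sprintf("row %d has unknown label '%s'",
                    bad_row + 1L, df$label[bad_row]))
    }
  }
  enose_dataset(feat, df$label, layout,
                trial_id = df$trial_id,
                is_synthetic = df$is_synthetic,
                classes = classes)
}

# --- adapter registry for external dataset dialects (best effort) ---------

adapter_registry <- new.env(parent = emptyenv())

#' Register a reader for an external dataset dialect
#'
#' Hook for loading third-party on-disk formats (e.g. a deposited raw e-nose
#' archive whose dialect this package does not hard-code). The adapter is a
#' function `(path, ...) -> enose_dataset`.
#'
#' @param name adapter name.
#' @param fun reader function.
#' @export
register_dataset_adapter <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = adapter_registry)
  invisible(name)
}

#' Load a dataset through a registered adapter
#' @param name adapter name previously registered.
#' @param path path handed to the adapter.
#' @param ... forwarded to the adapter.
#' @export
load_with_adapter <- function(name, path, ...) {
  if (!exists(name, envir = adapter_registry, inherits = FALSE))
    stop_("no dataset adapter registered under '", name, "'")
  out <- get(name, envir = adapter_registry)(path, ...)
  stopifnot(inherits(out, "enose_dataset"))
  out
}
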