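#' Plan for a benchmarking experiment
#'
#' Collects everything the harness needs: the data source (an existing
#' dataset or a generator scenario), the per-class split sizes, the
#' classifier specs, the augmentation configuration, the augmentation-size
#' grid, the number of repeated trainings per condition, and one master
#' seed. The master seed spawns labelled substreams (data / split /
#' augment x repeat / train x repeat) via [derive_seed()], so any cell of a
#' sweep can be reproduced in isolation and a full run is deterministic.
#'
#' The split is drawn once per experiment — the same untouched test set
#' serves every condition and repeat, and test trials are never available
#' as augmentation parents.
#'
#' @param dataset an `enose_dataset`, or `NULL` to generate one.
#' @param scenario generator scenario name (see [default_scenarios()]) or a
#'   [generator_config()]; used when `dataset` is `NULL`.
#' @param trials_per_class trials per class to generate (default 12).
#' @param train_per_class,test_per_class split sizes (defaults 7 and 5).
#' @param classifiers list of [classifier_spec()] (default ANN-3-50).
#' @param augment an [augment_config()] carrying the method and its
#'   parameters; `n_synthetic` is overridden by the sweep grids.
#' @param sizes augmentation-size grid (default `c(0, 100, 500, 2000)`).
#' @param repeats trainings per condition (default 10).
#' @param fresh_draws draw new synthetic data for every repeat (default
#'   `TRUE`), so repeat-to-repeat spread reflects both augmentation and
#'   training randomness; `FALSE` freezes one synthetic pool per condition.
#' @param seed master seed.
#' @return an object of class `experiment_plan`.
#' @export
experiment_plan <- function(dataset = NULL, scenario = "overlapping",
                            trials_per_class = 12L,
                            train_per_class = 7L, test_per_class = 5L,
                            classifiers = list(classifier_spec("ann")),
                            augment = augment_config("interp_extrap"),
                            sizes = c(0L, 100L, 500L, 2000L),
                            repeats = 10L, fresh_draws = TRUE, seed = 1L) {
  if (inherits(classifiers, "classifier_spec"))
    classifiers <- list(classifiers)
  stopifnot(all(vapply(classifiers, inherits, TRUE, "classifier_spec")),
            inherits(augment, "augment_config"))
  sizes <- as.integer(sizes)
  if (any(sizes < 0L)) stop_("augmentation sizes must be non-negative")
  repeats <- as.integer(repeats)
  if (repeats < 1L) stop_("repeats must be >= 1")
  structure(list(dataset = dataset, scenario = scenario,
                 trials_per_class = as.integer(trials_per_class),
                 train_per_class = as.integer(train_per_class),
                 test_per_class = as.integer(test_per_class),
                 classifiers = classifiers, augment = augment,
                 sizes = sizes, repeats = repeats,
                 fresh_draws = isTRUE(fresh_draws),
                 seed = as.integer(seed)),
            class = "experiment_plan")
}

# materialize the plan's dataset and its one train/test split
resolve_plan <- function(plan) {
  stopifnot(inherits(plan, "experiment_plan"))
  ds <- plan$dataset
  if (is.null(ds)) {
    cfg <- if (inherits(plan$scenario, "generator_config")) plan$scenario
           else scenario(plan$scenario)
    ds <- generate_dataset(cfg, plan$trials_per_class,
                           seed = derive_seed(plan$seed, "data"))
  }
  split <- stratified_split(ds, plan$train_per_class, plan$test_per_class,
                            seed = derive_seed(plan$seed, "split"))
  list(dataset = ds, train = split$train, test = split$test)
}

#' Assert that no test trial leaked into an augmentation's parents
#'
#' Every augmenter records the ids of the original trials its synthetic
#' trials derive from; this guard checks that all parents come from the
#' training partition and none from the test partition. The harness calls
#' it on every run.
#'
#' @param synth synthetic `enose_dataset` with a `"provenance"` attribute.
#' @param train,test the split partitions.
#' @return `TRUE` invisibly; errors on a violation.
#' @export
assert_no_leakage <- function(synth, train, test) {
  prov <- attr(synth, "provenance")
  if (is.null(prov)) stop_("synthetic dataset carries no provenance")
  parents <- stats::na.omit(unique(c(prov$anchor_id, prov$partner_id)))
  if (length(setdiff(parents, train$trial_id)))
    stop_("augmentation parent outside the training partition")
  if (length(intersect(parents, test$trial_id)))
    stop_("test trial used as an augmentation parent")
  invisible(TRUE)
}

#' Repeated trainings of one experimental condition
#'
#' Runs `repeats` independent trainings of one classifier at one
#' augmentation size on a fixed train/test split: per repeat, a synthetic
#' pool is drawn (fresh per repeat by default), appended to the raw
#' training trials, the classifier is trained on its own seed substream,
#' and accuracy is measured on the untouched test set. Test data are never
#' augmented.
#'
#' @param train,test the split partitions.
#' @param spec a [classifier_spec()].
#' @param aug an [augment_config()]; its `n_synthetic` is replaced by
#'   `n_aug`.
#' @param n_aug synthetic trials per repeat (0 bypasses augmentation).
#' @param repeats number of trainings.
#' @param seed substream seed for this condition.
#' @param fresh_draws redraw synthetic data each repeat (default `TRUE`).
#' @return a `sweep_result`: condition label, per-repeat accuracies, their
#'   mean and SD (SD reported as 0 with `single_repeat = TRUE` when
#'   `repeats = 1`).
#' @export
run_repeated <- function(train, test, spec, aug, n_aug, repeats = 10L,
                         seed = 1L, fresh_draws = TRUE) {
  stopifnot(inherits(spec, "classifier_spec"),
            inherits(aug, "augment_config"))
  n_aug <- as.integer(n_aug)
  repeats <- as.integer(repeats)
  accs <- numeric(repeats)
  for (r in seq_len(repeats)) {
    pool <- train
    if (n_aug > 0L) {
      draw_tag <- if (fresh_draws) r else 0L
      cfg <- aug
      cfg$n_synthetic <- n_aug
      cfg$seed <- derive_seed(seed, "augment", n_aug, draw_tag)
      synth <- augment(train, cfg)
      assert_no_leakage(synth, train, test)
      pool <- bind_datasets(train, synth)
    }
    model <- enose_train(spec, pool,
                         seed = derive_seed(seed, "train", n_aug, r))
    accs[r] <- evaluate(model, test)$accuracy
  }
  sweep_result(sprintf("%s @ %d AD", spec_label(spec), n_aug), accs)
}

#' Bundle per-repeat accuracies into a summarised result
#' @param condition label of the experimental condition.
#' @param accuracies per-repeat accuracy percentages.
#' @return a `sweep_result` with `mean` and `sd` recomputable from
#'   `accuracies`.
#' @export
sweep_result <- function(condition, accuracies) {
  stopifnot(length(accuracies) >= 1L)
  single <- length(accuracies) == 1L
  structure(list(condition = condition, accuracies = accuracies,
                 mean = mean(accuracies),
                 sd = if (single) 0 else stats::sd(accuracies),
                 single_repeat = single),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s: mean %.2f%% sd %.2f (%d repeat%s)\n",
              x$condition, x$mean, x$sd, length(x$accuracies),
              if (length(x$accuracies) == 1L) "" else "s"))
  invisible(x)
}

#' Augmentation-size sweep over classifiers
#'
#' One [run_repeated()] cell per (classifier, augmentation size), on a
#' single shared split. Returns the long per-repeat table plus
#' classifier-by-size matrices of mean accuracy and accuracy SD (the
#' benchmark's two summary tables).
#'
#' @param plan an [experiment_plan()].
#' @return list with `cells` (named list of `sweep_result`), `mean` and
#'   `sd` matrices (rows = classifiers, columns = sizes), `long`
#'   (data.frame: classifier, n_aug, repeat, accuracy), and the resolved
#'   `split`.
#' @export
aug_size_sweep <- function(plan) {
  res <- resolve_plan(plan)
  labels <- vapply(plan$classifiers, spec_label, "")
  mean_m <- sd_m <- matrix(NA_real_, length(labels), length(plan$sizes),
                           dimnames = list(labels,
                                           paste0(plan$sizes, " AD")))
  cells <- list()
  long <- NULL
  for (i in seq_along(plan$classifiers)) {
    for (j in seq_along(plan$sizes)) {
      n_aug <- plan$sizes[j]
      sr <- run_repeated(res$train, res$test, plan$classifiers[[i]],
                         plan$augment, n_aug, plan$repeats,
                         seed = derive_seed(plan$seed, "cell",
                                            labels[i], n_aug),
                         fresh_draws = plan$fresh_draws)
      cells[[sr$condition]] <- sr
      mean_m[i, j] <- sr$mean
      sd_m[i, j] <- sr$sd
      long <- rbind(long, data.frame(classifier = labels[i], n_aug = n_aug,
                                     rep = seq_along(sr$accuracies),
                                     accuracy = sr$accuracies))
    }
  }
  list(cells = cells, mean = mean_m, sd = sd_m, long = long,
       split = res[c("train", "test")])
}

#' Forward moving average with truncation at the tail
#'
#' Smooths an accuracy series by averaging each value with its following
#' `window - 1` values; positions with fewer successors average over the
#' available suffix.
#'
#' @param x numeric series.
#' @param window window length including the current value (default 11).
#' @return numeric vector of `length(x)`.
#' @export
moving_average_forward <- function(x, window = 11L) {
  n <- length(x)
  vapply(seq_len(n), function(i) mean(x[i:min(n, i + window - 1L)]),
         numeric(1))
}

#' Sweep of the extrapolation-bound parameter CV
#'
#' For each value on the CV grid the bounds `(0.5 - cv, 0.5 + cv)` are fed
#' to the interpolation-extrapolation augmenter (`n_aug` synthetic trials,
#' default 500), the plan's first classifier is trained and scored, and the
#' accuracy series is smoothed with the forward moving average
#' (window 11). `cv = 0.5` is the pure-interpolation cell.
#'
#' @param plan an [experiment_plan()].
#' @param cv_grid strictly increasing positive grid (default 40 points on
#'   `[0.02, 4]`).
#' @param n_aug synthetic trials per cell (default 500).
#' @param repeats trainings per cell (default 1, matching a one-bar-per-CV
#'   sweep; raise for mean curves).
#' @return list with `table` (data.frame: cv, c1, c2, accuracy, smoothed)
#'   and `cells`.
#' @export
cv_sweep <- function(plan, cv_grid = seq(0.02, 4, length.out = 40L),
                     n_aug = 500L, repeats = 1L) {
  if (any(cv_grid <= 0)) stop_("cv grid must be positive")
  if (is.unsorted(cv_grid, strictly = TRUE))
    stop_("cv grid must be strictly increasing")
  res <- resolve_plan(plan)
  spec <- plan$classifiers[[1L]]
  acc <- numeric(length(cv_grid))
  cells <- vector("list", length(cv_grid))
  for (i in seq_along(cv_grid)) {
    bounds <- cv_to_bounds(cv_grid[i])
    cfg <- plan$augment
    cfg$method <- "interp_extrap"
    cfg$c1 <- bounds[["c1"]]
    cfg$c2 <- bounds[["c2"]]
    sr <- run_repeated(res$train, res$test, spec, cfg, n_aug, repeats,
                       seed = derive_seed(plan$seed, "cv", i),
                       fresh_draws = plan$fresh_draws)
    acc[i] <- sr$mean
    cells[[i]] <- sr
  }
  tab <- data.frame(cv = cv_grid,
                    c1 = 0.5 - cv_grid, c2 = 0.5 + cv_grid,
                    accuracy = acc,
                    smoothed = moving_average_forward(acc, 11L))
  list(table = tab, cells = cells, split = res[c("train", "test")])
}

#' Compare augmentation methods over a size grid
#'
#' One mean-accuracy cell per (method, size) with the plan's first
#' classifier, all on the same split. The interpolation-based methods use
#' the plan's `k` and bounds; the noise/stretch baselines its `sigma` and
#' `stretch_alpha`.
#'
#' @param plan an [experiment_plan()].
#' @param methods augmentation method names (default all five).
#' @param sizes synthetic-pool sizes (default `c(100, 500, 2000)`).
#' @return list with `mean` (methods x sizes matrix), `sd`, `cells`.
#' @export
method_comparison <- function(plan,
                              methods = c("interp_extrap", "smote",
                                          "gaussian", "stretch",
                                          "gaussian_and_stretch"),
                              sizes = c(100L, 500L, 2000L)) {
  if (!length(methods)) stop_("methods must be non-empty")
  known <- c("interp_extrap", "smote", "gaussian", "stretch",
             "gaussian_and_stretch")
  bad <- setdiff(methods, known)
  if (length(bad)) stop_("unknown method name: ", paste(bad, collapse = ", "))
  res <- resolve_plan(plan)
  spec <- plan$classifiers[[1L]]
  sizes <- as.integer(sizes)
  mean_m <- sd_m <- matrix(NA_real_, length(methods), length(sizes),
                           dimnames = list(methods, paste0(sizes, " AD")))
  cells <- list()
  for (i in seq_along(methods)) {
    cfg <- plan$augment
    cfg$method <- methods[i]
    for (j in seq_along(sizes)) {
      sr <- run_repeated(res$train, res$test, spec, cfg, sizes[j],
                         plan$repeats,
                         seed = derive_seed(plan$seed, "method",
                                            methods[i], sizes[j]),
                         fresh_draws = plan$fresh_draws)
      cells[[sprintf("%s @ %d AD", methods[i], sizes[j])]] <- sr
      mean_m[i, j] <- sr$mean
      sd_m[i, j] <- sr$sd
    }
  }
  list(mean = mean_m, sd = sd_m, cells = cells,
       split = res[c("train", "test")])
}

#' Read an experiment plan from a YAML file
#'
#' Schema (all keys optional, defaults as in [experiment_plan()]):
#' ```yaml
#' scenario: overlapping
#' trials_per_class: 12
#' train_per_class: 7
#' test_per_class: 5
#' sizes: [0, 100, 500, 2000]
#' repeats: 10
#' seed: 1
#' dataset: path/to/data.csv        # overrides scenario
#' augment: {method: interp_extrap, k: 3, c1: -2, c2: 3,
#'           sigma: 0.05, stretch_alpha: 0.1}
#' classifiers:
#'   - {kind: ann, nl: 3, nu: 50}
#'   - {kind: msvm}
#' ```
#'
#' @param path YAML file path.
#' @return an [experiment_plan()].
#' @export
read_plan <- function(path) {
  y <- yaml::read_yaml(path)
  aug_args <- y$augment %||% list()
  aug_args$n_synthetic <- aug_args$n_synthetic %||% 0L
  augment <- do.call(augment_config, aug_args)
  classifiers <- lapply(y$classifiers %||% list(list(kind = "ann")),
                        function(cs) do.call(classifier_spec, cs))
  dataset <- if (!is.null(y$dataset)) load_dataset(y$dataset) else NULL
  experiment_plan(dataset = dataset,
                  scenario = y$scenario %||% "overlapping",
                  trials_per_class = y$trials_per_class %||% 12L,
                  train_per_class = y$train_per_class %||% 7L,
                  test_per_class = y$test_per_class %||% 5L,
                  classifiers = classifiers, augment = augment,
                  sizes = y$sizes %||% c(0L, 100L, 500L, 2000L),
                  repeats = y$repeats %||% 10L,
                  fresh_draws = y$fresh_draws %||% TRUE,
                  seed = y$seed %||% 1L)
}

#' Write sweep outputs to disk
#'
#' Emits the long per-repeat accuracies as CSV and the mean/SD matrices as
#' JSON under an output directory.
#'
#' @param sweep result of [aug_size_sweep()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_sweep <- function(sweep, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sweep$long, file.path(dir, "accuracies.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(mean = sweep$mean, sd = sweep$sd),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(dir)
}
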