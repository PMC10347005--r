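# fixtures built in code: tiny deterministic datasets for unit tests

toy_layout <- function(S = 1L, m = 4L) {
  sensor_layout(paste0("S", seq_len(S)), m)
}

# dataset from an explicit feature matrix (rows = trials)
toy_dataset <- function(features, labels, layout = NULL) {
  features <- as.matrix(features)
  if (is.null(layout)) layout <- toy_layout(1L, ncol(features))
  enose_dataset(features, labels, layout)
}

# two well-separated 240-dim Gaussian blobs: linearly separable by a margin
separable_blobs <- function(n_per_class = 15L, p = 240L, seed = 42L) {
  set.seed(seed)
  x1 <- matrix(rnorm(n_per_class * p, 0, 0.05), n_per_class, p)
  x2 <- matrix(rnorm(n_per_class * p, 2, 0.05), n_per_class, p)
  lay <- sensor_layout(paste0("S", 1:3), p / 3L)
  enose_dataset(rbind(x1, x2), rep(c("1", "2"), each = n_per_class), lay)
}

# random multi-class dataset with mild structure (for augmentation tests)
random_dataset <- function(n_per_class = 6L, n_classes = 3L, p = 240L,
                           seed = 7L) {
  set.seed(seed)
  feats <- do.call(rbind, lapply(seq_len(n_classes), function(c)
    matrix(rnorm(n_per_class * p, mean = c, sd = 0.5), n_per_class, p)))
  lay <- if (p %% 3L == 0L) sensor_layout(paste0("S", 1:3), p %/% 3L)
         else sensor_layout("S1", p)
  enose_dataset(feats, rep(as.character(seq_len(n_classes)),
                           each = n_per_class), lay)
}

# brute-force same-class kNN oracle: full pairwise distance sort
knn_oracle <- function(dataset, anchor, k) {
  cl <- dataset$labels[anchor]
  members <- setdiff(which(dataset$labels == cl), anchor)
  d <- sqrt(colSums((t(dataset$features[members, , drop = FALSE]) -
                       dataset$features[anchor, ])^2))
  members[order(d, members)][seq_len(min(k, length(members)))]
}

# recover alpha for one synthetic row by projection onto the parent line
recover_alpha <- function(synth_row, xi, xj) {
  d <- xj - xi
  sum((synth_row - xi) * d) / sum(d * d)
}

# relative collinearity residual of a synthetic row w.r.t. its parents
collinearity_residual <- function(synth_row, xi, xj) {
  a <- recover_alpha(synth_row, xi, xj)
  sqrt(sum((synth_row - xi - a * (xj - xi))^2)) / sqrt(sum((xj - xi)^2))
}

feature_row <- function(dataset, id) dataset$features[id, ]
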