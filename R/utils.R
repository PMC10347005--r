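# internal helpers shared across modules

#' Derive a reproducible child seed from a master seed and labels
#'
#' Hashes the master seed together with an arbitrary sequence of labels
#' (characters or integers) into a 31-bit integer, so that every randomized
#' stage of an experiment (split, per-repeat augmentation, per-repeat
#' training) runs on its own documented RNG stream and any single cell of a
#' sweep can be re-run in isolation.
#'
#' @param seed integer master seed.
#' @param ... labels identifying the substream, e.g. `"augment"`, repeat
#'   index.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  tokens <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
                  collapse = "/")
  h <- 0
  for (ch in utf8ToInt(tokens)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# run expr under a local RNG state seeded with `seed`, restoring the caller's
# stream afterwards so package functions never perturb user RNG
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)
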