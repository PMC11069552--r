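# Internal helpers shared across modules.

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so seeded operations compose without
# disturbing each other.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a global seed
#'
#' Stage seeds are a deterministic integer mix of the global seed and the
#' stage name, so enabling or disabling one pipeline stage never shifts the
#' randomness of another. The mix is a 31-bit linear-congruential fold of the
#' UTF-8 bytes of the stage name into the global seed.
#'
#' @param global_seed integer global seed.
#' @param stage character stage name.
#' @return a positive integer seed below 2^31.
#' @export
derive_seed <- function(global_seed, stage) {
  m <- 2147483647  # 2^31 - 1
  h <- as.numeric(global_seed) %% m
  for (b in utf8ToInt(stage)) h <- (h * 69069 + b * 2654435761) %% m
  as.integer(h %% (m - 1L) + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

logistic <- function(x) 1 / (1 + exp(-x))

# Stratified fold assignment for k-fold cross-validation: within each class,
# shuffled indices are dealt round-robin over folds.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}
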