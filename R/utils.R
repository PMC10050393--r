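`%||%` <- function(x, y) if (is.null(x)) y else x

# Deterministic sub-seed derivation: one master seed fans out to independent
# streams (split / sampler / augmentation / init). Kept below 2^31 - 1.
deriveSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  offsets <- c(split = 1L, sampler = 2L, augment = 3L, init = 4L,
               generator = 5L, tsne = 6L)
  off <- if (is.character(stream)) {
    if (!stream %in% names(offsets)) stop("unknown stream: ", stream)
    offsets[[stream]]
  } else as.integer(stream)
  as.integer((as.numeric(seed) * 48271 + off * 7919) %% 2147483629)
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

assertFinite <- function(x, stage) {
  if (!all(is.finite(x)))
    stop("non-finite values encountered at stage: ", stage)
  invisible(x)
}
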