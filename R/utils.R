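`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a deterministic per-stage seed from a global seed
#'
#' One global seed reproduces a whole pipeline run: each stage draws its own
#' seed from the global one by hashing the stage name, so stages are
#' decoupled (re-ordering or skipping a stage does not shift another stage's
#' random stream).
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483629  # large prime < 2^31
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  as.integer(h + 1)
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Fixed-precision number formatting shared by all text writers, so that
# identical objects always serialize to identical bytes and round-trip
# through the matching reader to < 1e-12.
fmt_num <- function(x) sprintf("%.17g", x)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}
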