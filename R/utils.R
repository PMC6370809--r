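# internal helpers shared across modules

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are pure functions of
#' their spec and never perturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_rng_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-stage seed from a global seed
#'
#' Stable polynomial hash of the stage name folded into the global seed,
#' kept below 2^31 so it is always a valid R integer seed. One global seed
#' therefore reproduces every stochastic stage of a pipeline run.
#'
#' @param seed integer global seed.
#' @param stage character scalar naming the stage.
#' @return an integer seed.
#' @export
#' @examples
#' derive_seed(42L, "gsea")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage),
            length(stage) == 1L)
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.double(abs(seed)) %% m
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  as.integer(h)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  }
  ok <- if (strict_lower) x > lower else x >= lower
  if (!ok || x > upper) {
    stop(sprintf("'%s' = %s is outside its valid range", name, format(x)),
         call. = FALSE)
  }
  invisible(x)
}
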