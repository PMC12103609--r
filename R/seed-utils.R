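# Reproducible randomness helpers.
#
# All simulators take an optional integer `seed`.  When supplied, the RNG
# state is set for the duration of the call and restored afterwards, so a
# simulation is a pure function of (parameters, seed) and never perturbs the
# caller's random stream.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible sub-stream seed
#'
#' Maps a global seed plus a sequence of string/number keys (site id, morph,
#' model name, replicate index, ...) to a deterministic 31-bit seed.  Every
#' stochastic stage of the pipeline draws its seed through this rule, so
#' adding a site or reordering the loop over morphs cannot perturb any other
#' stage's random numbers.
#'
#' The rule is a polynomial string hash: the keys are joined with `"/"`,
#' folded as `h <- (h * 31 + utf8(char)) mod 2147483563`, and mixed with the
#' global seed as `(seed * 69069 + h) mod 2147483563`.  All arithmetic stays
#' below 2^53 so the result is exact in double precision.
#'
#' @param seed integer global seed.
#' @param ... keys (coerced with `as.character`) identifying the sub-stream.
#' @return a single integer in `[1, 2147483562]`.
#' @examples
#' derive_seed(1, "img0001", "orange", "tc")
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483563
  key <- paste(vapply(list(...), as.character, ""), collapse = "/")
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% m
  s <- ((as.double(seed) %% m) * 69069 + h) %% m
  as.integer(s + 1)
}
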