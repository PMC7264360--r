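#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals never perturb
#' the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing number", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed and a stream label
#'
#' Deterministic counter/label based splitting so that adding one stochastic
#' component does not perturb the draws of any other. Result is always a
#' positive integer below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param ... character or integer labels identifying the stream.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(master) %% m
  for (code in utf8ToInt(labels)) {
    h <- (h * 131 + code) %% m
  }
  h <- (h * 48271) %% m # Lehmer step to decorrelate nearby labels
  as.integer(h + 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Population (n-denominator) standard deviation
#' @noRd
pop_sd <- function(x) {
  n <- length(x)
  sqrt(sum((x - mean(x))^2) / n)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}
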