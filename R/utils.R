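#' @useDynLib uitrans, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor rnorm rpois quantile var median acf sd dnorm pnorm runif
#' @importFrom utils head tail
NULL

# Evaluate code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so generators are pure functions of their arguments.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a child seed from a parent seed and a stream index, staying within
# 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 9973) %% 2147483629)
}

stopifnot_scalar_num <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max)
    stop(sprintf("`%s` must be a single finite number in [%g, %g]", name, min, max),
         call. = FALSE)
  invisible(x)
}

# FNV-1a hash of a character string, returned as hex; used to fingerprint
# configurations in checkpoints.
fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), b) + 2^30  # keep in int range
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

config_hash <- function(cfg) {
  fnv1a(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA))
}
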