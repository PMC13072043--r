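#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so library functions never perturb a caller's stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministic mixing keeps independent stages (splitting, edge sampling,
#' weight init, each swarm fitness evaluation) on separate streams that all
#' flow from one global seed. Result always fits a 32-bit integer.
#'
#' @param seed master integer seed.
#' @param offset integer stream identifier.
#' @return integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, offset = 0L) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(offset) * 69621 + 1
  as.integer(s %% 2147483647)
}

# FNV-1a over a string; enough to fingerprint a resolved config without
# pulling in a hashing dependency. 32-bit arithmetic emulated in doubles
# (split multiply keeps every intermediate below 2^53).
fnv1a_hex <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

#' Fingerprint an R object (canonical JSON, FNV-1a)
#' @param x a list-like configuration object.
#' @return 8-hex-digit string.
#' @export
config_hash <- function(x) {
  fnv1a_hex(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                             null = "null", force = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# argmax with ties broken by the lower index
argmax_first <- function(x) which.max(x)
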