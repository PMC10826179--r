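#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific random seed from a global seed
#'
#' Mixes a global integer seed with a character tag (FNV-1a over the tag
#' bytes) so that each stochastic stage of a run draws from its own stream,
#' reproducible in isolation. The result is always in `[0, 2^31 - 1]`.
#'
#' @param seed Integer global seed.
#' @param tag Character scalar naming the stage.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- fnv1a(paste0(tag, ":", format(seed, scientific = FALSE)))
  as.integer(h %% 2147483647)
}

# 32-bit FNV-1a hash, done in double arithmetic (kept exact below 2^53 by
# splitting the multiply into 16-bit halves)
fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    h <- xor32(h, b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * m + ((hi * m) %% 65536) * 65536) %% 4294967296
  }
  h
}

fnv1a_hex <- function(h) {
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# FNV-1a hash of a text file's contents, as hex (for run manifests)
fnv1a_file <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  fnv1a_hex(fnv1a(txt))
}

# xor of a non-negative double (< 2^32) with a byte, via its low 8 bits
xor32 <- function(h, b) {
  low <- h %% 256
  h - low + bitwXor(as.integer(low), as.integer(b))
}

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so
#' package internals never perturb the user's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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
  set.seed(as.integer(seed))
  expr
}

stop_mp <- function(...) stop(..., call. = FALSE)

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop_mp(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}
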