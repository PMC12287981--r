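`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a child RNG seed from a root seed and an index path
#'
#' Hierarchical seed splitting: each participant/day/stage gets its own
#' reproducible stream derived from one global seed, so regenerating a single
#' entity is independent of the order entities are visited in.
#'
#' @param seed integer root seed.
#' @param ... integer (or coercible) path components, e.g. participant index,
#'   day index.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
split_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(as.integer(seed) %% 2147483647L)
  for (k in idx) {
    kk <- if (is.character(k)) sum(utf8ToInt(k) * seq_along(utf8ToInt(k))) else as.double(k)
    h <- (h * 48271 + kk * 10007 + 1) %% 2147483647
  }
  as.integer(h)
}

# FNV-1a hash of a character scalar; used to stamp pipeline artifacts.
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648), as.integer(b))
    h <- (as.double(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stopf("'%s' must be a probability in [0, 1]", name)
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x != round(x))
    stopf("'%s' must be a nonnegative integer", name)
  invisible(x)
}

check_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) && (if (strict) x > 0 else x >= 0)
  if (!ok) stopf("'%s' must be %s", name, if (strict) "> 0" else ">= 0")
  invisible(x)
}
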