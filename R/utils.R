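# internal helpers shared across modules

# Set the RNG state for the duration of the calling function only.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  expr <- if (has_old) {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  } else {
    quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  set.seed(as.integer(seed))
  invisible(NULL)
}

# FNV-1a over a deparsed object; used for config fingerprints in manifests.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  # multiply mod 2^32 in doubles without losing precision
  mulmod <- function(a, b) {
    hi <- a %/% 65536
    lo <- a %% 65536
    (((hi * b) %% 65536) * 65536 + lo * b) %% 4294967296
  }
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256  # xor touches only the low byte (b < 256)
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- mulmod(h, 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_demosync <- function(...) stop(..., call. = FALSE)
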