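#' @keywords internal
#' @useDynLib netcost, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic child seed for a named pipeline stage; stays inside 32-bit range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483587L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Upper-triangle (i < j) logical index for an n x n matrix.
upper_tri <- function(n) upper.tri(matrix(0, n, n))

# FNV-1a hash of a character string, reported as 8 hex digits; used to stamp
# run manifests so outputs can be traced back to a configuration.
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

stop_netcost <- function(...) stop(..., call. = FALSE)
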