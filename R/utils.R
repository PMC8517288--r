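# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Wrap angles to [0, 2*pi).
wrap_2pi <- function(theta) {
  out <- theta %% (2 * pi)
  # guard against 2*pi returned by floating-point roundoff of tiny negatives
  out[out >= 2 * pi] <- 0
  out
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Signed circular difference a - b mapped to (-pi, pi].
circ_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  d[d > pi] <- d[d > pi] - 2 * pi
  d
}

# Parse ISO-8601-ish timestamps ("T" or space separated), UTC by default.
parse_timestamp <- function(x, tz = "UTC") {
  x <- as.character(x)
  out <- as.POSIXct(x, tz = tz, tryFormats = c(
    "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
    "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d"
  ), optional = TRUE)
  out
}

format_timestamp <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
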