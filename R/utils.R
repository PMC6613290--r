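#' Derive independent child seeds from one top-level seed
#'
#' All randomness in a pipeline run flows from a single integer seed; stages
#' (corpus generation, fold assignment, embedding, classifier, bootstrap)
#' receive child seeds derived deterministically from it, so that changing one
#' stage's code never silently reshuffles another stage's random stream.
#'
#' @param seed Integer top-level seed.
#' @param n Number of child seeds to derive.
#' @return Integer vector of `n` seeds, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # 64-bit-free LCG (Park-Miller style on doubles): stays below 2^31
  s <- (abs(as.numeric(seed)) %% 2147483646) + 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (s * 48271) %% 2147483647
    out[i] <- s
  }
  as.integer(out)
}

#' Coerce timestamps to fractional days
#'
#' The pipeline measures time in fractional days relative to an arbitrary
#' epoch. Numeric input is passed through; `POSIXct`/`Date` input is converted
#' (days since the Unix epoch, UTC).
#'
#' @param x Numeric, `Date`, or `POSIXct` vector.
#' @return Numeric vector of fractional days.
#' @export
as_days <- function(x) {
  if (inherits(x, "POSIXct")) return(as.numeric(x) / 86400)
  if (inherits(x, "Date")) return(as.numeric(x))
  if (is.numeric(x)) return(as.numeric(x))
  stop("timestamps must be numeric days, Date, or POSIXct", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a stage manifest (provenance sidecar) as JSON
write_manifest <- function(path, ...) {
  info <- list(...)
  info$written <- format(Sys.time(), tz = "UTC", usetz = TRUE)
  jsonlite::write_json(info, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
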