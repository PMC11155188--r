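#' Derive a stage-specific seed from a global seed
#'
#' A single global seed fans out to per-stage seeds via a deterministic
#' string hash, so each pipeline stage is independently reproducible.
#'
#' @param seed Integer global seed.
#' @param ... Character or numeric labels identifying the stage
#'   (e.g. `"local_train"`, round number, center id).
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(labels)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

#' Clip values into the unit interval
#' @param x Numeric vector, matrix or array.
#' @return `x` with values clamped to `[0, 1]`.
#' @keywords internal
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Round to a fixed number of decimals, half to even
#'
#' Matches conventional table reporting (three decimals, banker's rounding).
#' @param x Numeric.
#' @param digits Decimal places (default 3).
#' @keywords internal
round_half_even <- function(x, digits = 3) round(x, digits)

## internal: stop with a classed error so callers/tests can match on class
fh_stop <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

## internal: structured JSON-lines logger; sink may be NULL (silent),
## a connection/file path, or "" for stdout mirror
fh_log <- function(sink, record) {
  if (is.null(sink)) return(invisible(NULL))
  line <- jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA)
  if (identical(sink, "")) message(line) else cat(line, "\n", sep = "", file = sink, append = TRUE)
  invisible(NULL)
}
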