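#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed report tables in this field
#' conventionally round half up. `0.05 -> 0.1` at `digits = 1`.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(57.27, 22.147, 17.0022), 1)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Population standard deviation
#'
#' Replicate-consistency screening uses the population (denominator `n`)
#' standard deviation, not the sample estimator.
#'
#' @param x numeric vector.
#' @return scalar population SD; 0 for a single value.
#' @export
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

# Detect the field delimiter of a delimited text file from its header line.
detect_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) {
    return("\t")
  }
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

# stop() with a condition class so callers can test failures precisely
pki_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "pki_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
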