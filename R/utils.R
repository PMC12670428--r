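#' Round half away from zero
#'
#' Base R's `round()` rounds half to even, while printed structural tables in
#' this field conventionally round half up (e.g. 0.2025 nm^2 prints as
#' 0.203).  This helper reproduces that convention for comparisons against
#' printed values.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# minimum-image displacement for orthorhombic boxes; d and box in nm.
# Works on vectors/matrices recycled against box per column.
minimum_image <- function(d, box) {
  d - box * round(d / box)
}

# pooled standard deviation of per-molecule observations across groups:
# the plain sd of the pooled sample (groups here carry no separate means
# to preserve, the pooling is across leaflets/frames/replicates).
pooled_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x)
}

# trapezoidal integral over an ordered grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}
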