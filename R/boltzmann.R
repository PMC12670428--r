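#' Histogram a bonded-distribution sample
#'
#' Bin width defaults follow the derivation convention: 0.01 Angstrom for
#' bond lengths, 1 degree for angles.  The density is normalized to unit
#' integral over the binned range.
#'
#' @param samples Numeric vector (Angstrom for bonds, degrees for angles).
#' @param kind `"bond"` or `"angle"`.
#' @param bin_width Bin width; default by `kind`.
#' @param temperature Temperature in K carried to the inversion.
#' @return A `distribution_histogram`: tibble (`x`, `density`) with
#'   attributes `kind`, `bin_width`, `n`, `temperature`.
#' @export
distribution_histogram <- function(samples, kind = c("bond", "angle"),
                                   bin_width = NULL, temperature = 305) {
  kind <- match.arg(kind)
  samples <- samples[is.finite(samples)]
  if (!length(samples)) abort("empty sample")
  if (stats::sd(samples) == 0) abort("zero-variance samples cannot be binned into a distribution")
  if (is.null(bin_width)) bin_width <- if (kind == "bond") 0.01 else 1
  lo <- floor(min(samples) / bin_width) * bin_width
  hi <- ceiling(max(samples) / bin_width) * bin_width
  if (hi <= lo + bin_width) hi <- lo + 2 * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(samples, breaks = breaks, plot = FALSE)
  out <- tibble(x = h$mids, density = h$density)
  structure(out, kind = kind, bin_width = bin_width, n = length(samples),
            temperature = temperature,
            class = c("distribution_histogram", class(out)))
}

# Gaussian-kernel smoothing of the density column, used only for peak
# detection (never for fitting).
.smooth_density <- function(x, d, sd_bins = 2) {
  n <- length(d)
  k <- dnorm(seq(-4 * sd_bins, 4 * sd_bins), sd = sd_bins)
  k <- k / sum(k)
  pad <- (length(k) - 1) / 2
  dp <- c(rep(d[1], pad), d, rep(d[n], pad))
  as.numeric(stats::filter(dp, k, sides = 2))[pad + seq_len(n)]
}

# local maxima indices of a vector (strict on the left, non-strict right)
.local_maxima <- function(d) {
  n <- length(d)
  if (n < 3) return(integer())
  which(d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n]) + 1
}

#' Fit a single Gaussian to a binned distribution
#'
#' Moment estimates refined by least squares on the density; the fitted
#' width is corrected for grouping (Sheppard's correction, subtracting
#' bin_width^2/12 from the variance) so it estimates the width of the
#' underlying sample rather than of the binned histogram.  A multimodal
#' flag is raised when, after Gaussian-kernel smoothing, a secondary peak
#' exceeds 20% of the main peak height; the returned parameters are then the
#' single-Gaussian compromise fit (the behaviour used when bimodal mapped
#' distributions are deliberately represented by one harmonic term).
#'
#' @param hist A [distribution_histogram()].
#' @return A `gaussian_fit` with elements `x0`, `sigma`, `multimodal`,
#'   `kind`, `n`, `temperature`, `histogram`.
#' @export
fit_gaussian <- function(hist) {
  if (!inherits(hist, "distribution_histogram")) {
    abort("fit_gaussian expects a distribution_histogram")
  }
  x <- hist$x
  d <- hist$density
  bw <- attr(hist, "bin_width")
  if (length(x) < 2 || sum(d) == 0) abort("empty or degenerate histogram")
  mu <- sum(x * d) / sum(d)
  s2 <- sum((x - mu)^2 * d) / sum(d)
  if (s2 <= 0) abort("zero-variance histogram")
  s <- sqrt(s2)
  fit <- tryCatch({
    m <- nls(d ~ a * exp(-(x - m0)^2 / (2 * sg^2)),
             start = list(a = max(d), m0 = mu, sg = s),
             control = stats::nls.control(warnOnly = TRUE))
    cf <- coef(m)
    list(x0 = unname(cf["m0"]), sigma = abs(unname(cf["sg"])))
  }, error = function(e) list(x0 = mu, sigma = s))
  # Sheppard's correction for grouping
  fit$sigma <- sqrt(max(fit$sigma^2 - bw^2 / 12, 1e-12))

  sm <- .smooth_density(x, d, sd_bins = 2)
  peaks <- .local_maxima(sm)
  multimodal <- FALSE
  if (length(peaks) >= 2) {
    hts <- sm[peaks]
    ord <- order(hts, decreasing = TRUE)
    main <- peaks[ord[1]]
    # secondary peaks must be separated from the main one by > 4 bins
    rest <- peaks[ord[-1]]
    rest <- rest[abs(rest - main) > 4]
    if (length(rest) && max(sm[rest]) > 0.2 * sm[main]) multimodal <- TRUE
  }
  structure(list(x0 = fit$x0, sigma = fit$sigma, multimodal = multimodal,
                 kind = attr(hist, "kind"), n = attr(hist, "n"),
                 temperature = attr(hist, "temperature"), histogram = hist),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> %s: x0 = %.4f, sigma = %.5f (n = %d%s)\n",
              x$kind, x$x0, x$sigma, x$n,
              if (x$multimodal) ", multimodal" else ""))
  invisible(x)
}

#' @export
tidy.gaussian_fit <- function(x, ...) {
  tibble(kind = x$kind, x0 = x$x0, sigma = x$sigma,
         multimodal = x$multimodal, n = x$n, temperature = x$temperature)
}

#' @export
glance.gaussian_fit <- function(x, ...) tidy(x)

#' Boltzmann inversion of a Gaussian width
#'
#' A harmonic term sampled at temperature T produces a Gaussian distribution
#' `y = exp(-k (x - x0)^2 / (2 kB T))` with width `sigma = sqrt(kB T / k)`;
#' inverting gives `k = kB T / sigma^2`.  Bond widths in Angstrom give k in
#' kcal/(mol A^2); angle widths must be supplied in radians to give k in
#' kcal/(mol rad^2).
#'
#' @param sigma Gaussian width (Angstrom or radians), > 0.
#' @param temperature Temperature in K, > 0.
#' @return Force constant k.
#' @examples
#' boltzmann_invert(0.0807, 305)   # ~93 kcal/(mol A^2)
#' @export
boltzmann_invert <- function(sigma, temperature) {
  if (any(sigma <= 0)) abort("sigma must be positive")
  if (any(temperature <= 0)) abort("temperature must be positive")
  kB_kcal * temperature / sigma^2
}

#' @rdname boltzmann_invert
#' @param k Force constant, > 0.
#' @return `harmonic_width()` returns the Gaussian width sqrt(kB T / k).
#' @export
harmonic_width <- function(k, temperature) {
  if (any(k <= 0)) abort("k must be positive")
  if (any(temperature <= 0)) abort("temperature must be positive")
  sqrt(kB_kcal * temperature / k)
}

#' Sample a harmonic bonded term
#'
#' Draws from the Gaussian implied by `(x0, k, T)`: Normal(x0, sqrt(kB T/k)).
#' For angle terms `x0` is in degrees and `k` in kcal/(mol rad^2); the width
#' is converted back to degrees.
#'
#' @param x0 Equilibrium value (Angstrom or degrees).
#' @param k Force constant (kcal/(mol A^2) or kcal/(mol rad^2)).
#' @param temperature Temperature, K.
#' @param n Number of draws.
#' @param kind `"bond"` or `"angle"`.
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of n samples.
#' @export
sample_term <- function(x0, k, temperature, n, kind = c("bond", "angle"),
                        seed = NULL) {
  kind <- match.arg(kind)
  if (n < 1) abort("n must be at least 1")
  sg <- harmonic_width(k, temperature)
  if (kind == "angle") sg <- sg * 180 / pi
  with_seed_if(seed, rnorm(n, x0, sg))
}

#' Derive a harmonic bonded-parameter table from samples
#'
#' Fits a single Gaussian per term (histogram at the derivation bin widths,
#' moment estimate refined by least squares) and Boltzmann-inverts the width
#' into a force constant.  Angle widths are converted to radians before
#' inversion, so angle force constants are in kcal/(mol rad^2).  Terms whose
#' smoothed histogram shows a secondary peak above 20% of the main peak keep
#' the single-Gaussian compromise fit and carry `multimodal = TRUE`.  Terms
#' with fewer than 100 samples are excluded with a warning.
#'
#' @param samples Tibble with columns `term`, `kind`, `value` (Angstrom or
#'   degrees), e.g. from [bonded_samples()] or [gen_bonded_dataset()].
#' @param temperature Temperature in K of the sampled ensemble.
#' @param bond_bin,angle_bin Histogram bin widths.
#' @return Tibble with columns `term`, `kind`, `x0`, `sigma`, `k`, `n`,
#'   `multimodal`, `temperature`.
#' @export
derive_bonded_table <- function(samples, temperature = 305,
                                bond_bin = 0.01, angle_bin = 1) {
  counts <- count(samples, .data$term, .data$kind)
  thin <- filter(counts, .data$n < 100)
  if (nrow(thin)) {
    warn(paste0("excluding terms with < 100 samples: ",
                paste(thin$term, collapse = ", ")))
  }
  keep <- dplyr::anti_join(samples, select(thin, "term", "kind"),
                           by = c("term", "kind"))
  if (nrow(keep) == 0) {
    return(tibble(term = character(), kind = character(), x0 = numeric(),
                  sigma = numeric(), k = numeric(), n = integer(),
                  multimodal = logical(), temperature = numeric()))
  }
  keep %>%
    group_by(.data$term, .data$kind) %>%
    dplyr::group_modify(function(df, key) {
      bw <- if (key$kind == "bond") bond_bin else angle_bin
      ft <- fit_gaussian(distribution_histogram(df$value, key$kind,
                                                bin_width = bw,
                                                temperature = temperature))
      sg <- if (key$kind == "angle") ft$sigma * pi / 180 else ft$sigma
      tibble(x0 = ft$x0, sigma = ft$sigma,
             k = boltzmann_invert(sg, temperature),
             n = ft$n, multimodal = ft$multimodal,
             temperature = temperature)
    }) %>%
    ungroup()
}

#' Published bonded parameters and peak positions for the OH3/OH4 beads
#'
#' Reference values for the hydroxyl beads added to the phytosphingosine
#' base (OH3) and the alpha-hydroxy acyl chain (OH4) of the CG ceramide
#' models: harmonic bond terms (equilibrium length in Angstrom, force
#' constant in kcal/(mol A^2), derived at 305 K) and the CG peak centers of
#' the associated angle distributions (degrees; force constants for the
#' angle terms are not published, left `NA`).
#'
#' @return Tibble with columns `term`, `kind`, `x0`, `k`, `temperature`.
#' @export
oh_bead_reference <- function() {
  tibble(
    term = c("TAIL-OH3", "TAIL-OH4",
             "TAIL-TAIL-OH3", "TAIL-TAIL-OH4",
             "MHEAD2-TAIL-OH3", "AMIDE-TAIL-OH4"),
    kind = c("bond", "bond", "angle", "angle", "angle", "angle"),
    x0 = c(2.40, 2.50, 144, 141, 65, 71),
    k = c(93.0, 542.0, NA, NA, NA, NA),
    temperature = 305)
}

#' Write / read a harmonic bonded-parameter table
#'
#' Tab-separated text with columns (`term`, `kind`, `x0`, `sigma`, `k`, `n`,
#' `multimodal`, `temperature`); units follow [derive_bonded_table()].
#'
#' @param params Tibble as returned by [derive_bonded_table()].
#' @param path File path.
#' @export
write_bonded_table <- function(params, path) {
  utils::write.table(as.data.frame(params), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bonded_table
#' @export
read_bonded_table <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
}
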