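#' Physical constants and unit helpers
#'
#' `kB_kcal` is the Boltzmann constant in kcal/(mol K), the value used
#' throughout the harmonic Boltzmann-inversion machinery.  Masses are in
#' atomic mass units (amu), lengths in nm internally; bond samples cross to
#' Angstrom at the inversion boundary.
#'
#' @format `kB_kcal` is a length-one numeric.
#' @export
kB_kcal <- 0.0019872041

# standard atomic masses (amu)
.element_masses <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999)

# 1 amu / (1 g/cm^3) expressed in nm^3: 1.66054e-24 g / 1e-21 cm^3-per-nm^3
.amu_per_gcm3_nm3 <- 1.66054e-3

#' Mass of a chemical element
#'
#' @param element Character vector of element symbols (C, H, N, O).
#' @return Numeric vector of masses in amu.
#' @export
element_mass <- function(element) {
  out <- .element_masses[element]
  if (anyNA(out)) {
    abort(paste0("unknown element(s): ",
                 paste(unique(element[is.na(out)]), collapse = ", ")))
  }
  unname(out)
}

#' Molecular mass from a chemical formula
#'
#' Parses formulas such as `"C42H83NO3"` and returns the mass in amu using
#' standard atomic masses.  Used in tests as an independent check that
#' template bead masses close to the molecular mass.
#'
#' @param formula Character vector of Hill-style formulas.
#' @return Numeric vector, amu.
#' @export
formula_mass <- function(formula) {
  vapply(formula, function(f) {
    parts <- regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1]]
    sum(vapply(parts, function(p) {
      el <- gsub("[0-9]", "", p)
      nn <- gsub("[^0-9]", "", p)
      element_mass(el) * if (nzchar(nn)) as.numeric(nn) else 1
    }, numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
}
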