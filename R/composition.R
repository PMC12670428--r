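#' Define a lipid system composition
#'
#' @param ratios Named numeric vector of molar ratios over lipid species,
#'   e.g. `c(CER_NS = 1, CHOL = 0.5, FFA_C24 = 1)`.
#' @param n_lipids Total lipid count.
#' @param n_leaflets 2 (bilayer) or 6 (multilayer).
#' @param water_beads_per_lipid CG water beads per lipid (each bead is four
#'   water molecules); the study systems use 10, i.e. 40 waters per lipid.
#' @return A `composition_spec` object.
#' @examples
#' composition_spec(c(CER_NS = 1, CHOL = 0.5, FFA_C24 = 1), 1800, 6)
#' @export
composition_spec <- function(ratios, n_lipids, n_leaflets = 2,
                             water_beads_per_lipid = 10) {
  if (is.null(names(ratios)) || any(!nzchar(names(ratios)))) {
    abort("ratios must be a named numeric vector of species ratios")
  }
  if (any(ratios <= 0)) abort("ratios must be positive")
  if (!n_leaflets %in% c(2, 6)) abort("n_leaflets must be 2 or 6")
  if (n_lipids <= 0 || n_lipids != round(n_lipids)) {
    abort("n_lipids must be a positive integer")
  }
  structure(list(ratios = ratios, n_lipids = as.integer(n_lipids),
                 n_leaflets = as.integer(n_leaflets),
                 water_beads_per_lipid = water_beads_per_lipid),
            class = "composition_spec")
}

#' @export
print.composition_spec <- function(x, ...) {
  cat(sprintf("<composition_spec> %d lipids, %d leaflets, %g W beads/lipid\n",
              x$n_lipids, x$n_leaflets, x$water_beads_per_lipid))
  print(x$ratios)
  invisible(x)
}

#' Resolve molar ratios to integer molecule counts
#'
#' Largest-remainder rounding; errors if the rounding drifts any species by
#' more than one molecule from its exact share.
#'
#' @param spec A [composition_spec()].
#' @return A tibble with columns `species` and `count`; counts sum to
#'   `n_lipids`.
#' @examples
#' composition_counts(composition_spec(c(CER_NS = 1, CHOL = 0.5, FFA_C24 = 1), 1800))
#' @export
composition_counts <- function(spec) {
  exact <- spec$ratios / sum(spec$ratios) * spec$n_lipids
  base <- floor(exact)
  short <- spec$n_lipids - sum(base)
  frac_order <- order(exact - base, decreasing = TRUE)
  counts <- base
  if (short > 0) counts[frac_order[seq_len(short)]] <- counts[frac_order[seq_len(short)]] + 1
  if (any(abs(counts - exact) > 1)) {
    abort("composition does not resolve to integer counts within one lipid per species")
  }
  tibble(species = names(spec$ratios), count = as.integer(counts))
}

# effective hydrocarbon tail factors per species family
.tail_factor <- function(species) {
  f <- dplyr::case_when(
    startsWith(species, "CER") ~ 2,
    startsWith(species, "CHOL") ~ 1.9,
    startsWith(species, "FFA") ~ 1,
    TRUE ~ NA_real_
  )
  if (anyNA(f)) {
    abort(paste0("no effective tail factor for species: ",
                 paste(species[is.na(f)], collapse = ", ")))
  }
  f
}

#' Mean effective number of hydrocarbon tails per lipid
#'
#' Mole-fraction-weighted mean of the per-species effective tail counts
#' (1 for free fatty acids, 2 for ceramides, 1.9 for cholesterol), the
#' scaling used by the normalized lipid area.
#'
#' @param spec A [composition_spec()] (or a named ratio vector).
#' @return A single numeric.
#' @examples
#' mean_effective_tails(composition_spec(c(CER_NP = 1), 500))           # 2
#' mean_effective_tails(composition_spec(
#'   c(CER_NS = 1, CHOL = 0.5, FFA_C24 = 1), 1800))                     # 1.58
#' @export
mean_effective_tails <- function(spec) {
  ratios <- if (inherits(spec, "composition_spec")) spec$ratios else spec
  sum(ratios * .tail_factor(names(ratios))) / sum(ratios)
}
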