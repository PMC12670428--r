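#' Coarse-grained bead type registry
#'
#' One row per bead type used by the stratum corneum lipid models.  `mass` is
#' the nominal mass of the group the bead usually represents (actual template
#' bead masses are computed from their atom groups and may differ slightly,
#' e.g. a terminal TAIL bead carries an extra hydrogen).  `heavy_atoms`
#' counts non-hydrogen atoms.
#'
#' Headgroup beads: MHEAD2 (sphingoid C1-C3 backbone), AMIDE (amide N-H plus
#' the carbonyl carbon and oxygen), OH1-OH4 (individual hydroxyls), HEAD
#' (fatty acid carboxyl), CHEAD (sterol hydroxyl end).  Chain beads: TAIL
#' (three carbons), TER2 (terminal two carbons), CBODY/CTAIL (sterol ring and
#' tail groups, inherited mapping).  W is a four-water bead.
#'
#' @return A tibble with columns `name`, `mass` (amu), `heavy_atoms`, `role`
#'   (`"headgroup"`, `"tail"` or `"water"`).
#' @export
bead_types <- function() {
  tb <- tibble(
    name = c("MHEAD2", "AMIDE", "OH1", "OH2", "OH3", "OH4",
             "TAIL", "TER2", "HEAD", "CHEAD",
             "CBODY1", "CBODY2", "CBODY3", "CBODY4", "CTAIL1", "CTAIL2",
             "W"),
    mass = c(3 * 12.011 + 4 * 1.008,             # MHEAD2: C3H4 backbone
             14.007 + 1.008 + 12.011 + 15.999,   # AMIDE: N,H,C,O
             15.999 + 1.008, 15.999 + 1.008,     # OH1, OH2
             15.999 + 1.008, 15.999 + 1.008,     # OH3, OH4
             3 * 12.011 + 6 * 1.008,             # TAIL: (CH2)3
             2 * 12.011 + 5 * 1.008,             # TER2: CH2-CH3
             12.011 + 2 * 15.999 + 1.008,        # HEAD: COOH
             3 * 12.011 + 6 * 1.008 + 15.999,    # CHEAD
             4 * 12.011 + 6 * 1.008, 4 * 12.011 + 6 * 1.008,
             4 * 12.011 + 6 * 1.008, 4 * 12.011 + 7 * 1.008,
             4 * 12.011 + 8 * 1.008, 4 * 12.011 + 7 * 1.008,
             4 * (15.999 + 2 * 1.008)),          # W: four waters
    heavy_atoms = c(3L, 3L, 1L, 1L, 1L, 1L, 3L, 2L, 3L, 4L,
                    4L, 4L, 4L, 4L, 4L, 4L, 4L),
    role = c("headgroup", "headgroup", "headgroup", "headgroup", "headgroup",
             "headgroup", "tail", "tail", "headgroup", "headgroup",
             "tail", "tail", "tail", "tail", "tail", "tail",
             "water")
  )
  stopifnot(!anyDuplicated(tb$name), all(tb$mass > 0), all(tb$heavy_atoms >= 1))
  tb
}

#' Bead sequence for an alkyl chain
#'
#' Maps an n-carbon chain onto TAIL beads (three carbons each) finishing in
#' either a terminal TAIL (remainder 0 mod 3) or a TER2 bead (one methylene
#' plus the terminal methyl; remainder 2 mod 3).  Carbons already absorbed
#' into a headgroup bead (e.g. the amide carbonyl carbon, or the sphingoid
#' C1-C3 backbone in MHEAD2) are excluded via `carbons_in_headgroup`.
#'
#' @param n_carbons Total carbons in the chain.
#' @param carbons_in_headgroup Carbons of that chain already assigned to a
#'   headgroup bead.
#' @return A tibble with columns `bead` (TAIL/TER2) and `carbons`.
#' @examples
#' tail_bead_sequence(18)      # sphingoid base: six TAIL beads
#' tail_bead_sequence(24, 1)   # C24 acyl chain: seven TAIL + TER2
#' @export
tail_bead_sequence <- function(n_carbons, carbons_in_headgroup = 0) {
  rem <- n_carbons - carbons_in_headgroup
  if (rem < 2) {
    abort("chain must leave at least 2 carbons outside the headgroup")
  }
  r3 <- rem %% 3
  if (r3 == 1) {
    abort(sprintf(
      "unmappable chain: %d carbons outside the headgroup leave remainder 1 under the 3:1/2:1 rule",
      rem))
  }
  if (r3 == 0) {
    tibble(bead = rep("TAIL", rem / 3), carbons = rep(3L, rem / 3))
  } else {
    tibble(bead = c(rep("TAIL", (rem - 2) / 3), "TER2"),
           carbons = c(rep(3L, (rem - 2) / 3), 2L))
  }
}

#' Construct a CG molecule template
#'
#' Low-level constructor; most users want [build_template()].  A template
#' couples an ordered bead list, an exhaustive atom-to-bead partition, and
#' the bonded terms defined on the bead graph.
#'
#' @param name Species label.
#' @param beads Tibble with columns `index`, `bead` (type name), `role`,
#'   `chain` (e.g. "head", "sphingoid", "acyl", "sterol", "water").
#' @param atoms Tibble with columns `atom`, `element`, `bead_index`.
#' @param bonds Tibble with columns `i`, `j`, `term`.
#' @param angles Tibble with columns `i`, `j`, `k`, `term` (j is the vertex).
#' @param tail_factor Effective hydrocarbon tail count of the species
#'   (used by the normalized lipid area).
#' @return An object of class `cg_template`.
#' @export
new_cg_template <- function(name, beads, atoms, bonds, angles,
                            tail_factor = NA_real_) {
  atoms <- mutate(atoms, mass = element_mass(.data$element))
  beads <- beads %>%
    left_join(summarise(group_by(atoms, .data$bead_index),
                        mass = sum(.data$mass), .groups = "drop"),
              by = c(index = "bead_index"))
  tpl <- structure(
    list(name = name, beads = beads, atoms = atoms,
         bonds = bonds, angles = angles, tail_factor = tail_factor),
    class = "cg_template")
  validate_cg_template(tpl)
  tpl
}

#' Validate a CG template
#'
#' Checks the template invariants: every atom belongs to exactly one bead, bead
#' masses are positive and sum to the molecular mass of the atom set, bonded
#' indices are in range, and the bead graph is connected.
#'
#' @param tpl A `cg_template`.
#' @return `tpl`, invisibly; errors describe the violated invariant.
#' @export
validate_cg_template <- function(tpl) {
  b <- tpl$beads
  a <- tpl$atoms
  if (anyDuplicated(a$atom)) abort("duplicate atom names in template")
  if (!all(a$bead_index %in% b$index)) abort("atom assigned to unknown bead")
  if (!setequal(unique(a$bead_index), b$index)) abort("bead with empty atom group")
  if (any(is.na(b$mass)) || any(b$mass <= 0)) abort("bead with non-positive mass")
  idx <- c(tpl$bonds$i, tpl$bonds$j, tpl$angles$i, tpl$angles$j, tpl$angles$k)
  if (length(idx) && !all(idx %in% b$index)) abort("bonded index out of range")
  if (nrow(b) > 1) {
    # connectivity by bond-graph flood fill
    seen <- b$index[1]
    repeat {
      nb <- unique(c(tpl$bonds$j[tpl$bonds$i %in% seen],
                     tpl$bonds$i[tpl$bonds$j %in% seen]))
      grow <- setdiff(nb, seen)
      if (!length(grow)) break
      seen <- c(seen, grow)
    }
    if (!setequal(seen, b$index)) abort("bead graph is not connected")
  }
  invisible(tpl)
}

#' @export
print.cg_template <- function(x, ...) {
  cat(sprintf("<cg_template> %s: %d beads, %d atoms, %d bonds, %d angles, mass %.3f amu\n",
              x$name, nrow(x$beads), nrow(x$atoms),
              nrow(x$bonds), nrow(x$angles), template_mass(x)))
  invisible(x)
}

#' Total mass of a template
#' @param tpl A `cg_template`.
#' @return Mass in amu (sum of bead masses, which equals the atom-set mass).
#' @export
template_mass <- function(tpl) sum(tpl$beads$mass)

#' @export
tidy.cg_template <- function(x, ...) {
  mutate(x$beads, species = x$name, .before = 1)
}

# ---- internal template assembly helpers --------------------------------

# build the atom rows for a run of chain carbons given per-carbon H counts
.chain_atoms <- function(carbons, h_counts, prefix, bead_indices) {
  purrr::map_dfr(seq_along(carbons), function(ii) {
    cn <- carbons[ii]
    hs <- h_counts[ii]
    bind_rows(
      tibble(atom = sprintf("C%d%s", cn, prefix), element = "C",
             bead_index = bead_indices[ii]),
      if (hs > 0) tibble(atom = sprintf("H%d%s%s", cn, prefix, letters[seq_len(hs)]),
                         element = "H", bead_index = bead_indices[ii]))
  })
}

# assign chain carbons to TAIL/TER2 beads; returns list(beads=..., map=carbon->bead row)
.chain_beads <- function(n_carbons, first_carbon, seq_tbl, start_index, chain) {
  sizes <- seq_tbl$carbons
  bead_idx <- start_index + seq_along(sizes) - 1L
  carbons <- first_carbon + seq_len(sum(sizes)) - 1L
  list(
    beads = tibble(index = bead_idx, bead = seq_tbl$bead,
                   role = "tail", chain = chain),
    carbon_bead = rep(bead_idx, times = sizes),
    carbons = carbons
  )
}

.consecutive_terms <- function(idx, types) {
  bonds <- tibble(i = idx[-length(idx)], j = idx[-1],
                  term = paste(types[-length(types)], types[-1], sep = "-"))
  angles <- if (length(idx) >= 3) {
    tibble(i = idx[seq_len(length(idx) - 2)],
           j = idx[seq_len(length(idx) - 2) + 1],
           k = idx[seq_len(length(idx) - 2) + 2],
           term = paste(types[seq_len(length(idx) - 2)],
                        types[seq_len(length(idx) - 2) + 1],
                        types[seq_len(length(idx) - 2) + 2], sep = "-"))
  } else tibble(i = integer(), j = integer(), k = integer(), term = character())
  list(bonds = bonds, angles = angles)
}

# ceramide builder: subclasses differ in the 4,5 unsaturation (sphingosine)
# vs a 4-hydroxyl (phytosphingosine), and in the acyl alpha-hydroxyl.
.build_cer <- function(species) {
  phyto <- species %in% c("CER_NP", "CER_AP")   # OH3 on sphingoid C4
  alpha <- species %in% c("CER_AS", "CER_AP")   # OH4 on acyl C2
  # head beads
  head <- tibble(
    index = seq_len(4L + phyto + alpha),
    bead = c("MHEAD2", "OH1", "OH2", if (phyto) "OH3", "AMIDE", if (alpha) "OH4"),
    role = "headgroup",
    chain = "head")
  i_mh <- head$index[head$bead == "MHEAD2"]
  i_oh1 <- head$index[head$bead == "OH1"]
  i_oh2 <- head$index[head$bead == "OH2"]
  i_oh3 <- if (phyto) head$index[head$bead == "OH3"] else NA_integer_
  i_am <- head$index[head$bead == "AMIDE"]
  i_oh4 <- if (alpha) head$index[head$bead == "OH4"] else NA_integer_

  # sphingoid base: 18 carbons, C1-C3 inside MHEAD2 -> 5 TAIL beads
  sph <- .chain_beads(18, 4L, tail_bead_sequence(18, 3), max(head$index) + 1L, "sphingoid")
  # acyl chain: 24 carbons, carbonyl C1 inside AMIDE -> 7 TAIL + TER2
  acy <- .chain_beads(24, 2L, tail_bead_sequence(24, 1),
                      max(sph$beads$index) + 1L, "acyl")
  beads <- bind_rows(head, sph$beads, acy$beads)

  # ---- atoms -----------------------------------------------------------
  # sphingoid hydrogens: C4 1H always (bears OH3 or the double bond);
  # C5 1H if unsaturated else 2H; C6-C17 2H; C18 3H
  sph_h <- c(1L, if (phyto) 2L else 1L, rep(2L, 12), 3L)
  # acyl hydrogens: C2 1H if alpha-hydroxylated else 2H; C3-C23 2H; C24 3H
  acy_h <- c(if (alpha) 1L else 2L, rep(2L, 21), 3L)
  atoms <- bind_rows(
    # MHEAD2: C1(2H), C2(1H), C3(1H) of the sphingoid backbone
    .chain_atoms(1:3, c(2L, 1L, 1L), "S", rep(i_mh, 3)),
    tibble(atom = c("O1", "HO1"), element = c("O", "H"), bead_index = i_oh1),
    tibble(atom = c("O2", "HO2"), element = c("O", "H"), bead_index = i_oh2),
    if (phyto) tibble(atom = c("O3", "HO3"), element = c("O", "H"), bead_index = i_oh3),
    tibble(atom = c("N1", "HN1", "C1A", "OAM"),
           element = c("N", "H", "C", "O"), bead_index = i_am),
    if (alpha) tibble(atom = c("O4", "HO4"), element = c("O", "H"), bead_index = i_oh4),
    .chain_atoms(sph$carbons, sph_h, "S", sph$carbon_bead),
    .chain_atoms(acy$carbons, acy_h, "A", acy$carbon_bead)
  )

  # ---- bonded terms ----------------------------------------------------
  s_idx <- sph$beads$index; s_typ <- sph$beads$bead
  a_idx <- acy$beads$index; a_typ <- acy$beads$bead
  sph_chain <- .consecutive_terms(c(i_mh, s_idx), c("MHEAD2", s_typ))
  acy_chain <- .consecutive_terms(c(i_am, a_idx), c("AMIDE", a_typ))
  bonds <- bind_rows(
    tibble(i = i_mh, j = i_oh1, term = "MHEAD2-OH1"),
    tibble(i = i_mh, j = i_oh2, term = "MHEAD2-OH2"),
    tibble(i = i_mh, j = i_am, term = "MHEAD2-AMIDE"),
    sph_chain$bonds,
    acy_chain$bonds,
    if (phyto) tibble(i = s_idx[1], j = i_oh3, term = "TAIL-OH3"),
    if (alpha) tibble(i = a_idx[1], j = i_oh4, term = "TAIL-OH4")
  )
  angles <- bind_rows(
    sph_chain$angles,
    acy_chain$angles,
    tibble(i = i_oh1, j = i_mh, k = i_am, term = "OH1-MHEAD2-AMIDE"),
    tibble(i = i_oh2, j = i_mh, k = i_am, term = "OH2-MHEAD2-AMIDE"),
    tibble(i = i_mh, j = i_am, k = a_idx[1], term = "MHEAD2-AMIDE-TAIL"),
    if (phyto) bind_rows(
      tibble(i = i_mh, j = s_idx[1], k = i_oh3, term = "MHEAD2-TAIL-OH3"),
      tibble(i = s_idx[2], j = s_idx[1], k = i_oh3, term = "TAIL-TAIL-OH3")),
    if (alpha) bind_rows(
      tibble(i = i_am, j = a_idx[1], k = i_oh4, term = "AMIDE-TAIL-OH4"),
      tibble(i = a_idx[2], j = a_idx[1], k = i_oh4, term = "TAIL-TAIL-OH4"))
  )
  new_cg_template(species, beads, atoms, bonds, angles, tail_factor = 2)
}

.build_ffa <- function() {
  head <- tibble(index = 1L, bead = "HEAD", role = "headgroup", chain = "head")
  chain <- .chain_beads(24, 2L, tail_bead_sequence(24, 1), 2L, "acyl")
  beads <- bind_rows(head, chain$beads)
  atoms <- bind_rows(
    tibble(atom = c("C1", "O1", "O2", "HO1"),
           element = c("C", "O", "O", "H"), bead_index = 1L),
    .chain_atoms(chain$carbons, c(rep(2L, 22), 3L), "F", chain$carbon_bead)
  )
  terms <- .consecutive_terms(c(1L, chain$beads$index), c("HEAD", chain$beads$bead))
  new_cg_template("FFA_C24", beads, atoms, terms$bonds, terms$angles,
                  tail_factor = 1)
}

# Sterol mapping inherited from prior CG work; the four-carbon body/tail
# partition (and its hydrogen bookkeeping) is encoded as a documented,
# mass-closing stand-in for the pictorial assignment.
.build_chol <- function() {
  beads <- tibble(
    index = 1:7,
    bead = c("CHEAD", "CBODY1", "CBODY2", "CBODY3", "CBODY4", "CTAIL1", "CTAIL2"),
    role = c("headgroup", rep("tail", 6)),
    chain = "sterol")
  groups <- list(1:3, 4:7, 8:11, 12:15, 16:19, 20:23, 24:27)
  h_per_bead <- c(5L, 6L, 6L, 6L, 7L, 8L, 7L)  # + hydroxyl H on CHEAD = 46 H
  atoms <- bind_rows(
    tibble(atom = c("O1", "HO1"), element = c("O", "H"), bead_index = 1L),
    purrr::map_dfr(1:7, function(b) tibble(
      atom = sprintf("C%d", groups[[b]]), element = "C", bead_index = b)),
    purrr::map_dfr(1:7, function(b) tibble(
      atom = sprintf("HC%d%s", b, letters[seq_len(h_per_bead[b])]),
      element = "H", bead_index = b))
  )
  terms <- .consecutive_terms(beads$index, beads$bead)
  new_cg_template("CHOL", beads, atoms, terms$bonds, terms$angles,
                  tail_factor = 1.9)
}

.build_water <- function() {
  beads <- tibble(index = 1L, bead = "W", role = "water", chain = "water")
  atoms <- purrr::map_dfr(1:4, function(w) tibble(
    atom = c(sprintf("OW%d", w), sprintf("HW%d%s", w, c("a", "b"))),
    element = c("O", "H", "H"), bead_index = 1L))
  new_cg_template("WATER", beads, atoms,
                  tibble(i = integer(), j = integer(), term = character()),
                  tibble(i = integer(), j = integer(), k = integer(),
                         term = character()))
}

#' Build the CG template for a supported species
#'
#' Supported species: the four C24 ceramide subclasses (`CER_NS`, `CER_NP`,
#' `CER_AS`, `CER_AP`; NP adds a hydroxyl on the sphingoid C4 mapped to an
#' OH3 bead, AS adds one on the acyl C2 mapped to OH4, AP has both),
#' `FFA_C24` (lignoceric acid), `CHOL` (cholesterol, inherited mapping) and
#' `WATER` (one W bead for four water molecules).  The amide carbonyl carbon
#' is assigned to the AMIDE bead, so the 24-carbon acyl chain maps to seven
#' TAIL beads plus a terminal TER2.
#'
#' @param species One of the supported species labels.
#' @return A `cg_template`.
#' @examples
#' build_template("CER_NS")
#' @export
build_template <- function(species) {
  supported <- c("CER_NS", "CER_NP", "CER_AS", "CER_AP",
                 "FFA_C24", "CHOL", "WATER")
  if (!species %in% supported) {
    abort(sprintf("unknown species '%s'; supported: %s",
                  species, paste(supported, collapse = ", ")))
  }
  switch(species,
         FFA_C24 = .build_ffa(),
         CHOL = .build_chol(),
         WATER = .build_water(),
         .build_cer(species))
}

#' Template registry for all supported species
#'
#' @param species Character vector of species to include (default all).
#' @return A named list of `cg_template` objects.
#' @export
default_registry <- function(species = c("CER_NS", "CER_NP", "CER_AS",
                                         "CER_AP", "FFA_C24", "CHOL",
                                         "WATER")) {
  setNames(lapply(species, build_template), species)
}
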