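#' Recipe for a synthetic gel-phase lamellar configuration
#'
#' Describes the ground truth a generated configuration should embody:
#' in-plane packing (APL), collective chain tilt, headgroup-plane spacing,
#' midplane interdigitation, hairpin/extended split of the ceramides, and
#' thermal positional noise.  Defaults emulate the gel-phase lamellae the
#' structural metrics target: APL 0.40 nm^2, untilted chains, 5.3 nm
#' leaflet-pair spacing, 0.1 nm positional noise (a typical gel-phase RMS
#' displacement), ten 4-water beads per lipid.
#'
#' @param composition A [composition_spec()].
#' @param apl Area per lipid, nm^2.
#' @param tilt Collective chain tilt from the z axis, degrees, in \[0, 45\].
#' @param thickness Headgroup-plane spacing of a leaflet pair, nm.
#' @param overlap Depth of midplane interdigitation (each leaflet's chains
#'   reach `overlap/2` past the pair midplane), nm.
#' @param extended_pct Percentage of ceramides placed in the extended
#'   conformation, \[0, 100\].
#' @param noise_sigma Isotropic Gaussian positional noise, nm.
#' @param chain_jitter Half-width of the uniform per-molecule protrusion of
#'   the chains along their own axis, nm; smooths the bead comb in the
#'   density profile the way conformational disorder does in real chains.
#' @param pair_gap Gap between leaflet pairs in a multilayer, nm.
#' @return A `bilayer_recipe`.
#' @export
bilayer_recipe <- function(composition, apl = 0.40, tilt = 0,
                           thickness = 5.3, overlap = 0, extended_pct = 0,
                           noise_sigma = 0.1, chain_jitter = 0.2,
                           pair_gap = 0.4) {
  if (apl <= 0) abort("apl must be positive")
  if (tilt < 0 || tilt > 45) abort("tilt must be in [0, 45] degrees")
  if (extended_pct < 0 || extended_pct > 100) abort("extended_pct must be in [0, 100]")
  if (thickness <= 0 || overlap < 0 || noise_sigma < 0 || pair_gap < 0) {
    abort("thickness must be positive; overlap, noise_sigma, pair_gap non-negative")
  }
  structure(list(composition = composition, apl = apl, tilt = tilt,
                 thickness = thickness, overlap = overlap,
                 extended_pct = extended_pct, noise_sigma = noise_sigma,
                 chain_jitter = chain_jitter, pair_gap = pair_gap),
            class = "bilayer_recipe")
}

# z-stagger (into the leaflet) of each head bead type; small and balanced so
# the mass-weighted headgroup center stays essentially on the plane, keeping
# the headgroup density peak at the plane position.
.head_depths <- c(MHEAD2 = 0, OH1 = -0.05, OH2 = 0.05, OH3 = -0.03,
                  AMIDE = 0.03, OH4 = 0.07, HEAD = 0, CHEAD = 0)

# ideal (noise-free) local coordinates of one lipid of a species, for a
# leaflet whose tails point in +z; x/z are offsets from (site, plane).
# The C24 acyl chain (and the FFA chain) reaches `reach` = t/2 + overlap/2,
# carrying the midplane interdigitation; the shorter C18 sphingoid base
# stops 0.45 nm short of the midplane and the sterol rod 0.7 nm short, so
# the interdigitation band carries single-chain (not doubled) density, as
# tapering chain ends do in real lamellae.  Extended ceramides have the
# sphingoid chain flipped through the headgroup plane, collinear with the
# acyl rod so the molecular long axis (and hence tilt) is unchanged.
.species_local <- function(tpl, tilt_deg, reach, extended = FALSE) {
  b <- tpl$beads
  th <- tilt_deg * pi / 180
  tanth <- tan(th)
  # chain-to-chain offsets lie along the in-plane normal to the chain axis,
  # so the lateral spread is a principal direction and the molecular long
  # axis stays exactly on the chain direction at any tilt
  place_chain <- function(idx, lateral, creach, flip = FALSE, cstart = 0.3) {
    nb <- length(idx)
    if (creach <= cstart + 0.1 * (nb - 1)) {
      abort("infeasible recipe: leaflet depth smaller than the chain projection")
    }
    depths <- if (nb == 1) creach else seq(cstart, creach, length.out = nb)
    sgn <- if (flip) -1 else 1
    tibble(bead_index = idx,
           x = lateral * cos(th) + sgn * depths * tanth,
           y = 0,
           z = -lateral * sin(th) + sgn * depths)
  }
  heads <- b[b$chain == "head" | b$bead %in% c("HEAD", "CHEAD"), ]
  out <- list()
  if (nrow(heads)) {
    hd <- unname(.head_depths[heads$bead])
    out$head <- tibble(bead_index = heads$index, x = hd * tanth, y = 0, z = hd)
  }
  sph <- b$index[b$chain == "sphingoid" & b$role == "tail"]
  acy <- b$index[b$chain == "acyl" & b$role == "tail"]
  ste <- b$index[b$chain == "sterol" & b$role == "tail"]
  if (length(sph)) {
    # start the sphingoid base deeper so both chains share the same
    # mass-weighted mean depth, which zeroes the hairpin inertia cross-term
    # and keeps the molecular long axis exactly on the chain direction (the
    # base's first carbons live in the headgroup bead anyway)
    m_a <- b$mass[match(acy, b$index)]
    d_a <- seq(0.3, reach, length.out = length(acy))
    target <- sum(m_a * d_a) / sum(m_a)
    m_s <- b$mass[match(sph, b$index)]
    f_s <- (seq_along(sph) - 1) / (length(sph) - 1)
    big_f <- sum(m_s * f_s) / sum(m_s)
    sph_end <- max(0.9, reach - 0.45)
    sph_start <- max(0.15, (target - sph_end * big_f) / (1 - big_f))
    out$sph <- place_chain(sph, if (extended) 0.22 else -0.22,
                           sph_end, flip = extended, cstart = sph_start)
  }
  if (length(acy)) out$acy <- place_chain(acy, 0.22, reach)
  if (length(ste)) out$ste <- place_chain(ste, 0, max(0.9, reach - 0.7))
  pos <- bind_rows(out)
  pos %>%
    left_join(select(b, bead_index = "index", bead = "bead"), by = "bead_index") %>%
    mutate(mass = b$mass[match(.data$bead_index, b$index)])
}

# expected-profile interdigitation of the central pair: the lambda overlap
# functional evaluated on the infinite-sample, Gaussian-noise-convolved mass
# profiles of the ideal construction (0.005 nm grid).  This is the exact
# ground truth the binned single-frame estimate converges to.
.expected_lambda <- function(ideal, top_mols, bot_mols, sigma, dz = 0.005) {
  sig <- max(sigma, 1e-3)
  zt <- ideal$z[ideal$molecule %in% top_mols]
  mt <- ideal$mass[ideal$molecule %in% top_mols]
  zb <- ideal$z[ideal$molecule %in% bot_mols]
  mb <- ideal$mass[ideal$molecule %in% bot_mols]
  g <- seq(min(c(zt, zb)) - 6 * sig, max(c(zt, zb)) + 6 * sig, by = dz)
  kern <- dnorm(seq(-5 * sig, 5 * sig, by = dz), sd = sig)
  conv <- function(zs, ms) {
    binned <- numeric(length(g))
    idx <- pmin(pmax(round((zs - g[1]) / dz) + 1, 1), length(g))
    for (i in seq_along(idx)) binned[idx[i]] <- binned[idx[i]] + ms[i]
    as.numeric(stats::filter(c(numeric(length(kern)), binned,
                               numeric(length(kern))),
                             kern, sides = 2))[length(kern) + seq_along(g)]
  }
  a <- conv(zt, mt)
  b <- conv(zb, mb)
  a[is.na(a)] <- 0
  b[is.na(b)] <- 0
  f <- ifelse(a + b > 0, 4 * a * b / (a + b)^2, 0)
  trapz(g, f)
}

# split counts across leaflets by largest remainder, preserving totals
.leaflet_counts <- function(counts, n_leaflets) {
  share <- counts$count / n_leaflets
  out <- matrix(0L, nrow(counts), n_leaflets)
  left <- counts$count
  for (l in seq_len(n_leaflets - 1)) {
    base <- floor(share)
    short <- round(sum(share)) - sum(base)
    ord <- order(share - base, decreasing = TRUE)
    take <- base
    if (short > 0) take[ord[seq_len(short)]] <- take[ord[seq_len(short)]] + 1
    out[, l] <- as.integer(take)
    left <- left - take
  }
  out[, n_leaflets] <- as.integer(left)
  out
}

# core generator shared by gen_bilayer / gen_multilayer
.gen_lamella <- function(recipe, seed) {
  spec <- recipe$composition
  reg <- default_registry()
  k <- spec$n_leaflets
  n_per <- spec$n_lipids / k
  if (n_per != round(n_per)) abort("n_lipids must divide evenly over leaflets")
  counts <- composition_counts(spec)
  per_leaflet <- .leaflet_counts(counts, k)

  # hexagonal lattice sized so APL is exact
  area <- recipe$apl * n_per
  nx <- ceiling(sqrt(n_per))
  ny <- ceiling(n_per / nx)
  rhex <- sqrt(3) / 2
  lx <- sqrt(area * nx / (ny * rhex))
  ly <- area / lx
  ax <- lx / nx
  ay <- ly / ny
  site <- function(i) {
    row <- (i - 1) %/% nx
    col <- (i - 1) %% nx
    c((col + 0.5 * (row %% 2)) * ax + ax / 4, (row + 0.5) * ay)
  }

  t <- recipe$thickness
  gap <- recipe$pair_gap
  n_pairs <- k / 2
  # leaflet planes: pair p spans [p*(t+gap), p*(t+gap)+t]
  planes <- unlist(lapply(seq_len(n_pairs) - 1,
                          function(p) p * (t + gap) + c(0, t)))
  dirs <- rep(c(1, -1), n_pairs)
  reach <- t / 2 + recipe$overlap / 2

  # extended ceramides: exact counts per leaflet (largest remainder on total)
  cer_rows <- which(startsWith(counts$species, "CER"))
  n_cer_leaf <- colSums(per_leaflet[cer_rows, , drop = FALSE])
  n_ext_total <- round(recipe$extended_pct / 100 * sum(n_cer_leaf))
  ext_leaf <- integer(k)
  if (n_ext_total > 0) {
    sharex <- n_ext_total * n_cer_leaf / sum(n_cer_leaf)
    basex <- pmin(floor(sharex), n_cer_leaf)
    shortx <- n_ext_total - sum(basex)
    ordx <- order(sharex - basex, decreasing = TRUE)
    ext_leaf <- basex
    if (shortx > 0) ext_leaf[ordx[seq_len(shortx)]] <- ext_leaf[ordx[seq_len(shortx)]] + 1
  }

  # local coordinates per species/variant, computed once
  locals <- list()
  for (sp in counts$species) {
    locals[[sp]] <- .species_local(reg[[sp]], recipe$tilt, reach)
    if (startsWith(sp, "CER") && n_ext_total > 0) {
      locals[[paste0(sp, ".ext")]] <-
        .species_local(reg[[sp]], recipe$tilt, reach, extended = TRUE)
    }
  }

  ideal <- with_seed_if(seed, {
    mol_id <- 0L
    frames <- vector("list", k)
    for (l in seq_len(k)) {
      species_vec <- sample(rep(counts$species, per_leaflet[, l]))
      cer_pos <- which(startsWith(species_vec, "CER"))
      ext_set <- if (ext_leaf[l] > 0) cer_pos[seq_len(ext_leaf[l])] else integer()
      variant <- species_vec
      if (length(ext_set)) variant[ext_set] <- paste0(variant[ext_set], ".ext")
      n_mol <- length(species_vec)
      sxy <- t(vapply(seq_len(n_mol), site, numeric(2)))
      loc <- bind_rows(lapply(seq_len(n_mol), function(i) locals[[variant[i]]]),
                       .id = "i_mol")
      i_mol <- as.integer(loc$i_mol)
      frames[[l]] <- tibble(
        molecule = mol_id + i_mol,
        species = species_vec[i_mol],
        bead = loc$bead, bead_index = loc$bead_index, mass = loc$mass,
        x = sxy[i_mol, 1] + dirs[l] * loc$x,
        y = sxy[i_mol, 2] + loc$y,
        z = planes[l] + dirs[l] * loc$z,
        leaflet_true = l)
      mol_id <- mol_id + n_mol
    }
    out <- bind_rows(frames)
    # per-molecule chain protrusion along the chain axis: smooths the bead
    # comb in density profiles without moving headgroups or tilting axes
    if (recipe$chain_jitter > 0) {
      delta <- runif(mol_id, -recipe$chain_jitter, recipe$chain_jitter)
      tanth <- tan(recipe$tilt * pi / 180)
      is_chain <- out$bead %in% c("TAIL", "TER2", "CBODY1", "CBODY2",
                                  "CBODY3", "CBODY4", "CTAIL1", "CTAIL2")
      dmol <- delta[out$molecule] * is_chain
      dl <- dirs[out$leaflet_true]
      out$z <- out$z + dl * dmol
      out$x <- out$x + dl * dmol * tanth
    }
    out
  })

  # water slabs outside the stack
  w_per_bead_vol <- reg$WATER$beads$mass[1] * .amu_per_gcm3_nm3  # at 1 g/cm^3
  n_w <- spec$water_beads_per_lipid * spec$n_lipids
  slab <- (n_w / 2 * w_per_bead_vol) / area + 0.3
  z_lo <- min(planes) - 0.3
  z_hi <- max(planes) + 0.3
  lz <- (z_hi + slab) - (z_lo - slab)
  shift <- -(z_lo - slab)

  water <- with_seed_if(if (is.null(seed)) NULL else seed + 1L, tibble(
    bead_index = 1L, bead = "W",
    x = runif(n_w, 0, lx), y = runif(n_w, 0, ly),
    z = c(runif(floor(n_w / 2), z_lo - slab + 0.05, z_lo - 0.05),
          runif(n_w - floor(n_w / 2), z_hi + 0.05, z_hi + slab - 0.05)),
    mass = reg$WATER$beads$mass[1],
    molecule = max(ideal$molecule) + seq_len(n_w),
    species = "WATER", leaflet_true = NA_integer_))

  # ground-truth interdigitation of the central pair
  pair <- c(n_pairs, n_pairs + 1)  # leaflet indices k/2, k/2+1
  pair <- c(k / 2, k / 2 + 1)
  lam_true <- .expected_lambda(
    ideal,
    top_mols = unique(ideal$molecule[ideal$leaflet_true == pair[2]]),
    bot_mols = unique(ideal$molecule[ideal$leaflet_true == pair[1]]),
    sigma = recipe$noise_sigma)

  all_beads <- bind_rows(ideal, water)
  noisy <- with_seed_if(if (is.null(seed)) NULL else seed + 2L, {
    n <- nrow(all_beads)
    mutate(all_beads,
           x = (.data$x + rnorm(n, 0, recipe$noise_sigma)) %% lx,
           y = (.data$y + rnorm(n, 0, recipe$noise_sigma)) %% ly,
           z = (.data$z + shift + rnorm(n, 0, recipe$noise_sigma)) %% lz)
  })

  frame <- cg_frame(select(noisy, "molecule", "species", "bead",
                           "bead_index", "mass", "x", "y", "z"),
                    c(lx, ly, lz))
  truth <- list(
    apl = recipe$apl, tilt = recipe$tilt, thickness = t,
    n_leaflets = k, overlap = recipe$overlap,
    interdigitation = lam_true,
    extended_pct = if (sum(n_cer_leaf) > 0) 100 * n_ext_total / sum(n_cer_leaf) else NA_real_,
    s2 = 1, noise_sigma = recipe$noise_sigma,
    water_beads_per_lipid = spec$water_beads_per_lipid,
    counts = counts, box = c(lx, ly, lz), seed = seed)
  list(frame = frame, truth = truth)
}

#' Generate a synthetic gel-phase bilayer
#'
#' Places lipids on a hexagonal lattice with the box sized so the requested
#' APL is exact, straight chains at the requested collective tilt, headgroup
#' planes at the requested spacing and an exact count of extended ceramides;
#' Gaussian positional noise is added last.  The returned ground truth
#' carries the values every structural metric should recover, including the
#' interdigitation overlap functional evaluated analytically on the expected
#' density profiles of the construction.
#'
#' @param recipe A [bilayer_recipe()] whose composition has `n_leaflets = 2`.
#' @param seed Integer seed; the generator is deterministic per seed.
#' @return A list with elements `frame` (a [cg_frame()]) and `truth` (a
#'   named list of ground-truth values).
#' @export
gen_bilayer <- function(recipe, seed = NULL) {
  if (recipe$composition$n_leaflets != 2) {
    abort("gen_bilayer needs a composition with n_leaflets = 2")
  }
  .gen_lamella(recipe, seed)
}

#' Generate a synthetic six-leaflet multilayer
#'
#' Stacks leaflet pairs at the recipe spacing separated by `pair_gap`, with
#' water only at the two outer faces (the inner leaflets see no bulk water,
#' as in self-assembled lamellae).  The central pair carries the requested
#' midplane overlap.
#'
#' @param recipe A [bilayer_recipe()] whose composition has an even
#'   `n_leaflets` (6 for the standard multilayer).
#' @inheritParams gen_bilayer
#' @return As [gen_bilayer()].
#' @export
gen_multilayer <- function(recipe, seed = NULL) {
  k <- recipe$composition$n_leaflets
  if (k %% 2 != 0 || k < 4) abort("gen_multilayer needs an even n_leaflets >= 4")
  .gen_lamella(recipe, seed)
}

#' Generate Gaussian bonded-term samples with known parameters
#'
#' Draws `n` samples per term from the Gaussian each harmonic term implies
#' at its temperature, for round-trip testing of the Boltzmann-inversion
#' derivation.
#'
#' @param params Tibble with columns `term`, `kind`, `x0`, `k` and
#'   optionally `temperature` (default 305 K).
#' @param n Samples per term.
#' @param seed Integer seed.
#' @return List with `samples` (tibble `term`, `kind`, `value`) and `truth`
#'   (the input table).
#' @export
gen_bonded_dataset <- function(params, n, seed = NULL) {
  if (!"temperature" %in% names(params)) params$temperature <- 305
  samples <- purrr::map_dfr(seq_len(nrow(params)), function(i) {
    row <- params[i, ]
    tibble(term = row$term, kind = row$kind,
           value = sample_term(row$x0, row$k, row$temperature, n,
                               kind = row$kind,
                               seed = if (is.null(seed)) NULL else seed + i))
  })
  list(samples = samples, truth = params)
}
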