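#' Map an atomistic frame to CG beads
#'
#' Each bead is placed at the mass-weighted center of its atom group, so the
#' mapping conserves total mass and the system center of mass.  Molecules
#' broken across the periodic boundary must either be whole or `unwrap`
#' requested, in which case atoms are made whole per molecule by the
#' minimum-image convention relative to the molecule's first atom.
#'
#' @param atoms Atomistic frame: a tibble with columns `molecule`, `resname`,
#'   `atom`, `x`, `y`, `z` (nm) and either `element` or `mass`, plus a `box`
#'   attribute (or pass `box`).
#' @param registry Named list of templates, see [default_registry()].
#' @param assignment Named character vector mapping residue names to species,
#'   e.g. `c(CER = "CER_NS", FFA = "FFA_C24")`.
#' @param box Box lengths (nm) if not attached to `atoms`.
#' @param unwrap Make molecules whole across the boundary before mapping.
#' @return A [cg_frame()].
#' @export
map_frame <- function(atoms, registry = default_registry(), assignment,
                      box = attr(atoms, "box"), unwrap = FALSE) {
  if (is.null(box)) abort("no box: supply `box` or attach a box attribute")
  atoms <- as_tibble(atoms)
  if (!"mass" %in% names(atoms)) {
    atoms$mass <- element_mass(atoms$element)
  }
  unknown <- setdiff(unique(atoms$resname), names(assignment))
  if (length(unknown)) {
    abort(paste0("residues without species assignment: ",
                 paste(unknown, collapse = ", ")))
  }
  atoms$species <- unname(assignment[atoms$resname])

  # resolve atom -> bead through each species template
  lookup <- purrr::map_dfr(unique(atoms$species), function(sp) {
    tpl <- registry[[sp]]
    if (is.null(tpl)) abort(paste0("species not in registry: ", sp))
    mutate(select(tpl$atoms, "atom", "bead_index"), species = sp)
  })
  joined <- left_join(atoms, lookup, by = c("species", "atom"))

  # every template atom must be present in every molecule
  per_mol <- joined %>%
    group_by(.data$molecule, .data$species) %>%
    summarise(n_atoms = n(), n_unmatched = sum(is.na(.data$bead_index)),
              .groups = "drop")
  expect_n <- vapply(registry, function(t) nrow(t$atoms), numeric(1))
  bad <- per_mol %>%
    filter(.data$n_unmatched > 0 | .data$n_atoms != expect_n[.data$species])
  if (nrow(bad)) {
    mol1 <- bad$molecule[1]
    missing1 <- setdiff(registry[[bad$species[1]]]$atoms$atom,
                        joined$atom[joined$molecule == mol1])
    abort(sprintf(
      "molecule %s (%s): atom group mismatch%s",
      mol1, bad$species[1],
      if (length(missing1)) paste0("; missing atoms: ",
                                   paste(head(missing1, 5), collapse = ", "))
      else "; unassigned atoms present"))
  }

  if (unwrap) {
    joined <- joined %>%
      group_by(.data$molecule) %>%
      mutate(x = .data$x[1] + minimum_image(.data$x - .data$x[1], box[1]),
             y = .data$y[1] + minimum_image(.data$y - .data$y[1], box[2]),
             z = .data$z[1] + minimum_image(.data$z - .data$z[1], box[3])) %>%
      ungroup()
  } else {
    ext <- joined %>%
      group_by(.data$molecule) %>%
      summarise(ex = diff(range(.data$x)), ey = diff(range(.data$y)),
                ez = diff(range(.data$z)), .groups = "drop")
    broken <- ext$ex > box[1] / 2 | ext$ey > box[2] / 2 | ext$ez > box[3] / 2
    if (any(broken)) {
      abort(sprintf(
        "molecule %s appears broken across the periodic boundary; use unwrap = TRUE",
        ext$molecule[which(broken)[1]]))
    }
  }

  beads <- joined %>%
    group_by(.data$molecule, .data$species, .data$bead_index) %>%
    summarise(x = weighted.mean(.data$x, .data$mass),
              y = weighted.mean(.data$y, .data$mass),
              z = weighted.mean(.data$z, .data$mass),
              mass = sum(.data$mass),
              .groups = "drop") %>%
    arrange(.data$molecule, .data$bead_index)
  bead_names <- purrr::map_dfr(registry[unique(beads$species)], function(tpl) {
    mutate(select(tpl$beads, bead_index = "index", bead = "bead"),
           species = tpl$name)
  })
  beads <- left_join(beads, bead_names, by = c("species", "bead_index"))
  cg_frame(select(beads, "molecule", "species", "bead",
                  "bead_index", "mass", "x", "y", "z"),
           box)
}

#' Map water molecules to four-water beads
#'
#' Dynamic water mapping realized as greedy nearest-neighbour clustering:
#' repeatedly seed a cluster with the lowest-index unassigned water and
#' absorb its `ratio - 1` nearest unassigned neighbours; each bead sits at
#' the mass-weighted center of its cluster.  The clustering objective
#' (minimize within-cluster spread greedily) is deliberately simple and
#' recomputed per frame.
#'
#' @param waters Tibble of water molecule centers: columns `molecule`, `x`,
#'   `y`, `z` (nm) and optionally `mass` (default 18.015 amu each).
#' @param ratio Waters per bead (default 4).
#' @return Tibble of W beads (`bead`, `x`, `y`, `z`, `mass`, `n_waters`,
#'   `partial`); a trailing cluster smaller than `ratio` is flagged
#'   `partial = TRUE`.
#' @export
map_water <- function(waters, ratio = 4) {
  waters <- as_tibble(waters)
  if (nrow(waters) == 0) {
    return(tibble(bead = character(), x = numeric(), y = numeric(),
                  z = numeric(), mass = numeric(), n_waters = integer(),
                  partial = logical()))
  }
  if (!"mass" %in% names(waters)) waters$mass <- 2 * 1.008 + 15.999
  pos <- as.matrix(waters[, c("x", "y", "z")])
  n <- nrow(pos)
  unassigned <- rep(TRUE, n)
  out <- list()
  while (any(unassigned)) {
    seed <- which(unassigned)[1]
    cand <- which(unassigned)
    d2 <- colSums((t(pos[cand, , drop = FALSE]) - pos[seed, ])^2)
    take <- cand[order(d2)][seq_len(min(ratio, length(cand)))]
    unassigned[take] <- FALSE
    m <- waters$mass[take]
    out[[length(out) + 1]] <- tibble(
      bead = "W",
      x = weighted.mean(pos[take, 1], m),
      y = weighted.mean(pos[take, 2], m),
      z = weighted.mean(pos[take, 3], m),
      mass = sum(m), n_waters = length(take),
      partial = length(take) < ratio)
  }
  bind_rows(out)
}

#' Harvest bonded-distribution samples from CG frames
#'
#' For every molecule of the template's species in every frame, measures each
#' bond length (minimum-image convention; reported in Angstrom) and each
#' angle (degrees, in \[0, 180\]).
#'
#' @param frames A `cg_frame` or list of them.
#' @param template The `cg_template` whose bonded terms to sample.
#' @return Tibble with columns `frame`, `molecule`, `term`, `kind`
#'   (`"bond"`/`"angle"`), `value`.
#' @export
bonded_samples <- function(frames, template) {
  frames <- .as_frame_list(frames)
  if (!length(frames)) abort("need at least one frame")
  out <- purrr::imap_dfr(frames, function(fr, fi) {
    box <- frame_box(fr)
    sel <- filter(as_tibble(fr), .data$species == template$name)
    if (nrow(sel) == 0) abort(paste0("no molecules of species ", template$name))
    pos <- select(sel, "molecule", "bead_index", "x", "y", "z")
    bnd <- if (nrow(template$bonds)) {
      template$bonds %>%
        inner_join(rename(pos, xi = "x", yi = "y", zi = "z"),
                   by = c(i = "bead_index"), relationship = "many-to-many") %>%
        inner_join(rename(pos, xj = "x", yj = "y", zj = "z"),
                   by = c(j = "bead_index", "molecule")) %>%
        mutate(dx = minimum_image(.data$xj - .data$xi, box[1]),
               dy = minimum_image(.data$yj - .data$yi, box[2]),
               dz = minimum_image(.data$zj - .data$zi, box[3]),
               value = 10 * sqrt(.data$dx^2 + .data$dy^2 + .data$dz^2),
               kind = "bond") %>%
        select("molecule", "term", "kind", "value")
    }
    ang <- if (nrow(template$angles)) {
      template$angles %>%
        inner_join(rename(pos, xi = "x", yi = "y", zi = "z"),
                   by = c(i = "bead_index"), relationship = "many-to-many") %>%
        inner_join(rename(pos, xj = "x", yj = "y", zj = "z"),
                   by = c(j = "bead_index", "molecule")) %>%
        inner_join(rename(pos, xk = "x", yk = "y", zk = "z"),
                   by = c(k = "bead_index", "molecule")) %>%
        mutate(ux = minimum_image(.data$xi - .data$xj, box[1]),
               uy = minimum_image(.data$yi - .data$yj, box[2]),
               uz = minimum_image(.data$zi - .data$zj, box[3]),
               vx = minimum_image(.data$xk - .data$xj, box[1]),
               vy = minimum_image(.data$yk - .data$yj, box[2]),
               vz = minimum_image(.data$zk - .data$zj, box[3]),
               cosang = (.data$ux * .data$vx + .data$uy * .data$vy +
                           .data$uz * .data$vz) /
                 (sqrt(.data$ux^2 + .data$uy^2 + .data$uz^2) *
                    sqrt(.data$vx^2 + .data$vy^2 + .data$vz^2)),
               value = acos(pmin(1, pmax(-1, .data$cosang))) * 180 / pi,
               kind = "angle") %>%
        select("molecule", "term", "kind", "value")
    }
    mutate(bind_rows(bnd, ang), frame = fi, .before = 1)
  })
  out
}
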