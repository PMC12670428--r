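# shared fixtures built in code

# a bare rod "lipid" frame: n_mol straight chains of n_beads TAIL beads with
# a single HEAD-like bead (MHEAD2) at the base; directions given per molecule
rod_frame <- function(dirs, base = cbind(0, 0, 0), n_beads = 6,
                      spacing = 0.38, box = c(20, 20, 20), species = "CER_NS") {
  n <- nrow(dirs)
  if (nrow(base) == 1) base <- base[rep(1, n), , drop = FALSE]
  beads <- purrr::map_dfr(seq_len(n), function(i) {
    u <- dirs[i, ] / sqrt(sum(dirs[i, ]^2))
    t <- seq(0, by = spacing, length.out = n_beads)
    tibble::tibble(
      molecule = i, species = species,
      bead = c("MHEAD2", rep("TAIL", n_beads)),
      bead_index = seq_len(n_beads + 1),
      mass = c(40, rep(42, n_beads)),
      x = base[i, 1] + c(-0.1 * u[1], t * u[1]),
      y = base[i, 2] + c(-0.1 * u[2], t * u[2]),
      z = base[i, 3] + c(-0.1 * u[3], t * u[3]))
  })
  cg_frame(dplyr::mutate(beads, x = x + box[1] / 2, y = y + box[2] / 2,
                         z = z + box[3] / 2), box)
}

# uniformly random unit vectors
random_unit_vectors <- function(n, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(3 * n), ncol = 3)
    m / sqrt(rowSums(m^2))
  })
}

# rectangular density profile on a shared grid
rect_profile <- function(z, lo, hi, height = 1, bin = z[2] - z[1]) {
  d <- ifelse(z >= lo & z <= hi, height, 0)
  structure(tibble::tibble(z = z, density = d),
            bin_width = bin, area = 1, total_mass = sum(d) * bin,
            n_frames = 1L,
            class = c("density_profile", class(tibble::tibble())))
}

# atomistic frame from a template with supplied coordinates (one molecule)
template_atoms_frame <- function(tpl, xyz, box = c(10, 10, 10),
                                 resname = tpl$name, molecule = 1L) {
  at <- tpl$atoms
  tibble::tibble(molecule = molecule, resname = resname, atom = at$atom,
                 element = at$element,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]) -> out
  attr(out, "box") <- box
  out
}
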