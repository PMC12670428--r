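#' Read an atomistic frame from a GRO file
#'
#' Minimal fixed-width reader for the GROMACS coordinate format (no R
#' package in the stack reads it).  Coordinates are already in nm.  Residue
#' ids become molecule ids; masses are looked up from the first character of
#' the atom name unless the caller supplies them later.
#'
#' @param path GRO file path.
#' @return Atomistic frame tibble (`molecule`, `resname`, `atom`, `element`,
#'   `x`, `y`, `z`) with a `box` attribute.
#' @export
read_atomistic_gro <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  body <- lines[3:(2 + n)]
  boxline <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])
  out <- tibble(
    molecule = as.integer(substr(body, 1, 5)),
    resname = trimws(substr(body, 6, 10)),
    atom = trimws(substr(body, 11, 15)),
    x = as.numeric(substr(body, 21, 28)),
    y = as.numeric(substr(body, 29, 36)),
    z = as.numeric(substr(body, 37, 44))
  )
  out$element <- substr(gsub("[0-9]", "", out$atom), 1, 1)
  attr(out, "box") <- boxline[1:3]
  out
}

#' Read an atomistic frame from a PDB file
#'
#' Thin wrapper around `bio3d::read.pdb()`; coordinates are converted from
#' Angstrom to nm.  Requires the bio3d package.
#'
#' @param path PDB file path.
#' @param box Box lengths in nm (PDB CRYST1 is used when present).
#' @return Atomistic frame tibble as in [read_atomistic_gro()].
#' @export
read_atomistic_pdb <- function(path, box = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("read_atomistic_pdb requires the bio3d package")
  }
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  out <- tibble(
    molecule = as.integer(a$resno),
    resname = trimws(a$resid),
    atom = trimws(a$elety),
    element = ifelse(nzchar(trimws(a$elesy)), trimws(a$elesy),
                     substr(gsub("[0-9]", "", trimws(a$elety)), 1, 1)),
    x = a$x / 10, y = a$y / 10, z = a$z / 10
  )
  if (is.null(box)) {
    cell <- tryCatch(pdb$cryst1$abc, error = function(e) NULL)
    if (!is.null(cell) && length(cell) == 3 && all(cell > 0)) box <- cell / 10
  }
  if (!is.null(box)) attr(out, "box") <- box
  out
}

#' Read trajectory frames from a DCD file
#'
#' Thin wrapper around `bio3d::read.dcd()`: each stored frame is combined
#' with the topology (atom/residue identities) of a reference frame, giving
#' a list of atomistic frames ready for [map_frame()].  DCD coordinates are
#' Angstrom and converted to nm.
#'
#' @param path DCD trajectory path.
#' @param topology Atomistic frame tibble supplying `molecule`, `resname`,
#'   `atom`, `element` in file atom order (e.g. from
#'   [read_atomistic_pdb()]).
#' @param box Box lengths (nm) applied to every frame (DCD cell records are
#'   not relied upon).
#' @return List of atomistic frame tibbles with `box` attributes.
#' @export
read_atomistic_dcd <- function(path, topology, box) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("read_atomistic_dcd requires the bio3d package")
  }
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  n_at <- ncol(xyz) / 3
  if (n_at != nrow(topology)) {
    abort(sprintf("trajectory has %d atoms but topology has %d",
                  n_at, nrow(topology)))
  }
  lapply(seq_len(nrow(xyz)), function(i) {
    fr <- topology
    fr$x <- xyz[i, seq(1, 3 * n_at, by = 3)] / 10
    fr$y <- xyz[i, seq(2, 3 * n_at, by = 3)] / 10
    fr$z <- xyz[i, seq(3, 3 * n_at, by = 3)] / 10
    attr(fr, "box") <- box
    fr
  })
}

#' Serialize a CG template as structured text
#'
#' Sectioned plain-text format (`[beads]`, `[atoms]`, `[bonds]`, `[angles]`)
#' so templates can be inspected and exchanged without R.
#'
#' @param tpl A `cg_template`.
#' @param path File path.
#' @export
write_cg_template <- function(tpl, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cg_template %s tail_factor %s", tpl$name,
                     format(tpl$tail_factor)), con)
  dump_section <- function(name, tb) {
    writeLines(paste0("[", name, "]"), con)
    utils::write.table(as.data.frame(tb), con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  dump_section("beads", select(tpl$beads, -dplyr::any_of("mass")))
  dump_section("atoms", tpl$atoms[, c("atom", "element", "bead_index")])
  dump_section("bonds", tpl$bonds)
  dump_section("angles", tpl$angles)
  invisible(path)
}

#' @rdname write_cg_template
#' @export
read_cg_template <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], " ")[[1]]
  name <- hdr[3]
  tail_factor <- suppressWarnings(as.numeric(hdr[5]))
  marks <- grep("^\\[", lines)
  sections <- list()
  for (i in seq_along(marks)) {
    lab <- gsub("[][]", "", lines[marks[i]])
    to <- if (i < length(marks)) marks[i + 1] - 1 else length(lines)
    block <- lines[(marks[i] + 1):to]
    block <- block[nzchar(block)]
    sections[[lab]] <- as_tibble(utils::read.table(
      text = paste(block, collapse = "\n"), header = TRUE, sep = "\t"))
  }
  new_cg_template(name, sections$beads, sections$atoms,
                  sections$bonds, sections$angles, tail_factor = tail_factor)
}
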