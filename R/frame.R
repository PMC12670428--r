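#' Construct a CG frame
#'
#' A `cg_frame` is a tibble of beads carrying an orthorhombic periodic box
#' as an attribute.  Required columns: `molecule` (integer id), `species`,
#' `bead` (type name), `bead_index` (index within the molecule template),
#' `mass` (amu), `x`, `y`, `z` (nm).
#'
#' @param beads Tibble of beads.
#' @param box Numeric length-3, box edge lengths in nm.
#' @return A `cg_frame` (tibble subclass).
#' @export
cg_frame <- function(beads, box) {
  need <- c("molecule", "species", "bead", "bead_index", "mass", "x", "y", "z")
  miss <- setdiff(need, names(beads))
  if (length(miss)) abort(paste0("missing bead columns: ", paste(miss, collapse = ", ")))
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
    abort("box must be three positive finite lengths (nm)")
  }
  if (any(!is.finite(beads$x + beads$y + beads$z))) abort("non-finite coordinates")
  out <- as_tibble(beads)
  attr(out, "box") <- box
  class(out) <- c("cg_frame", class(out))
  out
}

#' Box lengths of a frame
#' @param frame A `cg_frame`.
#' @return Numeric length-3 (nm).
#' @export
frame_box <- function(frame) {
  box <- attr(frame, "box")
  if (is.null(box)) abort("frame has no box attribute; is it a cg_frame?")
  box
}

#' @export
print.cg_frame <- function(x, ...) {
  box <- attr(x, "box")
  cat(sprintf("<cg_frame> %d beads, %d molecules, box %.3f x %.3f x %.3f nm\n",
              nrow(x), dplyr::n_distinct(x$molecule), box[1], box[2], box[3]))
  NextMethod()
}

# coerce a list-or-single frame argument into a list of cg_frames
.as_frame_list <- function(frames) {
  if (inherits(frames, "cg_frame")) list(frames) else frames
}

#' Write / read a CG frame as plain text
#'
#' Tab-separated bead table with a `# box lx ly lz` header line; a portable
#' plain-text exchange format for CG configurations.
#'
#' @param frame A `cg_frame`.
#' @param path File path.
#' @return `read_cg_frame()` returns a `cg_frame`; `write_cg_frame()` the
#'   path, invisibly.
#' @export
write_cg_frame <- function(frame, path) {
  box <- frame_box(frame)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# box %.8f %.8f %.8f", box[1], box[2], box[3]), con)
  utils::write.table(as.data.frame(frame), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cg_frame
#' @export
read_cg_frame <- function(path) {
  hdr <- readLines(path, n = 1)
  box <- as.numeric(strsplit(sub("^# box ", "", hdr), " ")[[1]])
  beads <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1)
  cg_frame(as_tibble(beads), box)
}
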