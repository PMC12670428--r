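#' Assign lipids to leaflets
#'
#' Groups lipids by one-dimensional k-means clustering of their mean
#' headgroup z coordinate into the requested number of leaflets (centers
#' initialized at evenly spaced quantiles, so the assignment is
#' deterministic); leaflets are numbered bottom to top.
#'
#' @param frame A [cg_frame()].
#' @param n_leaflets Number of leaflets expected.
#' @param head_beads Bead type names treated as headgroup anchors.
#' @return A `leaflet_assignment`: tibble (`molecule`, `species`, `head_z`,
#'   `leaflet`) with attributes `n_leaflets` and `centers` (sorted z, nm).
#' @export
assign_leaflets <- function(frame, n_leaflets = 2,
                            head_beads = c("MHEAD2", "HEAD", "CHEAD")) {
  lipids <- frame %>%
    as_tibble() %>%
    filter(.data$species != "WATER")
  hz <- lipids %>%
    filter(.data$bead %in% head_beads) %>%
    group_by(.data$molecule, .data$species) %>%
    summarise(head_z = mean(.data$z), .groups = "drop")
  nolip <- setdiff(unique(lipids$molecule), hz$molecule)
  if (length(nolip)) {
    abort(sprintf("%d lipids have no headgroup bead among: %s",
                  length(nolip), paste(head_beads, collapse = ", ")))
  }
  nuz <- length(unique(round(hz$head_z, 6)))
  if (nuz < n_leaflets) {
    abort(sprintf("found only %d distinguishable headgroup levels for %d leaflets",
                  nuz, n_leaflets))
  }
  qs <- stats::quantile(hz$head_z, probs = (seq_len(n_leaflets) - 0.5) / n_leaflets,
                        names = FALSE)
  km <- kmeans(hz$head_z, centers = matrix(unique(qs), ncol = 1), iter.max = 100)
  if (length(km$size) < n_leaflets || any(km$size == 0)) {
    abort(sprintf("leaflet clustering found %d clusters, expected %d",
                  sum(km$size > 0), n_leaflets))
  }
  ord <- order(km$centers[, 1])
  relabel <- match(seq_along(ord), ord)
  out <- mutate(hz, leaflet = relabel[km$cluster])
  structure(out, n_leaflets = n_leaflets,
            centers = sort(km$centers[, 1]),
            class = c("leaflet_assignment", class(out)))
}

#' Inner-leaflet indices of an assignment
#'
#' The inner subset excludes the two outermost leaflets (those facing bulk
#' water in a multilayer).
#'
#' @param leaflets A `leaflet_assignment`.
#' @return Integer vector of leaflet indices.
#' @export
inner_leaflets <- function(leaflets) {
  k <- attr(leaflets, "n_leaflets")
  if (k <= 2) abort("a bilayer has no inner leaflets")
  seq(2, k - 1)
}

#' Central leaflet pair of an assignment
#' @param leaflets A `leaflet_assignment`.
#' @return Integer vector of length 2.
#' @export
central_pair <- function(leaflets) {
  k <- attr(leaflets, "n_leaflets")
  c(k / 2, k / 2 + 1)
}

#' Area per lipid
#'
#' Box cross-sectional area divided by the number of lipids in each leaflet.
#'
#' @param frame A [cg_frame()].
#' @param leaflets A `leaflet_assignment` for `frame`.
#' @param subset Leaflet indices to report (default all).
#' @return Tibble (`leaflet`, `n_lipids`, `apl` in nm^2) with attribute
#'   `mean_apl`, the leaflet-averaged APL.
#' @export
apl <- function(frame, leaflets, subset = NULL) {
  box <- frame_box(frame)
  area <- box[1] * box[2]
  tb <- leaflets %>%
    as_tibble() %>%
    count(.data$leaflet, name = "n_lipids") %>%
    mutate(apl = area / .data$n_lipids)
  if (!is.null(subset)) {
    if (!all(subset %in% tb$leaflet)) abort("empty leaflet in requested subset")
    tb <- filter(tb, .data$leaflet %in% subset)
  }
  if (any(tb$n_lipids == 0)) abort("empty leaflet")
  structure(tb, mean_apl = mean(tb$apl))
}

#' Normalized lipid area
#'
#' APL divided by the mole-fraction-weighted mean effective number of
#' hydrocarbon tails per lipid (1 for FFA, 2 for CER, 1.9 for CHOL), which
#' removes the trivial dependence of APL on lipid size.
#'
#' @param apl_value APL in nm^2 (scalar or vector).
#' @param spec A [composition_spec()] or named ratio vector.
#' @return NLA in nm^2.
#' @examples
#' nla(0.405, c(CER_NP = 1))                              # pure ceramide
#' nla(0.304, c(CER_NS = 1, CHOL = 0.5, FFA_C24 = 1))     # 1:0.5:1 mixture
#' @export
nla <- function(apl_value, spec) {
  apl_value / mean_effective_tails(spec)
}

#' Mass density profile along z
#'
#' Histogram of bead mass along the box normal divided by the bin volume,
#' averaged over frames.  z coordinates are wrapped into the box.
#'
#' @param frames A `cg_frame` or list of them (shared box z assumed).
#' @param subset Optional filter expression on the bead table, e.g.
#'   `bead == "W"` or `molecule %in% ids`.
#' @param bin_width Bin width in nm (default 0.1).
#' @return A `density_profile`: tibble (`z`, `density` in amu/nm^3) with
#'   attributes `bin_width`, `area`, `total_mass`, `n_frames`.
#' @export
density_profile <- function(frames, subset = NULL, bin_width = 0.1) {
  frames <- .as_frame_list(frames)
  box <- frame_box(frames[[1]])
  qsub <- enquo(subset)
  edges <- seq(0, box[3], by = bin_width)
  if (edges[length(edges)] < box[3]) edges <- c(edges, box[3])
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  vols <- diff(edges) * box[1] * box[2]
  dens <- matrix(0, length(mids), length(frames))
  total_mass <- 0
  for (fi in seq_along(frames)) {
    tb <- as_tibble(frames[[fi]])
    if (!quo_is_null(qsub)) tb <- filter(tb, !!qsub)
    if (nrow(tb) == 0) abort("empty selection for density profile")
    zw <- tb$z %% box[3]
    idx <- pmin(findInterval(zw, edges, rightmost.closed = TRUE), length(mids))
    m <- vapply(seq_along(mids), function(b) sum(tb$mass[idx == b]), numeric(1))
    dens[, fi] <- m / vols
    total_mass <- total_mass + sum(tb$mass)
  }
  out <- tibble(z = mids, density = rowMeans(dens))
  structure(out, bin_width = bin_width, area = box[1] * box[2],
            total_mass = total_mass / length(frames),
            n_frames = length(frames),
            class = c("density_profile", class(out)))
}

# 3-point parabolic refinement of a peak position
.refine_peak <- function(z, d, i) {
  if (i <= 1 || i >= length(z)) return(z[i])
  denom <- d[i - 1] - 2 * d[i] + d[i + 1]
  if (denom == 0) return(z[i])
  z[i] + 0.5 * (z[i + 1] - z[i]) * (d[i - 1] - d[i + 1]) / denom
}

#' Peak-to-peak thickness from a density profile
#'
#' Distance between the two dominant density maxima flanking the midplane
#' (the mass-weighted center of the profile), with 3-point parabolic
#' interpolation of each peak position.  On each side the flanking
#' (outermost) local maximum whose height reaches `min_height` of that
#' side's tallest maximum is taken, so the headgroup peaks are selected
#' even when chain interdigitation raises a comparable ridge at the
#' midplane.  This is the bilayer thickness for a two-leaflet profile and
#' the leaflet-pair thickness when the profile is restricted to one leaflet
#' pair of a multilayer.
#'
#' @param profile A [density_profile()].
#' @param min_height Fraction of each side's tallest maximum a peak must
#'   reach to qualify as the flanking peak (default 0.5).
#' @return Thickness in nm.
#' @export
thickness <- function(profile, min_height = 0.5) {
  z <- profile$z
  d <- profile$density
  peaks <- .local_maxima(d)
  if (d[1] > d[2]) peaks <- c(1L, peaks)
  n <- length(d)
  if (d[n] > d[n - 1]) peaks <- c(peaks, n)
  if (length(peaks) < 2) abort("fewer than two density maxima; no peak-to-peak thickness")
  mid <- sum(z * d) / sum(d)
  lower <- peaks[z[peaks] < mid]
  upper <- peaks[z[peaks] >= mid]
  if (!length(lower) || !length(upper)) {
    abort("density maxima do not flank the profile midplane")
  }
  pick <- function(side, outermost_first) {
    qual <- side[d[side] >= min_height * max(d[side])]
    if (outermost_first) qual[1] else qual[length(qual)]
  }
  pl <- pick(lower, TRUE)
  pu <- pick(upper, FALSE)
  .refine_peak(z, d, pu) - .refine_peak(z, d, pl)
}

# make molecules whole across the periodic boundary (minimum image about
# each molecule's first bead); assumes molecular extent < box/2 per axis
.unwrap_molecules <- function(tb, box) {
  tb %>%
    group_by(.data$molecule) %>%
    mutate(x = .data$x[1] + minimum_image(.data$x - .data$x[1], box[1]),
           y = .data$y[1] + minimum_image(.data$y - .data$y[1], box[2]),
           z = .data$z[1] + minimum_image(.data$z - .data$z[1], box[3])) %>%
    ungroup()
}

#' Per-lipid molecular directors
#'
#' The long axis of each lipid's tail beads: the eigenvector of the smallest
#' eigenvalue of the mass-weighted inertia tensor (the axis of least
#' resistance to rotation).  The sign is fixed to point away from the
#' headgroup (from the headgroup-side bead toward the tail center of mass).
#'
#' @param frame A [cg_frame()].
#' @param tail_beads Bead names forming the tail selection.
#' @param molecules Optional molecule ids to restrict to.
#' @return Tibble (`molecule`, `species`, `ux`, `uy`, `uz`, `n_beads`);
#'   lipids with fewer than two tail beads are dropped with a warning.
#' @export
lipid_directors <- function(frame,
                            tail_beads = c("TAIL", "TER2", "CBODY1", "CBODY2",
                                           "CBODY3", "CBODY4", "CTAIL1",
                                           "CTAIL2"),
                            molecules = NULL) {
  tb <- frame %>%
    as_tibble() %>%
    filter(.data$species != "WATER")
  if (!is.null(molecules)) tb <- filter(tb, .data$molecule %in% molecules)
  tails <- filter(tb, .data$bead %in% tail_beads)
  sizes <- count(tails, .data$molecule, .data$species)
  thin <- filter(sizes, .data$n < 2)
  if (nrow(thin)) {
    warn(sprintf("excluding %d lipids with < 2 tail beads", nrow(thin)))
    tails <- filter(tails, !.data$molecule %in% thin$molecule)
  }
  if (nrow(tails) == 0) abort("no tail beads selected")
  tails <- .unwrap_molecules(tails, frame_box(frame))
  tails %>%
    group_by(.data$molecule, .data$species) %>%
    dplyr::group_modify(function(df, key) {
      r <- cbind(df$x, df$y, df$z)
      m <- df$mass
      com <- colSums(r * m) / sum(m)
      rc <- sweep(r, 2, com)
      inertia <- diag(sum(m * rowSums(rc^2)), 3) -
        t(rc * m) %*% rc
      u <- eigen(inertia, symmetric = TRUE)$vectors[, 3]
      # orient away from the headgroup: along increasing bead_index
      ref <- rc[which.max(df$bead_index), ] - rc[which.min(df$bead_index), ]
      if (sum(u * ref) < 0) u <- -u
      tibble(ux = u[1], uy = u[2], uz = u[3], n_beads = nrow(df))
    }) %>%
    ungroup()
}

#' Per-lipid tilt angles
#'
#' Angle between the bilayer normal (z axis) and each lipid's director,
#' folded to \[0, 90\] degrees (the director is a headless axis).  The
#' pooled standard deviation across lipids, frames and replicates is the
#' reporting convention for tilt.
#'
#' @inheritParams lipid_directors
#' @param leaflets Optional `leaflet_assignment`; with `subset`, restricts to
#'   those leaflets.
#' @param subset Leaflet indices (requires `leaflets`).
#' @return Tibble (`molecule`, `species`, `tilt_deg`).
#' @export
tilt_angles <- function(frame, leaflets = NULL, subset = NULL,
                        tail_beads = c("TAIL", "TER2", "CBODY1", "CBODY2",
                                       "CBODY3", "CBODY4", "CTAIL1",
                                       "CTAIL2")) {
  mols <- NULL
  if (!is.null(leaflets) && !is.null(subset)) {
    mols <- leaflets$molecule[leaflets$leaflet %in% subset]
  }
  dirs <- lipid_directors(frame, tail_beads, mols)
  dirs %>%
    mutate(tilt_deg = acos(pmin(1, abs(.data$uz))) * 180 / pi) %>%
    select("molecule", "species", "tilt_deg")
}

#' Nematic order parameter S2
#'
#' Largest eigenvalue of the nematic tensor Q = (3/2) <u u^T> - I/2 over the
#' molecular directors u; 1 for perfect alignment, 0 for an isotropic set,
#' bounded in \[-0.5, 1\].
#'
#' @inheritParams tilt_angles
#' @return A single numeric S2.
#' @export
nematic_order <- function(frame, leaflets = NULL, subset = NULL,
                          tail_beads = c("TAIL", "TER2", "CBODY1", "CBODY2",
                                         "CBODY3", "CBODY4", "CTAIL1",
                                         "CTAIL2")) {
  mols <- NULL
  if (!is.null(leaflets) && !is.null(subset)) {
    mols <- leaflets$molecule[leaflets$leaflet %in% subset]
  }
  dirs <- lipid_directors(frame, tail_beads, mols)
  if (nrow(dirs) < 2) abort("need at least two molecular directors for S2")
  u <- as.matrix(dirs[, c("ux", "uy", "uz")])
  q <- 1.5 * crossprod(u) / nrow(u) - diag(3) / 2
  max(eigen(q, symmetric = TRUE)$values)
}

#' Interdigitation from opposing density profiles
#'
#' Overlap length of the top- and bottom-lipid mass density profiles,
#' lambda = 4 \eqn{\int} rho_top rho_bot / (rho_top + rho_bot)^2 dz,
#' integrated by the trapezoidal rule over the shared grid; the integrand is
#' defined as 0 where both densities vanish.  lambda equals w for identical
#' rectangular profiles of width w and 0 for disjoint profiles.
#'
#' @param rho_top,rho_bot [density_profile()]s on the same grid.
#' @return Overlap length in nm.
#' @export
interdigitation <- function(rho_top, rho_bot) {
  if (nrow(rho_top) != nrow(rho_bot) ||
      max(abs(rho_top$z - rho_bot$z)) > 1e-9) {
    abort("profiles are not on the same z grid")
  }
  a <- rho_top$density
  b <- rho_bot$density
  f <- ifelse(a + b > 0, 4 * a * b / (a + b)^2, 0)
  trapz(rho_top$z, f)
}

#' Interdigitation of a leaflet pair
#'
#' Convenience wrapper: takes the lipids of a leaflet pair, splits them into
#' top and bottom by headgroup position relative to the pair midpoint
#' (recomputed per frame), builds their mass density profiles on a shared
#' grid and integrates the overlap.
#'
#' @param frame A [cg_frame()].
#' @param leaflets A `leaflet_assignment`.
#' @param pair Two leaflet indices (default the central pair).
#' @param bin_width Profile bin width, nm.
#' @return Overlap length in nm.
#' @export
pair_interdigitation <- function(frame, leaflets, pair = central_pair(leaflets),
                                 bin_width = 0.1) {
  la <- as_tibble(leaflets)
  top_m <- la$molecule[la$leaflet == max(pair)]
  bot_m <- la$molecule[la$leaflet == min(pair)]
  if (!length(top_m) || !length(bot_m)) abort("empty leaflet in pair")
  rt <- density_profile(frame, molecule %in% top_m, bin_width = bin_width)
  rb <- density_profile(frame, molecule %in% bot_m, bin_width = bin_width)
  interdigitation(rt, rb)
}

#' Fraction of ceramides in the extended conformation
#'
#' A ceramide is extended (tails in adjacent leaflets) rather than hairpin
#' when the angle between the directional vectors of its two tails exceeds
#' 90 degrees.  Each tail's directional vector runs from its first (closest
#' to the headgroup) tail bead to the tail's center of mass.
#'
#' @param frame A [cg_frame()].
#' @param registry Template registry (identifies each species' two chains).
#' @param molecules Optional ceramide molecule ids (default: all CER
#'   species).  Selecting non-ceramide molecules is an error.
#' @return Percentage in \[0, 100\].
#' @export
extended_fraction <- function(frame, registry = default_registry(),
                              molecules = NULL) {
  tb <- as_tibble(frame)
  if (is.null(molecules)) {
    molecules <- unique(tb$molecule[startsWith(tb$species, "CER")])
  }
  sel <- filter(tb, .data$molecule %in% molecules)
  if (any(!startsWith(unique(sel$species), "CER"))) {
    abort("extended_fraction is defined for ceramides only")
  }
  if (!nrow(sel)) abort("no ceramides selected")
  chain_of <- purrr::map_dfr(unique(sel$species), function(sp) {
    tpl <- registry[[sp]]
    mutate(select(filter(tpl$beads, .data$role == "tail"),
                  bead_index = "index", chain = "chain"), species = sp)
  })
  tails <- inner_join(sel, chain_of, by = c("species", "bead_index"))
  tails <- .unwrap_molecules(tails, frame_box(frame))
  vecs <- tails %>%
    group_by(.data$molecule, .data$chain) %>%
    arrange(.data$bead_index, .by_group = TRUE) %>%
    summarise(vx = weighted.mean(.data$x, .data$mass) - .data$x[1],
              vy = weighted.mean(.data$y, .data$mass) - .data$y[1],
              vz = weighted.mean(.data$z, .data$mass) - .data$z[1],
              .groups = "drop")
  wide <- vecs %>%
    tidyr::pivot_wider(names_from = "chain",
                       values_from = c("vx", "vy", "vz"))
  dot <- wide$vx_sphingoid * wide$vx_acyl + wide$vy_sphingoid * wide$vy_acyl +
    wide$vz_sphingoid * wide$vz_acyl
  100 * mean(dot < 0)
}

#' Water molecules per lipid in an interleaflet region
#'
#' Counts W beads between the headgroup planes of a leaflet pair and scales
#' by the waters per bead; normalized by the number of lipids in the pair.
#'
#' @param frame A [cg_frame()].
#' @param leaflets A `leaflet_assignment`.
#' @param pair Two leaflet indices (default the central pair).
#' @param waters_per_bead Water molecules represented by one W bead.
#' @return Water molecules per lipid.
#' @export
water_per_lipid <- function(frame, leaflets, pair = central_pair(leaflets),
                            waters_per_bead = 4) {
  centers <- attr(leaflets, "centers")
  if (is.null(centers) || any(pair > length(centers))) {
    abort("undefined interleaflet region for the requested pair")
  }
  lo <- centers[min(pair)]
  hi <- centers[max(pair)]
  tb <- as_tibble(frame)
  n_w <- sum(tb$bead == "W" & tb$z > lo & tb$z < hi)
  la <- as_tibble(leaflets)
  n_lip <- sum(la$leaflet %in% pair)
  if (n_lip == 0) abort("no lipids in the bounding leaflet pair")
  waters_per_bead * n_w / n_lip
}
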