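#' Estimated leaflet cross-sectional area
#'
#' `A_est = APL_est * N_lipids / N_leaflets`, the target box area used by
#' the shape-annealing self-assembly protocol.
#'
#' @param apl_est Estimated area per lipid, nm^2.
#' @param n_lipids Lipid count.
#' @param n_leaflets Number of leaflets (2 or 6).
#' @return Area in nm^2.
#' @examples
#' estimate_area(0.34, 1800, 6)   # 102 nm^2
#' @export
estimate_area <- function(apl_est, n_lipids, n_leaflets) {
  if (n_leaflets <= 0) abort("n_leaflets must be positive")
  if (apl_est <= 0 || n_lipids <= 0) abort("apl_est and n_lipids must be positive")
  apl_est * n_lipids / n_leaflets
}

#' Initial box dimensions for a randomized packing
#'
#' Box sizing for the pre-assembly random packing: lipid volume from the
#' total lipid mass at the packing density (0.8 g/cm^3), water volume from
#' the water-bead mass at 1 g/cm^3; the z length is the total volume over
#' the target cross-sectional area, and x = y = sqrt(area).
#'
#' @param spec A [composition_spec()].
#' @param leaflet_area Target cross-sectional area, nm^2 (e.g. from
#'   [estimate_area()]).
#' @param registry Template registry supplying species masses.
#' @param lipid_density,water_density Packing densities, g/cm^3.
#' @return One-row tibble: `lx`, `ly`, `lz` (nm), `lipid_volume`,
#'   `water_volume` (nm^3).
#' @export
initial_box <- function(spec, leaflet_area, registry = default_registry(),
                        lipid_density = 0.8, water_density = 1.0) {
  counts <- composition_counts(spec)
  miss <- setdiff(counts$species, names(registry))
  if (length(miss)) {
    abort(paste0("no template (mass) for species: ", paste(miss, collapse = ", ")))
  }
  masses <- vapply(registry[counts$species], template_mass, numeric(1))
  m_lipid <- sum(counts$count * masses)
  n_w <- spec$water_beads_per_lipid * spec$n_lipids
  m_water <- n_w * template_mass(registry$WATER)
  v_lipid <- m_lipid * .amu_per_gcm3_nm3 / lipid_density
  v_water <- m_water * .amu_per_gcm3_nm3 / water_density
  tibble(lx = sqrt(leaflet_area), ly = sqrt(leaflet_area),
         lz = (v_lipid + v_water) / leaflet_area,
         lipid_volume = v_lipid, water_volume = v_water)
}

#' Shape-annealing and temperature-ramp schedule
#'
#' The self-assembly protocol as data: relaxation preludes
#' (two displacement-capped constant-energy runs and a 10 ns NPT density
#' equilibration), constant-volume shape annealing (area expanded to
#' 2.5 A_est over 150 ns at 500 K, compressed back to A_est over 150 ns
#' while cooling linearly to 305 K), an NPT heating/cooling anneal
#' (305 -> 400 K over 100 ns, back to 305 K over 50 ns) and a 150 ns NPT
#' production phase at 305 K and 1 bar.  During NVT phases the box height
#' adjusts to keep the volume constant.
#'
#' @param a_est Estimated leaflet area, nm^2 (see [estimate_area()]).
#' @param expansion_factor Area expansion multiple (default 2.5).
#' @return An `anneal_schedule` tibble with columns `phase`, `ensemble`,
#'   `duration_ns`, `temp_start_K`, `temp_end_K`, `area_start_nm2`,
#'   `area_end_nm2`, `pressure_bar`, `note`.
#' @examples
#' build_schedule(estimate_area(0.34, 1800, 6))
#' @export
build_schedule <- function(a_est, expansion_factor = 2.5) {
  if (a_est <= 0) abort("a_est must be positive")
  out <- tibble(
    phase = c("nve_relax_cold", "nve_relax", "npt_density",
              "nvt_expand", "nvt_compress", "npt_heat", "npt_cool",
              "npt_production"),
    ensemble = c("NVE", "NVE", "NPT", "NVT", "NVT", "NPT", "NPT", "NPT"),
    duration_ns = c(0.01, 0.01, 10, 150, 150, 100, 50, 150),
    temp_start_K = c(105, 305, 305, 500, 500, 305, 400, 305),
    temp_end_K = c(105, 305, 305, 500, 305, 400, 305, 305),
    area_start_nm2 = c(NA, NA, NA, a_est, expansion_factor * a_est,
                       NA, NA, NA),
    area_end_nm2 = c(NA, NA, NA, expansion_factor * a_est, a_est,
                     NA, NA, NA),
    pressure_bar = c(NA, NA, 1, NA, NA, 1, 1, 1),
    note = c("0.1 A displacement cap per step", "0.1 A displacement cap per step",
             "density equilibration", "shape annealing: expand at constant volume",
             "shape annealing: compress, linear cooling",
             "defect anneal, semi-isotropic barostat",
             "defect anneal, semi-isotropic barostat",
             "production at physiological conditions"))
  structure(out, a_est = a_est,
            class = c("anneal_schedule", class(out)))
}

#' Temperature along a schedule
#'
#' Piecewise-linear interpolation of the set-point temperature at elapsed
#' time `t_ns` (measured from the start of the schedule).
#'
#' @param schedule An `anneal_schedule`.
#' @param t_ns Elapsed times, ns.
#' @return Temperatures in K.
#' @export
schedule_temperature <- function(schedule, t_ns) {
  ends <- cumsum(schedule$duration_ns)
  starts <- c(0, head(ends, -1))
  vapply(t_ns, function(t) {
    if (t < 0 || t > ends[length(ends)]) return(NA_real_)
    i <- which(t <= ends)[1]
    frac <- (t - starts[i]) / schedule$duration_ns[i]
    schedule$temp_start_K[i] + frac * (schedule$temp_end_K[i] - schedule$temp_start_K[i])
  }, numeric(1))
}

#' Total scheduled time
#'
#' @param schedule An `anneal_schedule`.
#' @param main_only Count only the annealing and production phases (the
#'   600 ns core), excluding the relaxation preludes.
#' @return Duration in ns.
#' @export
schedule_duration <- function(schedule, main_only = FALSE) {
  tb <- schedule
  if (main_only) {
    tb <- filter(tb, .data$phase %in% c("nvt_expand", "nvt_compress",
                                        "npt_heat", "npt_cool",
                                        "npt_production"))
  }
  sum(tb$duration_ns)
}

#' @export
tidy.anneal_schedule <- function(x, ...) as_tibble(x)

#' Write a schedule as structured text
#' @param schedule An `anneal_schedule`.
#' @param path File path.
#' @export
write_schedule <- function(schedule, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# a_est_nm2 %.6f", attr(schedule, "a_est")), con)
  utils::write.table(as.data.frame(schedule), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
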