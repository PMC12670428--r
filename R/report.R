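#' Structural metrics for one frame
#'
#' Computes the full metric suite for a single CG frame following the
#' multilayer reporting conventions: APL, NLA and the extended-conformation
#' fraction over the inner leaflets (all leaflets for a bilayer); tilt,
#' peak-to-peak thickness, S2, interdigitation and water per lipid for the
#' central leaflet pair (the two leaflets of a bilayer).
#'
#' @param frame A [cg_frame()].
#' @param spec A [composition_spec()] (for the NLA tail scaling).
#' @param n_leaflets Leaflet count to resolve (defaults to `spec`).
#' @param registry Template registry.
#' @param bin_width Density-profile bin width, nm.
#' @param inner_only For multilayers, restrict APL/NLA/extended to the inner
#'   leaflets (default TRUE; ignored for bilayers).
#' @return One-row tibble with columns `apl`, `nla`, `tilt`, `thickness`,
#'   `s2`, `interdigitation`, `extended_pct`, `water_per_lipid` and a
#'   list-column `tilt_angles` of the per-lipid values.
#' @export
frame_metrics <- function(frame, spec, n_leaflets = spec$n_leaflets,
                          registry = default_registry(), bin_width = 0.1,
                          inner_only = TRUE) {
  leaflets <- assign_leaflets(frame, n_leaflets)
  wide <- if (n_leaflets > 2 && inner_only) inner_leaflets(leaflets)
          else sort(unique(leaflets$leaflet))
  pair <- central_pair(leaflets)

  apl_tb <- apl(frame, leaflets, subset = wide)
  apl_mean <- attr(apl_tb, "mean_apl")

  la <- as_tibble(leaflets)
  pair_mols <- la$molecule[la$leaflet %in% pair]
  prof <- density_profile(frame, molecule %in% pair_mols, bin_width = bin_width)
  th <- thickness(prof)

  tl <- tilt_angles(frame, leaflets, subset = pair)
  s2 <- nematic_order(frame, leaflets, subset = pair)
  lam <- pair_interdigitation(frame, leaflets, pair, bin_width = bin_width)

  cer_mols <- la$molecule[startsWith(la$species, "CER") & la$leaflet %in% wide]
  ext <- if (length(cer_mols)) {
    extended_fraction(frame, registry, molecules = cer_mols)
  } else NA_real_
  wpl <- water_per_lipid(frame, leaflets, pair)

  tibble(apl = apl_mean, nla = nla(apl_mean, spec),
         tilt = mean(tl$tilt_deg), thickness = th, s2 = s2,
         interdigitation = lam, extended_pct = ext, water_per_lipid = wpl,
         tilt_angles = list(tl$tilt_deg))
}

#' Aggregate per-frame metrics into a structure report
#'
#' Averaging follows the leaflet -> frame -> replicate order: metrics are
#' already leaflet-averaged per frame, frames are averaged within each
#' replicate, and the reported mean and standard deviation are taken across
#' replicate means.  Tilt is the exception: its dispersion is the pooled
#' per-molecule standard deviation across all leaflets, frames and
#' replicates.  With a single replicate the SDs are reported as `NA` (not
#' zero).
#'
#' @param per_frame Tibble of [frame_metrics()] rows, one per frame, with an
#'   optional `replicate` column (assumed single replicate if absent).
#' @return A `structure_report` with elements `summary` (tibble: `metric`,
#'   `mean`, `sd`, `n_replicates`) and `per_frame`.
#' @export
aggregate_structure <- function(per_frame) {
  if (!nrow(per_frame)) abort("no frames to aggregate")
  if (!"replicate" %in% names(per_frame)) per_frame$replicate <- 1L
  metrics <- c("apl", "nla", "tilt", "thickness", "s2", "interdigitation",
               "extended_pct", "water_per_lipid")
  metrics <- intersect(metrics, names(per_frame))
  by_rep <- per_frame %>%
    group_by(.data$replicate) %>%
    summarise(dplyr::across(dplyr::all_of(metrics), ~mean(.x, na.rm = TRUE)),
              .groups = "drop")
  n_rep <- nrow(by_rep)
  summary <- by_rep %>%
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric") %>%
    group_by(.data$metric) %>%
    summarise(mean = mean(.data$value),
              sd = if (n_rep > 1) stats::sd(.data$value) else NA_real_,
              .groups = "drop") %>%
    mutate(n_replicates = n_rep)
  if ("tilt_angles" %in% names(per_frame)) {
    pooled <- pooled_sd(unlist(per_frame$tilt_angles))
    summary$sd[summary$metric == "tilt"] <- pooled
  }
  summary <- summary[match(metrics, summary$metric), ]
  structure(list(summary = summary, per_frame = per_frame),
            class = "structure_report")
}

#' @export
print.structure_report <- function(x, ...) {
  cat(sprintf("<structure_report> %d frames, %d replicate(s)\n",
              nrow(x$per_frame), x$summary$n_replicates[1]))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.structure_report <- function(x, ...) x$summary

#' @export
glance.structure_report <- function(x, ...) {
  tidyr::pivot_wider(select(x$summary, "metric", "mean"),
                     names_from = "metric", values_from = "mean")
}
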