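#' Biomass-weighted average of posterior draws
#'
#' The community aggregation repeatedly takes weighted averages of predicted
#' ratios across posterior draws: over subregions within a (species, region,
#' size class), then over species within a (region, size class), with
#' weights proportional to biomass density. This helper applies one such
#' weighting to a draws matrix (rows = draws, columns = cells); weights are
#' normalised to sum to one.
#'
#' @param draws S x k matrix of posterior draws.
#' @param w Length-k non-negative weights, not all zero.
#' @return A length-S vector of weighted-average draws.
#' @export
weighted_mean_draws <- function(draws, w) {
  if (all(w == 0)) abort("All weights are zero.", class = "ppmr_no_biomass")
  as.numeric(draws %*% (w / sum(w)))
}

#' Summarise community draws into median and uncertainty interval
#'
#' Percentiles use linear interpolation between order statistics (R quantile
#' type 7).
#'
#' @param draws Numeric vector of posterior draws (at least 100).
#' @param probs Lower and upper percentile (default 5th and 95th).
#' @return A one-row tibble with `median`, `q05`, `q95`.
#' @export
summarize_community <- function(draws, probs = c(0.05, 0.95)) {
  if (length(draws) < 100) {
    abort("Need at least 100 draws to summarise.", class = "ppmr_too_few_draws")
  }
  q <- quantile(draws, probs, type = 7, names = FALSE)
  tibble::tibble(median = median(draws), q05 = q[1], q95 = q[2])
}

#' Predict cells through the fallback ladder
#'
#' When a biomass cell's (species, region, subregion) labels were not all
#' seen by the fitted model, predictions fall back to the deepest trained
#' level: subregion, then region, then species, then family, then order,
#' then the fixed effects alone (always available). The level used is
#' recorded per cell.
#'
#' @param fit A [fit_ppmr()] object.
#' @param cells Tibble with `species`, `region`, `subregion`,
#'   `bin_lo_log10g`.
#' @param taxonomy Optional tibble `species`, `family`, `order` covering
#'   species absent from the training data (needed for family-level
#'   fallback of novel species).
#' @return A list: `draws` (S x nrow(cells) matrix) and `level_used`
#'   (character vector per cell).
#' @export
fallback_predict <- function(fit, cells, taxonomy = NULL) {
  cells <- tibble::as_tibble(cells)
  tax <- dplyr::bind_rows(taxonomy, training_taxonomy(fit)) |>
    dplyr::distinct(.data$species, .keep_all = TRUE)
  nd <- cells |>
    dplyr::select(dplyr::any_of(c("species", "region", "subregion", "bin_lo_log10g"))) |>
    dplyr::left_join(tax, by = "species")

  labs <- nested_labels(nd)
  trained <- fit$design$labels
  level_used <- rep("fixed", nrow(nd))
  for (l in rev(LEVELS)) {  # subregion first (deepest), order last
    hit <- level_used == "fixed" & !is.na(labs[[l]]) & labs[[l]] %in% trained[[l]]
    level_used[hit] <- l
  }

  S <- nrow(fit$draws)
  draws <- matrix(NA_real_, S, nrow(nd))
  for (l in unique(level_used)) {
    j <- which(level_used == l)
    draws[, j] <- suppressWarnings(predict_ppmr(fit, nd[j, , drop = FALSE], level = l))
  }
  list(draws = draws, level_used = level_used)
}

#' Community-wide mean PPMR per region and size class
#'
#' Aggregates model-predicted group-level PPMR into community-wide means
#' with full posterior uncertainty propagation. Per posterior draw,
#' subregion-level predictions are averaged into region-level species values
#' with weights proportional to each subregion's biomass density, and those
#' are averaged into a community value with weights proportional to each
#' species' biomass within the (region, size class). Aggregation happens on
#' the ratio (back-transformed) scale, and the resulting per-draw community
#' values are summarised by their median and 5th/95th percentiles.
#'
#' `coverage` reports the biomass fraction of each (region, size class)
#' predicted at species level or deeper; the per-cell fallback levels are
#' attached as attribute `"level_used"`. When the fitted group table covers
#' a cell, biomass-weighted community fish-diet proportions are also
#' reported.
#'
#' @param fit A [fit_ppmr()] object.
#' @param biomass Tibble with `species`, `region`, `subregion`,
#'   `bin_lo_log10g`, `density_kg_km` (non-negative).
#' @param taxonomy Optional taxonomy for species absent from training (see
#'   [fallback_predict()]).
#' @param probs Percentiles for the uncertainty interval.
#' @return A tibble of class `ppmr_community`: `region`, `bin_lo_log10g`,
#'   `metric`, `median`, `q05`, `q95`, `coverage`, `fish_prop_mass`,
#'   `fish_prop_count`. Attribute `"level_used"` holds the per-cell ladder
#'   outcome; attribute `"draws"` the per-(region, bin) community draws.
#' @export
community_ppmr <- function(fit, biomass, taxonomy = NULL, probs = c(0.05, 0.95)) {
  stopifnot(all(c("species", "region", "subregion", "bin_lo_log10g", "density_kg_km")
                %in% names(biomass)))
  if (any(biomass$density_kg_km < 0)) {
    abort("Biomass densities must be non-negative.", class = "ppmr_invalid_measurement")
  }
  cells <- biomass |> dplyr::filter(.data$density_kg_km > 0)
  if (nrow(cells) == 0) abort("All biomass densities are zero.", class = "ppmr_no_biomass")

  fp <- fallback_predict(fit, cells, taxonomy)

  # stage 1: subregion -> region within species x bin (Eq. 7-8 weighting)
  key_sp <- paste(cells$species, cells$region, cells$bin_lo_log10g, sep = "\r")
  sp_groups <- split(seq_len(nrow(cells)), key_sp)
  R_sp <- vapply(sp_groups, function(j) {
    weighted_mean_draws(fp$draws[, j, drop = FALSE], cells$density_kg_km[j])
  }, numeric(nrow(fp$draws)))
  sp_meta <- cells[vapply(sp_groups, `[`, integer(1), 1), c("species", "region", "bin_lo_log10g")]
  sp_meta$B <- vapply(sp_groups, function(j) sum(cells$density_kg_km[j]), numeric(1))

  # stage 2: species -> community within region x bin (Eq. 9-10 weighting)
  key_c <- paste(sp_meta$region, sp_meta$bin_lo_log10g, sep = "\r")
  c_groups <- split(seq_len(nrow(sp_meta)), key_c)
  comm_draws <- lapply(c_groups, function(j) {
    weighted_mean_draws(R_sp[, j, drop = FALSE], sp_meta$B[j])
  })
  c_meta <- sp_meta[vapply(c_groups, `[`, integer(1), 1), c("region", "bin_lo_log10g")]

  cover <- cells |>
    dplyr::mutate(level_used = fp$level_used) |>
    dplyr::group_by(.data$region, .data$bin_lo_log10g) |>
    dplyr::summarise(
      coverage = sum(.data$density_kg_km[.data$level_used %in%
                                           c("subregion", "region", "species")]) /
        sum(.data$density_kg_km),
      .groups = "drop")

  fish <- community_fish_props(fit, cells)

  out <- purrr::map2_dfr(comm_draws, seq_len(nrow(c_meta)), function(d, i) {
    dplyr::bind_cols(c_meta[i, ], summarize_community(d, probs))
  }) |>
    dplyr::mutate(metric = fit$response, .after = "bin_lo_log10g") |>
    dplyr::left_join(cover, by = c("region", "bin_lo_log10g")) |>
    dplyr::left_join(fish, by = c("region", "bin_lo_log10g")) |>
    dplyr::arrange(.data$region, .data$bin_lo_log10g)

  attr(out, "level_used") <- cells |>
    dplyr::mutate(level_used = fp$level_used) |>
    dplyr::count(.data$region, .data$level_used)
  attr(out, "draws") <- setNames(comm_draws,
                                 paste(c_meta$region, c_meta$bin_lo_log10g, sep = "/"))
  class(out) <- c("ppmr_community", class(out))
  out
}

# Biomass-weighted community diet composition from the fitted group table.
community_fish_props <- function(fit, cells) {
  gt <- fit$design$data
  cells |>
    dplyr::inner_join(
      gt |> dplyr::select("species", "region", "subregion", "bin_lo_log10g",
                          "fish_prop_mass", "fish_prop_count"),
      by = c("species", "region", "subregion", "bin_lo_log10g")) |>
    dplyr::group_by(.data$region, .data$bin_lo_log10g) |>
    dplyr::summarise(
      fish_prop_mass = sum(.data$fish_prop_mass * .data$density_kg_km) /
        sum(.data$density_kg_km),
      fish_prop_count = sum(.data$fish_prop_count * .data$density_kg_km) /
        sum(.data$density_kg_km),
      .groups = "drop")
}
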