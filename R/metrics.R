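#' Individual-predator PPMR metrics
#'
#' Two mean predator-prey mass ratios can be computed for one stomach. The
#' number-weighted ratio is the mean of the per-prey mass ratios,
#' \deqn{r^{num} = \frac{1}{n}\sum_j M/m_j,}
#' and is dominated by numerous small prey. The biomass-weighted ratio weights
#' each per-prey ratio by that prey's share of the stomach's total prey
#' biomass \eqn{w}, which collapses algebraically to predator mass over mean
#' prey mass:
#' \deqn{r^{bio} = \sum_j \frac{M}{m_j}\frac{m_j}{w} = \frac{M}{\bar m}.}
#' By the AM-HM inequality \eqn{r^{num} \ge r^{bio}}, with equality only when
#' all prey masses are equal.
#'
#' @param M Predator body mass (g), a single positive number.
#' @param prey_masses Individual prey body masses (g), non-empty, positive.
#' @return A dimensionless ratio.
#' @examples
#' r_num(1000, c(25, 25, 0.1, 0.1)) # 5020
#' r_bio(1000, c(25, 25, 0.1, 0.1)) # 79.68...
#' @export
r_num <- function(M, prey_masses) {
  check_stomach(M, prey_masses)
  mean(M / prey_masses)
}

#' @rdname r_num
#' @export
r_bio <- function(M, prey_masses) {
  check_stomach(M, prey_masses)
  M / mean(prey_masses)
}

check_stomach <- function(M, prey_masses) {
  if (length(prey_masses) == 0) {
    abort("Stomach holds no prey.", class = "ppmr_no_prey")
  }
  if (M <= 0 || any(prey_masses <= 0)) {
    abort("All masses must be positive.", class = "ppmr_invalid_measurement")
  }
  invisible(NULL)
}

#' Assign a predator to a 0.1-wide log10 body-mass bin
#'
#' Bins are half-open intervals \code{[lo, lo + 0.1)} on the log10-gram scale
#' with the lower bound inclusive; the returned value is the bin's lower
#' bound. A small tolerance keeps masses that are exact powers of 10^(k/10)
#' in the bin whose lower edge they sit on.
#'
#' @param M Predator body mass (g), vectorised.
#' @return Lower bin edge(s) in log10 g.
#' @examples
#' assign_mass_bin(10^2.34) # 2.3
#' assign_mass_bin(1)       # 0
#' @export
assign_mass_bin <- function(M) {
  if (any(M <= 0)) abort("Masses must be positive.", class = "ppmr_invalid_measurement")
  floor(log10(M) * 10 + 1e-9) / 10
}

#' Group-level weighted mean PPMR
#'
#' Aggregates individual-predator ratios over a group (typically one species,
#' 0.1-log10 body-mass class, and subregion). The number-weighted group mean
#' weights each predator by its share of the prey individuals counted in the
#' group, \eqn{R^{num} = \sum_i r_i^{num} n_i / N}. The biomass-weighted group
#' mean weights each predator by its specific total prey mass (g prey per g
#' predator) relative to the group total:
#' \eqn{R^{bio} = \sum_i r_i^{bio} p_i}, \eqn{p_i = (w_i/M_i)/\sum(w_i/M_i)}.
#'
#' @param r Individual ratios (`r_num` values for `group_R_num`, `r_bio`
#'   values for `group_R_bio`).
#' @param n Per-predator prey counts.
#' @param w Per-predator total prey biomass (g).
#' @param M Per-predator body mass (g).
#' @return The weighted group mean ratio.
#' @examples
#' group_R_num(c(10, 100), n = c(2, 8)) # 82
#' @export
group_R_num <- function(r, n) {
  stopifnot(length(r) == length(n), length(r) > 0)
  sum(r * n) / sum(n)
}

#' @rdname group_R_num
#' @export
group_R_bio <- function(r, w, M) {
  stopifnot(length(r) == length(w), length(r) == length(M), length(r) > 0)
  p <- (w / M) / sum(w / M)
  sum(r * p)
}

#' Per-predator PPMR table from preprocessed diet records
#'
#' Collapses a cleaned prey-record table (one row per prey record, with
#' resolved individual counts and masses) to one row per predator holding its
#' number- and biomass-weighted PPMR and diet composition. Prey rows carry
#' `n_ind` equal-mass individuals summarised by `sum_mass_g` and the sum of
#' reciprocal masses `sum_invmass`, so per-prey-row ratios aggregate exactly
#' without materialising every individual.
#'
#' @param clean A cleaned diet table as produced by [preprocess_diet()].
#' @return A tibble with one row per predator: taxonomy and location columns,
#'   `M` (g), `n_prey`, `w` (total prey biomass, g), `r_num`, `r_bio`,
#'   `fish_prop_mass`, `fish_prop_count`.
#' @export
ppmr_individual <- function(clean) {
  stopifnot(all(c("predator_id", "pred_mass_g", "n_ind", "sum_mass_g", "sum_invmass") %in%
                  names(clean)))
  clean |>
    dplyr::group_by(.data$predator_id, .data$species, .data$family, .data$order,
                    .data$region, .data$subregion) |>
    dplyr::summarise(
      M = .data$pred_mass_g[1],
      n_prey = sum(.data$n_ind),
      w = sum(.data$sum_mass_g),
      r_num = .data$pred_mass_g[1] / sum(.data$n_ind) * sum(.data$sum_invmass),
      r_bio = .data$pred_mass_g[1] * sum(.data$n_ind) / sum(.data$sum_mass_g),
      fish_prop_mass =
        sum(.data$sum_mass_g[.data$prey_group == "fish"]) / sum(.data$sum_mass_g),
      fish_prop_count =
        sum(.data$n_ind[.data$prey_group == "fish"]) / sum(.data$n_ind),
      .groups = "drop"
    )
}

#' Group PPMR table over species x mass bin x subregion
#'
#' Builds the group-level table the hierarchical model consumes: one row per
#' (species, 0.1-log10 mass bin, subregion) with at least `min_n` predators.
#' Weighted mean predator body mass is computed under both weighting schemes
#' (prey-count weights for the number-weighted response, specific-prey-mass
#' weights for the biomass-weighted response) for use as the matching
#' predictor. Fish diet proportions are group totals: fish prey biomass over
#' all prey biomass, and fish prey counts over all prey counts.
#'
#' Groups with fewer than `min_n` predators are dropped and recorded in the
#' drop log attached as attribute `"drop_log"` (see [drop_log()]).
#'
#' @param individuals Per-predator table from [ppmr_individual()], or a
#'   cleaned diet table from [preprocess_diet()] (detected by its columns).
#' @param min_n Minimum predators per group (default 10).
#' @return A tibble of class `ppmr_groups` with columns `species`, `family`,
#'   `order`, `region`, `subregion`, `bin_lo_log10g`, `n_pred`,
#'   `mean_mass_numw_g`, `mean_mass_biow_g`, `R_num`, `R_bio`,
#'   `fish_prop_mass`, `fish_prop_count`.
#' @export
ppmr_groups <- function(individuals, min_n = 10) {
  if ("sum_invmass" %in% names(individuals)) {
    individuals <- ppmr_individual(individuals)
  }
  ind <- individuals |>
    dplyr::mutate(bin_lo_log10g = assign_mass_bin(.data$M))

  grouped <- ind |>
    dplyr::group_by(.data$species, .data$bin_lo_log10g, .data$subregion)

  tab <- grouped |>
    dplyr::summarise(
      family = .data$family[1],
      order = .data$order[1],
      region = .data$region[1],
      n_pred = dplyr::n(),
      R_num = group_R_num(.data$r_num, .data$n_prey),
      R_bio = group_R_bio(.data$r_bio, .data$w, .data$M),
      mean_mass_numw_g = sum(.data$M * .data$n_prey) / sum(.data$n_prey),
      mean_mass_biow_g = sum(.data$M * (.data$w / .data$M)) / sum(.data$w / .data$M),
      fish_prop_mass = sum(.data$fish_prop_mass * .data$w) / sum(.data$w),
      fish_prop_count = sum(.data$fish_prop_count * .data$n_prey) / sum(.data$n_prey),
      .groups = "drop"
    ) |>
    dplyr::select("species", "family", "order", "region", "subregion",
                  "bin_lo_log10g", "n_pred", "mean_mass_numw_g",
                  "mean_mass_biow_g", "R_num", "R_bio",
                  "fish_prop_mass", "fish_prop_count")

  small <- tab |> dplyr::filter(.data$n_pred < min_n)
  tab <- tab |> dplyr::filter(.data$n_pred >= min_n)
  log <- add_drop(new_drop_log(),
                  paste(small$species, small$bin_lo_log10g, small$subregion, sep = "/"),
                  "group_below_min_n")
  attr(tab, "drop_log") <- log
  class(tab) <- c("ppmr_groups", class(tab))
  tab
}

#' Retrieve the drop log attached to a pipeline result
#'
#' Preprocessing and grouping record every excluded record with a reason code;
#' this accessor returns that log as a tibble.
#'
#' @param x An object returned by [preprocess_diet()] or [ppmr_groups()].
#' @return A tibble with columns `record_id` and `reason`.
#' @export
drop_log <- function(x) {
  attr(x, "drop_log") %||% new_drop_log()
}
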