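#' Configuration for the synthetic stomach-content generator
#'
#' Defines the study conditions the generator emulates: a five-level
#' taxonomic/spatial hierarchy (order / family / species / region /
#' subregion), predators spanning roughly four orders of magnitude in body
#' mass, prey drawn from species-specific log-normal feeding kernels (which
#' makes small prey numerically dominant), aggregated invertebrate records
#' reported as count + total mass or total mass only, and partially digested
#' prey. Effect standard deviations default to a species-dominant variance
#' structure.
#'
#' @param n_orders,families_per_order,species_per_family Taxonomy sizes.
#' @param n_regions,subregions_per_region Spatial structure.
#' @param bins_per_species Number of consecutive 0.1-log10 mass bins each
#'   species occupies; species size ranges are placed uniformly at random
#'   within `mass_range_log10`.
#' @param predators_per_group Predators sampled per (species, bin, region,
#'   subregion) cell.
#' @param fixed_coefs Fixed-effect triple (intercept, linear, quadratic) for
#'   log10 realized PPMR against standardized log10 predator mass.
#' @param order_effect_sds,family_effect_sds,species_effect_sds,region_effect_sds,subregion_effect_sds
#'   Standard-deviation triples (intercept, linear, quadratic) for each
#'   nested random-effect level, on the log10 ratio scale.
#' @param kernel_width_sigma Feeding-kernel width: sd of log10 prey mass
#'   around its central value (log10 units).
#' @param prey_per_stomach_mean Mean prey count per stomach (counts are
#'   1 + Poisson(mean - 1), so every stomach holds prey).
#' @param frac_aggregated Fraction of invertebrate records reported as
#'   count + total mass only.
#' @param frac_total_only Fraction reported as total mass only (count and
#'   individual masses unrecorded).
#' @param frac_digested Fraction of prey records flagged below 75% intact;
#'   digested fish and crab keep their lengths (so mass is reconstructable),
#'   digested invertebrates do not.
#' @param mass_range_log10 Predator body-mass range, log10 g.
#' @param seed Integer seed; every stochastic output is reproducible from
#'   (config, seed).
#' @return A list of class `ppmr_sim_config`.
#' @export
sim_config <- function(n_orders = 2, families_per_order = 3, species_per_family = 4,
                       n_regions = 2, subregions_per_region = 2,
                       bins_per_species = 6, predators_per_group = 15,
                       fixed_coefs = c(2.8, 0.3, -0.25),
                       order_effect_sds = c(0.10, 0.05, 0.05),
                       family_effect_sds = c(0.15, 0.05, 0.05),
                       species_effect_sds = c(0.50, 0.15, 0.10),
                       region_effect_sds = c(0.05, 0.02, 0.02),
                       subregion_effect_sds = c(0.10, 0.03, 0.03),
                       kernel_width_sigma = 0.5,
                       prey_per_stomach_mean = 6,
                       frac_aggregated = 0.64, frac_total_only = 0.19,
                       frac_digested = 0.10,
                       mass_range_log10 = c(0.5, 4.5),
                       seed = 1L) {
  cfg <- as.list(environment())
  sds <- c(cfg$order_effect_sds, cfg$family_effect_sds, cfg$species_effect_sds,
           cfg$region_effect_sds, cfg$subregion_effect_sds)
  if (any(sds < 0)) abort("Effect sds must be non-negative.", class = "ppmr_invalid_config")
  if (cfg$frac_aggregated + cfg$frac_total_only > 1) {
    abort("Aggregation fractions must sum to at most 1.", class = "ppmr_invalid_config")
  }
  if (diff(mass_range_log10) <= 1) {
    abort("Mass range must span more than one decade.", class = "ppmr_invalid_config")
  }
  if (n_orders < 1 || families_per_order < 1 || species_per_family < 1) {
    abort("Taxonomy sizes must be positive.", class = "ppmr_invalid_config")
  }
  structure(cfg, class = "ppmr_sim_config")
}

# Length-weight relationships the generator uses (and returns) for prey and
# predators; lengths are derived from masses through these exactly.
SIM_PREY_LW <- tibble::tibble(
  prey_taxon = c("forage_fish", "misc_fish", "crab_sp"),
  life_stage = "any",
  coef_a = c(1e-5, 8e-6, 5e-4),   # g mm^-b
  exponent_b = c(3, 3.05, 2.8)
)
SIM_PRED_LW_A <- 0.01  # g cm^-3
SIM_PRED_LW_B <- 3

# Deterministic predictor scaler for truth curves: moments of log10 mass and
# its square over a fine grid spanning the configured mass range.
sim_scaler <- function(mass_range_log10) {
  g <- seq(mass_range_log10[1], mass_range_log10[2], by = 0.01)
  list(mean_x = mean(g), sd_x = sd(g), mean_x2 = mean(g^2), sd_x2 = sd(g^2))
}

sim_eta <- function(log10M, sc, fixed, eff_rows) {
  x <- (log10M - sc$mean_x) / sc$sd_x
  x2 <- (log10M^2 - sc$mean_x2) / sc$sd_x2
  fixed[1] + fixed[2] * x + fixed[3] * x2 +
    eff_rows$i0 + eff_rows$i1 * x + eff_rows$i2 * x2
}

draw_effects <- function(labels, sds) {
  tibble::tibble(label = labels,
                 b0 = rnorm(length(labels), 0, sds[1]),
                 b1 = rnorm(length(labels), 0, sds[2]),
                 b2 = rnorm(length(labels), 0, sds[3]))
}

#' Simulate a raw stomach-content dataset with known ground truth
#'
#' Generates individual diet records, a biomass-density table, and the ground
#' truth needed to validate every downstream stage. Each species carries a
#' quadratic log10 realized-PPMR curve built from fixed coefficients plus
#' nested random deviations (order, family, species, region-in-species,
#' subregion-in-region). For a predator of mass \eqn{M} with curve value
#' \eqn{\eta}, individual log10 prey masses are drawn
#' \eqn{N(\log_{10} M - \eta, \sigma_{kernel}^2)}. Log-normal moment
#' identities give the exact group-level truth:
#' \eqn{R^{bio*} = 10^{\eta - \sigma^2 \ln 10 / 2}} and
#' \eqn{R^{num*} = 10^{\eta + \sigma^2 \ln 10 / 2}}, so the number-weighted
#' metric always exceeds the biomass-weighted one by the factor
#' \eqn{10^{\sigma^2 \ln 10}}.
#'
#' Record-format realism: invertebrate prey are pooled per stomach and taxon
#' and reported as count + total mass, total mass only, or listed individual
#' masses (configurable fractions); fish and crab prey are individual rows
#' with lengths consistent with the returned length-weight tables; a fraction
#' of records is flagged as digested (<75% intact), with lengths retained
#' only for fish and crab; a fraction of predators is recorded with length
#' only.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @return A list: `diet` (raw prey-record tibble in the [read_diet_csv()]
#'   schema with list-columns), `biomass` (tibble: species, region,
#'   subregion, bin_lo_log10g, density_kg_km), and `truth` (list holding the
#'   fixed coefficients, per-level effect sds and draws, the truth scaler,
#'   the per-group `group_truth` table with `r_bio_true`/`r_num_true`, and
#'   the generator's length-weight tables `prey_lw`/`pred_lw`).
#' @export
simulate_diet_data <- function(cfg = sim_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "ppmr_sim_config"))
  set.seed(seed)
  sc <- sim_scaler(cfg$mass_range_log10)

  # taxonomy and spatial labels
  tax <- tidyr::expand_grid(
    order = sprintf("O%02d", seq_len(cfg$n_orders)),
    fam_i = seq_len(cfg$families_per_order),
    sp_i = seq_len(cfg$species_per_family)
  ) |>
    dplyr::mutate(family = paste0(.data$order, "-F", .data$fam_i),
                  species = paste0(.data$family, "-S", .data$sp_i)) |>
    dplyr::select("order", "family", "species")
  regions <- sprintf("R%d", seq_len(cfg$n_regions))
  space <- tidyr::expand_grid(region = regions,
                              sub_i = seq_len(cfg$subregions_per_region)) |>
    dplyr::mutate(subregion = paste0(.data$region, letters[.data$sub_i])) |>
    dplyr::select("region", "subregion")

  # nested random effects
  eff_order <- draw_effects(unique(tax$order), cfg$order_effect_sds)
  eff_family <- draw_effects(unique(tax$family), cfg$family_effect_sds)
  eff_species <- draw_effects(tax$species, cfg$species_effect_sds)
  sp_reg <- tidyr::expand_grid(species = tax$species, region = regions)
  eff_region <- draw_effects(paste(sp_reg$species, sp_reg$region), cfg$region_effect_sds)
  sp_sub <- tidyr::expand_grid(species = tax$species, space)
  eff_subreg <- draw_effects(paste(sp_sub$species, sp_sub$region, sp_sub$subregion),
                             cfg$subregion_effect_sds)

  # species size ranges: consecutive 0.1 bins inside the global mass range
  all_bins <- seq(cfg$mass_range_log10[1], cfg$mass_range_log10[2] - 0.1 + 1e-9, by = 0.1)
  nb <- length(all_bins)
  bps <- min(cfg$bins_per_species, nb)
  starts <- sample.int(nb - bps + 1, nrow(tax), replace = TRUE)
  sp_bins <- tibble::tibble(
    species = rep(tax$species, each = bps),
    bin_lo_log10g = round(all_bins[rep(starts, each = bps) + rep(0:(bps - 1), nrow(tax))], 10)
  )

  grid <- sp_bins |>
    dplyr::left_join(tax, by = "species") |>
    tidyr::crossing(space)

  # total deviation triple per (species, region, subregion)
  unit_eff <- grid |>
    dplyr::distinct(.data$order, .data$family, .data$species, .data$region, .data$subregion) |>
    dplyr::mutate(
      i0 = eff_order$b0[match(.data$order, eff_order$label)] +
        eff_family$b0[match(.data$family, eff_family$label)] +
        eff_species$b0[match(.data$species, eff_species$label)] +
        eff_region$b0[match(paste(.data$species, .data$region), eff_region$label)] +
        eff_subreg$b0[match(paste(.data$species, .data$region, .data$subregion),
                            eff_subreg$label)],
      i1 = eff_order$b1[match(.data$order, eff_order$label)] +
        eff_family$b1[match(.data$family, eff_family$label)] +
        eff_species$b1[match(.data$species, eff_species$label)] +
        eff_region$b1[match(paste(.data$species, .data$region), eff_region$label)] +
        eff_subreg$b1[match(paste(.data$species, .data$region, .data$subregion),
                            eff_subreg$label)],
      i2 = eff_order$b2[match(.data$order, eff_order$label)] +
        eff_family$b2[match(.data$family, eff_family$label)] +
        eff_species$b2[match(.data$species, eff_species$label)] +
        eff_region$b2[match(paste(.data$species, .data$region), eff_region$label)] +
        eff_subreg$b2[match(paste(.data$species, .data$region, .data$subregion),
                            eff_subreg$label)]
    )

  # predators
  preds <- grid |>
    dplyr::left_join(unit_eff,
                     by = c("order", "family", "species", "region", "subregion")) |>
    tidyr::uncount(cfg$predators_per_group) |>
    dplyr::mutate(
      predator_id = sprintf("P%07d", dplyr::row_number()),
      log10M = runif(dplyr::n(), .data$bin_lo_log10g, .data$bin_lo_log10g + 0.1),
      M = 10^.data$log10M,
      eta = sim_eta(.data$log10M, sc, cfg$fixed_coefs,
                    list(i0 = .data$i0, i1 = .data$i1, i2 = .data$i2)),
      n_prey = 1L + rpois(dplyr::n(), cfg$prey_per_stomach_mean - 1)
    )

  # individual prey
  prey <- preds |>
    dplyr::select("predator_id", "species", "family", "order", "region",
                  "subregion", "M", "log10M", "eta", "n_prey") |>
    tidyr::uncount(.data$n_prey) |>
    dplyr::mutate(
      m = 10^rnorm(dplyr::n(), .data$log10M - .data$eta, cfg$kernel_width_sigma),
      prey_group = dplyr::case_when(
        .data$m >= 1 & runif(dplyr::n()) < 0.85 ~ "fish",
        .data$m >= 1 ~ "crab",
        TRUE ~ "other_invert"
      ),
      prey_taxon = dplyr::case_when(
        .data$prey_group == "crab" ~ "crab_sp",
        .data$prey_group == "fish" & .data$m < 20 ~ "forage_fish",
        .data$prey_group == "fish" ~ "misc_fish",
        .data$m < 0.01 ~ "copepod",
        .data$m < 0.1 ~ "amphipod",
        TRUE ~ "euphausiid"
      ),
      life_stage = "adult"
    )

  fishcrab <- prey |>
    dplyr::filter(.data$prey_group != "other_invert") |>
    dplyr::mutate(
      lw_i = match(.data$prey_taxon, SIM_PREY_LW$prey_taxon),
      len_mm = (.data$m / SIM_PREY_LW$coef_a[.data$lw_i])^(1 / SIM_PREY_LW$exponent_b[.data$lw_i]),
      digested = runif(dplyr::n()) < cfg$frac_digested,
      pct_intact = ifelse(.data$digested, runif(dplyr::n(), 20, 74.9),
                          runif(dplyr::n(), 75, 100)),
      ind_mass_g = purrr::map2(.data$m, .data$digested,
                               function(m, dig) if (dig) numeric(0) else m),
      ind_length_mm = as.list(.data$len_mm),
      prey_count = NA_real_, prey_total_mass_g = NA_real_
    ) |>
    dplyr::select(-"lw_i", -"len_mm", -"digested", -"m")

  inverts <- prey |>
    dplyr::filter(.data$prey_group == "other_invert") |>
    dplyr::group_by(.data$predator_id, .data$species, .data$family, .data$order,
                    .data$region, .data$subregion, .data$prey_taxon,
                    .data$life_stage, .data$prey_group) |>
    dplyr::summarise(count = dplyr::n(), total = sum(.data$m),
                     masses = list(.data$m), .groups = "drop") |>
    dplyr::mutate(
      u = runif(dplyr::n()),
      mode = dplyr::case_when(
        .data$u < cfg$frac_aggregated ~ "count_total",
        .data$u < cfg$frac_aggregated + cfg$frac_total_only ~ "total_only",
        TRUE ~ "listed"
      ),
      digested = runif(dplyr::n()) < cfg$frac_digested,
      pct_intact = ifelse(.data$digested, runif(dplyr::n(), 20, 74.9),
                          runif(dplyr::n(), 75, 100)),
      prey_count = ifelse(.data$mode == "count_total", .data$count, NA_real_),
      prey_total_mass_g = ifelse(.data$mode == "listed", NA_real_, .data$total),
      ind_mass_g = purrr::map2(.data$masses, .data$mode,
                               function(ms, md) if (md == "listed") ms else numeric(0)),
      ind_length_mm = purrr::map(seq_len(dplyr::n()), function(i) numeric(0))
    ) |>
    dplyr::select(-"count", -"total", -"masses", -"u", -"mode", -"digested")

  diet <- dplyr::bind_rows(
    fishcrab |> dplyr::select(-"log10M", -"eta", -"n_prey"),
    inverts
  ) |>
    dplyr::left_join(preds |> dplyr::select("predator_id", "M"), by = "predator_id",
                     suffix = c("", ".pred")) |>
    dplyr::mutate(
      M = dplyr::coalesce(.data$M, .data$M.pred)
    ) |>
    dplyr::select(-dplyr::any_of("M.pred")) |>
    dplyr::arrange(.data$predator_id)

  # 46% of predators recorded with length only
  pred_len_only <- preds |>
    dplyr::mutate(len_only = runif(dplyr::n()) < 0.46) |>
    dplyr::select("predator_id", "len_only", "M")
  diet <- diet |>
    dplyr::left_join(pred_len_only, by = "predator_id", suffix = c("", ".p")) |>
    dplyr::mutate(
      pred_mass_g = ifelse(.data$len_only, NA_real_, .data$M),
      pred_length_cm = ifelse(.data$len_only,
                              (.data$M / SIM_PRED_LW_A)^(1 / SIM_PRED_LW_B),
                              NA_real_)
    ) |>
    dplyr::select("predator_id", "species", "family", "order", "region",
                  "subregion", "pred_mass_g", "pred_length_cm", "prey_taxon",
                  "life_stage", "prey_count", "prey_total_mass_g",
                  "ind_mass_g", "ind_length_mm", "pct_intact", "prey_group")

  # biomass densities, log-normal per cell
  biomass <- grid |>
    dplyr::distinct(.data$species, .data$region, .data$subregion, .data$bin_lo_log10g) |>
    dplyr::mutate(density_kg_km = rlnorm(dplyr::n(), meanlog = log(10), sdlog = 1))

  # exact group-level truth at bin midpoints
  half_off <- cfg$kernel_width_sigma^2 * log(10) / 2
  group_truth <- grid |>
    dplyr::left_join(unit_eff,
                     by = c("order", "family", "species", "region", "subregion")) |>
    dplyr::mutate(
      mid = .data$bin_lo_log10g + 0.05,
      eta = sim_eta(.data$mid, sc, cfg$fixed_coefs,
                    list(i0 = .data$i0, i1 = .data$i1, i2 = .data$i2)),
      r_bio_true = 10^(.data$eta - half_off),
      r_num_true = 10^(.data$eta + half_off)
    ) |>
    dplyr::select("species", "family", "order", "region", "subregion",
                  "bin_lo_log10g", "eta", "r_bio_true", "r_num_true")

  truth <- list(
    fixed_coefs = cfg$fixed_coefs,
    level_sds = list(order = cfg$order_effect_sds, family = cfg$family_effect_sds,
                     species = cfg$species_effect_sds, region = cfg$region_effect_sds,
                     subregion = cfg$subregion_effect_sds),
    effects = list(order = eff_order, family = eff_family, species = eff_species,
                   region = eff_region, subregion = eff_subreg),
    scaler = sc,
    kernel_width_sigma = cfg$kernel_width_sigma,
    group_truth = group_truth,
    prey_lw = SIM_PREY_LW,
    pred_lw = tibble::tibble(species = tax$species, coef_a = SIM_PRED_LW_A,
                             exponent_b = SIM_PRED_LW_B)
  )
  list(diet = diet, biomass = biomass, truth = truth, config = cfg)
}

#' True community-wide mean PPMR from ground truth
#'
#' Independent oracle for the community aggregation: applies the
#' biomass-weighted averaging directly to the generator's true group-level
#' ratios in a single brute-force pass over (species, subregion) cells, with
#' no model prediction and no fallback ladder.
#'
#' @param truth The `truth` element of [simulate_diet_data()].
#' @param biomass The biomass tibble from the same simulation.
#' @return A tibble with `region`, `bin_lo_log10g`, `r_bio_true`,
#'   `r_num_true` — the true community-wide weighted means.
#' @export
truth_community_R <- function(truth, biomass) {
  truth$group_truth |>
    dplyr::inner_join(biomass, by = c("species", "region", "subregion", "bin_lo_log10g")) |>
    dplyr::group_by(.data$region, .data$bin_lo_log10g) |>
    dplyr::summarise(
      r_bio_true = sum(.data$r_bio_true * .data$density_kg_km) / sum(.data$density_kg_km),
      r_num_true = sum(.data$r_num_true * .data$density_kg_km) / sum(.data$density_kg_km),
      .groups = "drop"
    )
}

#' Simulate a group-level PPMR table directly from the hierarchical model
#'
#' Bypasses stomach-level simulation: draws nested random effects and
#' residual noise and emits a ready-made group table (the exact schema
#' [ppmr_groups()] produces) whose generative process is precisely the
#' hierarchical model. Because the response is built from the same
#' standardized design matrix the model fitting reconstructs, the true fixed
#' coefficients are exactly recoverable, which makes this the tool of choice
#' for sampler parameter-recovery and coverage checks.
#'
#' @param cfg A [sim_config()]; taxonomy/spatial sizes and effect sds are
#'   taken from it.
#' @param sigma_resid Residual sd of log10 R around the group-level curve.
#' @param seed Integer seed.
#' @return A list: `groups` (a `ppmr_groups`-schema tibble) and `truth`
#'   (fixed coefficients, level sds, per-unit effect draws, `sigma_resid`).
#' @export
simulate_group_table <- function(cfg = sim_config(), sigma_resid = 0.1,
                                 seed = cfg$seed) {
  stopifnot(inherits(cfg, "ppmr_sim_config"))
  set.seed(seed)

  tax <- tidyr::expand_grid(
    order = sprintf("O%02d", seq_len(cfg$n_orders)),
    fam_i = seq_len(cfg$families_per_order),
    sp_i = seq_len(cfg$species_per_family)
  ) |>
    dplyr::mutate(family = paste0(.data$order, "-F", .data$fam_i),
                  species = paste0(.data$family, "-S", .data$sp_i)) |>
    dplyr::select("order", "family", "species")
  regions <- sprintf("R%d", seq_len(cfg$n_regions))
  space <- tidyr::expand_grid(region = regions,
                              sub_i = seq_len(cfg$subregions_per_region)) |>
    dplyr::mutate(subregion = paste0(.data$region, letters[.data$sub_i])) |>
    dplyr::select("region", "subregion")

  all_bins <- seq(cfg$mass_range_log10[1], cfg$mass_range_log10[2] - 0.1 + 1e-9, by = 0.1)
  nb <- length(all_bins)
  bps <- min(cfg$bins_per_species, nb)
  starts <- sample.int(nb - bps + 1, nrow(tax), replace = TRUE)
  sp_bins <- tibble::tibble(
    species = rep(tax$species, each = bps),
    bin_lo_log10g = round(all_bins[rep(starts, each = bps) + rep(0:(bps - 1), nrow(tax))], 10)
  )

  eff_order <- draw_effects(unique(tax$order), cfg$order_effect_sds)
  eff_family <- draw_effects(unique(tax$family), cfg$family_effect_sds)
  eff_species <- draw_effects(tax$species, cfg$species_effect_sds)
  sp_reg <- tidyr::expand_grid(species = tax$species, region = regions)
  eff_region <- draw_effects(paste(sp_reg$species, sp_reg$region), cfg$region_effect_sds)
  sp_sub <- tidyr::expand_grid(species = tax$species, space)
  eff_subreg <- draw_effects(paste(sp_sub$species, sp_sub$region, sp_sub$subregion),
                             cfg$subregion_effect_sds)

  g <- sp_bins |>
    dplyr::left_join(tax, by = "species") |>
    tidyr::crossing(space) |>
    dplyr::mutate(
      mean_mass_numw_g = 10^(.data$bin_lo_log10g + 0.05),
      mean_mass_biow_g = .data$mean_mass_numw_g
    )

  lx <- log10(g$mean_mass_biow_g)
  x <- as.numeric(scale(lx))
  x2 <- as.numeric(scale(lx^2))

  triple <- function(eff, lab) {
    i <- match(lab, eff$label)
    eff$b0[i] + eff$b1[i] * x + eff$b2[i] * x2
  }
  eta <- cfg$fixed_coefs[1] + cfg$fixed_coefs[2] * x + cfg$fixed_coefs[3] * x2 +
    triple(eff_order, g$order) + triple(eff_family, g$family) +
    triple(eff_species, g$species) + triple(eff_region, paste(g$species, g$region)) +
    triple(eff_subreg, paste(g$species, g$region, g$subregion))
  y_bio <- eta + rnorm(nrow(g), 0, sigma_resid)
  y_num <- y_bio + cfg$kernel_width_sigma^2 * log(10)  # lognormal-kernel offset

  groups <- g |>
    dplyr::mutate(
      n_pred = cfg$predators_per_group,
      R_bio = 10^y_bio,
      R_num = 10^y_num,
      fish_prop_mass = runif(dplyr::n()),
      fish_prop_count = runif(dplyr::n())
    ) |>
    dplyr::select("species", "family", "order", "region", "subregion",
                  "bin_lo_log10g", "n_pred", "mean_mass_numw_g",
                  "mean_mass_biow_g", "R_num", "R_bio",
                  "fish_prop_mass", "fish_prop_count")
  class(groups) <- c("ppmr_groups", class(groups))

  list(groups = groups,
       truth = list(fixed_coefs = cfg$fixed_coefs,
                    level_sds = list(order = cfg$order_effect_sds,
                                     family = cfg$family_effect_sds,
                                     species = cfg$species_effect_sds,
                                     region = cfg$region_effect_sds,
                                     subregion = cfg$subregion_effect_sds),
                    effects = list(order = eff_order, family = eff_family,
                                   species = eff_species, region = eff_region,
                                   subregion = eff_subreg),
                    sigma_resid = sigma_resid))
}
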