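test_that("the generator is deterministic given (config, seed)", {
  cfg <- sim_config(n_orders = 1, families_per_order = 2, species_per_family = 2,
                    predators_per_group = 5, seed = 9)
  a <- simulate_diet_data(cfg)
  b <- simulate_diet_data(cfg)
  expect_identical(a$diet, b$diet)
  expect_identical(a$biomass, b$biomass)
  expect_identical(a$truth$group_truth, b$truth$group_truth)
  # and CSV serialisations are byte-identical
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  write_diet_csv(a$diet, fa); write_diet_csv(b$diet, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("a degenerate feeding kernel collapses both PPMR metrics to the species curve", {
  cfg <- sim_config(n_orders = 1, families_per_order = 1, species_per_family = 2,
                    predators_per_group = 6, kernel_width_sigma = 0,
                    frac_digested = 0, seed = 21)
  sim <- simulate_diet_data(cfg)
  clean <- suppressMessages(preprocess_diet(sim$diet, pred_lw = sim$truth$pred_lw))
  ind <- ppmr_individual(clean)
  # every prey in a stomach has the same mass, so r_num == r_bio exactly
  expect_equal(ind$r_num, ind$r_bio, tolerance = 1e-9)
  # and the truth tables agree: zero kernel width means no metric gap
  expect_equal(sim$truth$group_truth$r_bio_true, sim$truth$group_truth$r_num_true)
})

test_that("kernel width sets the gap between number- and biomass-weighted PPMR", {
  # lognormal moments: R_num*/R_bio* = 10^(sigma^2 ln 10)
  sigma <- 0.5
  expect_equal(10^(sigma^2 * log(10)), 3.765, tolerance = 1e-3)

  # individual masses must be listed for the moment identity to be testable:
  # count+total aggregation deliberately flattens within-row mass variation
  cfg <- sim_config(n_orders = 1, families_per_order = 1, species_per_family = 1,
                    bins_per_species = 1, n_regions = 1, subregions_per_region = 1,
                    predators_per_group = 100, prey_per_stomach_mean = 8,
                    kernel_width_sigma = sigma, frac_digested = 0,
                    frac_aggregated = 0, frac_total_only = 0, seed = 31)
  sim <- simulate_diet_data(cfg)
  clean <- suppressMessages(preprocess_diet(sim$diet, pred_lw = sim$truth$pred_lw))
  g <- ppmr_groups(clean, min_n = 10)
  expect_equal(nrow(g), 1L)
  ratio <- g$R_num / g$R_bio
  expect_lt(abs(ratio - 3.765) / 3.765, 0.15)
  # numeric dominance of small prey: the number-weighted metric is larger
  ind <- ppmr_individual(clean)
  expect_true(all(ind$r_num >= ind$r_bio))
})

test_that("the pipeline recovers true group R_bio for well-sampled groups", {
  cfg <- sim_config(n_orders = 1, families_per_order = 2, species_per_family = 2,
                    n_regions = 1, subregions_per_region = 1, bins_per_species = 4,
                    predators_per_group = 40, prey_per_stomach_mean = 8, seed = 77)
  sim <- simulate_diet_data(cfg)
  clean <- suppressMessages(preprocess_diet(sim$diet, pred_lw = sim$truth$pred_lw))
  ind <- ppmr_individual(clean)
  g <- ppmr_groups(ind, min_n = 10)
  prey_per_group <- clean |>
    dplyr::mutate(bin_lo_log10g = assign_mass_bin(.data$pred_mass_g)) |>
    dplyr::group_by(.data$species, .data$bin_lo_log10g, .data$subregion) |>
    dplyr::summarise(n_prey = sum(.data$n_ind), .groups = "drop")
  gt <- g |>
    dplyr::inner_join(prey_per_group, by = c("species", "bin_lo_log10g", "subregion")) |>
    dplyr::inner_join(sim$truth$group_truth,
                      by = c("species", "region", "subregion", "bin_lo_log10g")) |>
    dplyr::filter(.data$n_prey >= 200)
  expect_gt(nrow(gt), 5)
  rel <- abs(gt$R_bio - gt$r_bio_true) / gt$r_bio_true
  expect_lt(median(rel), 0.10)
  expect_lt(mean(rel > 0.25), 0.1)
})

test_that("the truth-community oracle is a plain biomass-weighted mean", {
  truth <- list(group_truth = tibble::tibble(
    species = c("a", "b"), family = "f", order = "o",
    region = "R1", subregion = "R1a", bin_lo_log10g = 2,
    eta = NA_real_, r_bio_true = c(100, 200), r_num_true = c(400, 800)))
  bio <- tibble::tibble(species = c("a", "b"), region = "R1", subregion = "R1a",
                        bin_lo_log10g = 2, density_kg_km = c(1, 1))
  tc <- truth_community_R(truth, bio)
  expect_equal(tc$r_bio_true, 150)
  expect_equal(tc$r_num_true, 600)
  # single species: the community curve is that species' curve
  tc1 <- truth_community_R(list(group_truth = truth$group_truth[1, ]), bio[1, ])
  expect_equal(tc1$r_bio_true, 100)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(species_per_family = 0), class = "ppmr_invalid_config")
  expect_error(sim_config(frac_aggregated = 0.9, frac_total_only = 0.2),
               class = "ppmr_invalid_config")
  expect_error(sim_config(mass_range_log10 = c(1, 1.5)), class = "ppmr_invalid_config")
  expect_error(sim_config(species_effect_sds = c(-1, 0, 0)), class = "ppmr_invalid_config")
})
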