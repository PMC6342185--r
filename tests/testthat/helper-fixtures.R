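# Shared, lazily built fixtures. Everything is generated in code; the cache
# just avoids refitting the same small model in several test files.
.fixtures <- new.env(parent = emptyenv())

fixture_sim <- function() {
  if (is.null(.fixtures$sim)) {
    cfg <- sim_config(n_orders = 2, families_per_order = 2, species_per_family = 3,
                      predators_per_group = 12, seed = 42)
    .fixtures$sim <- simulate_diet_data(cfg)
  }
  .fixtures$sim
}

fixture_clean <- function() {
  if (is.null(.fixtures$clean)) {
    sim <- fixture_sim()
    .fixtures$clean <- suppressMessages(
      preprocess_diet(sim$diet, pred_lw = sim$truth$pred_lw))
  }
  .fixtures$clean
}

fixture_groups <- function() {
  if (is.null(.fixtures$groups)) .fixtures$groups <- ppmr_groups(fixture_clean())
  .fixtures$groups
}

fixture_fit <- function() {
  if (is.null(.fixtures$fit)) {
    .fixtures$fit <- fit_ppmr(fixture_groups(), "R_bio", preset = "fast", seed = 7)
  }
  .fixtures$fit
}

# A tiny raw diet table covering the preprocessing paths explicitly.
toy_diet <- function() {
  tibble::tibble(
    predator_id = c("p1", "p1", "p2", "p2", "p3"),
    species = "cod", family = "Gadidae", order = "Gadiformes",
    region = "R1", subregion = "R1a",
    pred_mass_g = c(1000, 1000, NA, NA, 500),
    pred_length_cm = c(NA, NA, 40, 40, NA),
    prey_taxon = c("herring", "krill", "herring", "krill", "herring"),
    life_stage = "adult",
    prey_count = c(NA, 50, NA, NA, NA),
    prey_total_mass_g = c(NA, 5, NA, 1.0, NA),
    ind_mass_g = list(c(25, 25), numeric(0), numeric(0), numeric(0), numeric(0)),
    ind_length_mm = list(c(136, 136), numeric(0), c(136), numeric(0), c(100)),
    pct_intact = c(90, 80, 50, 80, 50),
    prey_group = c("fish", "other_invert", "fish", "other_invert", "fish")
  )
}

toy_prey_lw <- function() {
  tibble::tibble(prey_taxon = "herring", life_stage = "any",
                 coef_a = 1e-5, exponent_b = 3)
}

toy_pred_lw <- function() {
  tibble::tibble(species = "cod", coef_a = 0.01, exponent_b = 3)
}
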