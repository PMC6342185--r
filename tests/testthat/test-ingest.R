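test_that("digested fish mass is reconstructed from length, intact prey untouched", {
  d <- toy_diet()
  out <- reconstruct_digested_mass(d, toy_prey_lw())
  # p2's digested herring (50% intact, 136 mm) gains a back-calculated mass
  i <- which(out$predator_id == "p2" & out$prey_taxon == "herring")
  expect_true(out$mass_reconstructed[i])
  expect_equal(out$ind_mass_g[[i]], 1e-5 * 136^3)
  # the intact (90%) herring record keeps its measured masses
  expect_equal(out$ind_mass_g[[1]], c(25, 25))
  expect_false(out$mass_reconstructed[1])

  # direct arithmetic: three lengths under a cubic law
  d3 <- toy_diet()[3, ]
  d3$ind_length_mm <- list(c(50, 60, 70))
  r3 <- reconstruct_digested_mass(d3, toy_prey_lw())
  expect_equal(r3$ind_mass_g[[1]], c(1.25, 2.16, 3.43))

  # 80% intact is above threshold: never reconstructed
  d80 <- toy_diet()[1, ]
  d80$pct_intact <- 80
  d80$ind_mass_g <- list(numeric(0))
  expect_false(reconstruct_digested_mass(d80, toy_prey_lw())$mass_reconstructed[1])
})

test_that("digestion filter drops <75% intact without reconstruction, keeps 75 exactly", {
  d <- toy_diet()
  d$pct_intact <- c(74.9, 75.0, 50, 75, 50)
  d$ind_length_mm <- rep(list(numeric(0)), 5)  # nothing reconstructable
  out <- filter_digestion(d)
  expect_equal(nrow(out), 2L)                   # both records at exactly 75 survive
  expect_true(all(out$pct_intact == 75))
  lg <- drop_log(out)
  expect_equal(sort(unique(lg$reason)), "digested_no_length")
  expect_equal(nrow(lg), 3L)

  # a predator whose only prey is dropped is logged once in preprocessing
  d5 <- toy_diet()
  d5$pct_intact <- c(90, 80, 50, 80, 50)
  d5$ind_length_mm <- rep(list(numeric(0)), 5)
  res <- suppressMessages(preprocess_diet(d5, prey_lw = toy_prey_lw(),
                                          pred_lw = toy_pred_lw()))
  expect_false("p3" %in% res$predator_id)
  expect_equal(sum(drop_log(res)$record_id == "p3" &
                     drop_log(res)$reason == "predator_no_prey"), 1L)
})

test_that("prey mass imputation handles counts, totals and the fallback ladder", {
  base <- toy_diet()[2, ]  # krill record, count 50, total 5 g

  # case A: equal shares conserve total mass exactly
  a <- impute_prey_mass(base)
  expect_equal(a$n_ind, 50)
  expect_equal(a$sum_mass_g, 5)
  expect_equal(a$sum_invmass, 50 / 0.1)
  expect_false(a$count_imputed)

  # case B: count from rounded total / table mean, each at the table mean
  mm <- list(
    by_region = tibble::tibble(prey_taxon = character(), life_stage = character(),
                               region = character(), mean_mass_g = numeric()),
    by_stage = tibble::tibble(prey_taxon = "krill", life_stage = "adult",
                              mean_mass_g = 0.12),
    by_taxon = tibble::tibble(prey_taxon = "krill", mean_mass_g = 0.12)
  )
  b <- base
  b$prey_count <- NA
  b$prey_total_mass_g <- 1.0
  rb <- impute_prey_mass(b, mm)
  expect_equal(rb$n_ind, 8)             # round(1.0 / 0.12)
  expect_equal(rb$sum_mass_g, 8 * 0.12)
  expect_true(rb$count_imputed)

  # degenerate case B: rounding floors at one individual keeping the total
  tiny <- b
  tiny$prey_total_mass_g <- 0.05
  rt <- impute_prey_mass(tiny, mm)
  expect_equal(rt$n_ind, 1)
  expect_equal(rt$sum_mass_g, 0.05)

  # no table entry anywhere: unresolvable, dropped and logged
  orphan <- b
  orphan$prey_taxon <- "unknown_taxon"
  ro <- impute_prey_mass(orphan, mm)
  expect_equal(nrow(ro), 0L)
  expect_equal(drop_log(ro)$reason, "unresolvable_mass")

  # regional means take precedence over global ones
  mm2 <- mm
  mm2$by_region <- tibble::tibble(prey_taxon = "krill", life_stage = "adult",
                                  region = "R1", mean_mass_g = 0.5)
  rr <- impute_prey_mass(b, mm2)
  expect_equal(rr$n_ind, 2)             # round(1.0 / 0.5)
})

test_that("pooled mean-mass tables divide summed totals by summed counts", {
  d <- toy_diet()[c(2, 2), ]
  d$prey_count <- c(10, 30)
  d$prey_total_mass_g <- c(2, 2)
  mm <- mean_mass_table(d)
  expect_equal(mm$by_taxon$mean_mass_g, 4 / 40)
  expect_equal(mm$by_region$region, "R1")
})

test_that("predator mass estimation fills gaps from length and is idempotent", {
  d <- toy_diet()
  out <- suppressMessages(estimate_predator_mass(d, toy_pred_lw()))
  i <- which(out$predator_id == "p2")
  expect_equal(unique(out$pred_mass_g[i]), 0.01 * 40^3)  # 640 g
  expect_true(all(out$pred_mass_estimated[i]))
  # already-present masses unchanged
  expect_equal(out$pred_mass_g[out$predator_id == "p1"], c(1000, 1000))

  # no model and no mass: dropped with reason
  d2 <- toy_diet()
  d2$species <- "eel"
  o2 <- estimate_predator_mass(d2, toy_pred_lw())
  expect_false("p2" %in% o2$predator_id)
  expect_true("p2" %in% drop_log(o2)$record_id)

  dz <- toy_diet()
  dz$pred_length_cm[3] <- 0
  expect_error(estimate_predator_mass(dz, toy_pred_lw()),
               class = "ppmr_invalid_measurement")
})

test_that("full preprocessing is idempotent and monotone with a complete drop log", {
  sim <- fixture_sim()
  d <- sim$diet[1:800, ]
  once <- suppressMessages(preprocess_diet(d, pred_lw = sim$truth$pred_lw))
  twice <- suppressMessages(preprocess_diet(once, pred_lw = sim$truth$pred_lw))
  expect_equal(nrow(once), nrow(twice))
  expect_equal(once$n_ind, twice$n_ind)
  expect_equal(once$sum_mass_g, twice$sum_mass_g)
  expect_equal(once$pred_mass_g, twice$pred_mass_g)

  expect_lte(dplyr::n_distinct(once$predator_id), dplyr::n_distinct(d$predator_id))
  lg <- drop_log(once)
  expect_false(any(duplicated(lg)))
  expect_true(all(lg$reason %in% c("digested_no_length", "unresolvable_mass",
                                   "predator_no_mass", "predator_no_prey")))
  # case-A conservation: resolved totals match recorded totals exactly
  ca <- once[!is.na(once$prey_count) & !is.na(once$prey_total_mass_g) &
               !once$count_imputed, ]
  expect_lt(max(abs(ca$sum_mass_g - ca$prey_total_mass_g) / ca$prey_total_mass_g), 1e-9)
})

test_that("diet CSVs round-trip including semicolon-joined individual lists", {
  d <- toy_diet()
  path <- withr::local_tempfile(fileext = ".csv")
  write_diet_csv(d, path)
  back <- read_diet_csv(path)
  expect_equal(nrow(back), nrow(d))
  expect_equal(back$ind_mass_g[[1]], c(25, 25))
  expect_equal(back$ind_length_mm[[3]], 136)
  expect_equal(back$ind_mass_g[[2]], numeric(0))
  expect_equal(back$pred_mass_g, d$pred_mass_g)
})
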