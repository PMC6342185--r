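test_that("the design standardizes predictors and nests grouping labels", {
  g <- fixture_groups()
  d <- build_design(g, "R_bio")
  expect_equal(mean(d$X[, 2]), 0, tolerance = 1e-12)
  expect_equal(sd(d$X[, 2]), 1, tolerance = 1e-12)
  expect_equal(sd(d$X[, 3]), 1, tolerance = 1e-12)

  # quadratic column is the standardized square of raw log10 mass,
  # not the square of the standardized column
  lx <- log10(g$mean_mass_biow_g)
  expect_equal(d$X[, 3], as.numeric(scale(lx^2)))
  expect_false(isTRUE(all.equal(d$X[, 3], d$X[, 2]^2)))

  # scaler round-trips
  sc <- d$scaler
  x <- (lx - sc$mean_x) / sc$sd_x
  expect_equal(x * sc$sd_x + sc$mean_x, lx, tolerance = 1e-12)

  # two-point standardization uses the sample sd
  g2 <- g[1:2, ]
  g2$mean_mass_biow_g <- c(10, 1000)
  d2 <- build_design(g2, "R_bio")
  expect_equal(d2$X[, 2], c(-1, 1) / sqrt(2), tolerance = 1e-12)

  # child labels are unique within parents
  expect_true(all(table(sub("/.*", "", d$labels$family)) >= 1))
  expect_equal(length(d$labels$subregion),
               nrow(unique(g[, c("species", "region", "subregion")])))

  bad <- g; bad$R_bio[1] <- -1
  expect_error(build_design(bad, "R_bio"), class = "ppmr_invalid_response")
  one <- g[1:3, ]; one$mean_mass_biow_g <- 100
  expect_error(build_design(one, "R_bio"), class = "ppmr_invalid_design")
})

# A minimal hand-built fit object for closed-form checks of the R2 machinery.
fake_fit <- function(beta, sigma, n_draws = 4) {
  g <- fixture_groups()[1:6, ]
  g$mean_mass_biow_g <- 10^seq(1, 3.5, length.out = 6)
  d <- build_design(g, "R_bio")
  cols <- c(sprintf("beta[%d]", 1:3), "sigma")
  for (l in ppmr:::LEVELS) {
    n_u <- length(d$labels[[l]])
    cols <- c(cols, sprintf("b_%s[%d,%d]", l, rep(seq_len(n_u), 3),
                            rep(1:3, each = n_u)))
  }
  draws <- matrix(0, n_draws, length(cols), dimnames = list(NULL, cols))
  draws[, sprintf("beta[%d]", 1:3)] <- matrix(beta, n_draws, 3, byrow = TRUE)
  draws[, "sigma"] <- sigma
  structure(list(draws = draws, design = d, response = "R_bio",
                 preset = mcmc_preset("fast"), prior = "default", seed = 1,
                 diagnostics = tibble::tibble(parameter = character(),
                                              rhat = numeric(), ess = numeric())),
            class = "ppmr_fit")
}

test_that("Bayesian R2 matches its closed form and stays in [0, 1]", {
  # Var(yhat) computed on the standardized design: beta = (0, 1, 0) gives
  # Var(yhat) = 1, so R2 = 1 / (1 + sigma^2)
  f <- fake_fit(beta = c(0, 1, 0), sigma = 1)
  r2 <- bayesian_r2(f)
  expect_equal(r2$median[r2$level_set == "fixed"], 0.5, tolerance = 1e-12)

  # sigma -> 0 limit: perfect fit
  f0 <- fake_fit(beta = c(0, 1, 0), sigma = 1e-9)
  expect_gt(bayesian_r2(f0)$median[1], 1 - 1e-12)

  r2f <- bayesian_r2(fixture_fit())
  expect_true(all(r2f$median >= 0 & r2f$median <= 1))
  expect_true(all(r2f$hpd_lo <= r2f$median & r2f$median <= r2f$hpd_hi))
})

test_that("predictions decompose by level and reject unknown groups", {
  fit <- fixture_fit()
  g <- fit$design$data
  nd <- g[1:3, c("species", "region", "subregion", "bin_lo_log10g")]

  strip <- function(m) { attributes(m) <- list(dim = dim(m)); m }

  # fixed level equals the fixed linear predictor reconstructed by hand
  pf <- predict_ppmr(fit, nd, level = "fixed")
  lx <- nd$bin_lo_log10g + 0.05
  sc <- fit$design$scaler
  Xn <- cbind(1, (lx - sc$mean_x) / sc$sd_x, (lx^2 - sc$mean_x2) / sc$sd_x2)
  beta <- fit$draws[, sprintf("beta[%d]", 1:3)]
  expect_equal(strip(pf), strip(10^(beta %*% t(Xn))), tolerance = 1e-12)

  # subregion and region levels differ exactly by the subregion deviations
  ps <- predict_ppmr(fit, nd, level = "subregion")
  pr <- predict_ppmr(fit, nd, level = "region")
  lab <- paste(g$order[1:3], g$family[1:3], g$species[1:3], sep = "/")
  lab <- paste(lab, g$region[1:3], g$subregion[1:3], sep = "/")
  iu <- match(lab, fit$design$labels$subregion)
  dev <- sapply(seq_len(3), function(j) {
    fit$draws[, sprintf("b_subregion[%d,1]", iu[j])] +
      fit$draws[, sprintf("b_subregion[%d,2]", iu[j])] * Xn[j, 2] +
      fit$draws[, sprintf("b_subregion[%d,3]", iu[j])] * Xn[j, 3]
  })
  expect_equal(strip(log10(ps) - log10(pr)), strip(dev), tolerance = 1e-10)

  ndu <- nd; ndu$subregion <- "nowhere"
  expect_error(predict_ppmr(fit, ndu, level = "subregion"),
               class = "ppmr_unknown_group")
  # extrapolation beyond the observed mass range is flagged
  ndx <- nd[1, ]; ndx$bin_lo_log10g <- 9
  expect_warning(px <- predict_ppmr(fit, ndx, level = "fixed"))
  expect_true(attr(px, "extrapolated"))
})

test_that("a fit with no group-level variance shrinks every level sd", {
  # enough order-level units (6) that the order sd is identified by data
  # rather than by its half-Cauchy prior
  cfg <- sim_config(n_orders = 6, families_per_order = 2, species_per_family = 2,
                    order_effect_sds = c(0, 0, 0), family_effect_sds = c(0, 0, 0),
                    species_effect_sds = c(0, 0, 0), region_effect_sds = c(0, 0, 0),
                    subregion_effect_sds = c(0, 0, 0), seed = 55)
  gs <- simulate_group_table(cfg, sigma_resid = 0.01, seed = 55)
  # shrinkage, not mixing, is the property under test: sds pinned near their
  # boundary make the split-Rhat statistic noisy
  f <- fit_ppmr(gs$groups, "R_bio", preset = "fast", seed = 56, rhat_limit = Inf)
  td <- tidy(f)
  sds <- td[grepl("^sd_", td$term), ]
  expect_true(all(sds$estimate < 0.1))
  # fixed effects recover the truth within their 95% HPD intervals
  fx <- td[td$term %in% c("b0", "b1_mass", "b2_mass2"), ]
  expect_true(all(gs$truth$fixed_coefs >= fx$conf.low &
                    gs$truth$fixed_coefs <= fx$conf.high))
  # with no true group variance, incremental R2 beyond fixed is negligible
  r2 <- bayesian_r2(f)
  expect_true(all(diff(r2$median) < 0.05))
})

test_that("posterior draws are reproducible and invariant to order-preserving relabeling", {
  g <- fixture_groups()
  f1 <- fit_ppmr(g, "R_bio", preset = list(chains = 2, adapt = 300, burn = 100,
                                           sample = 150, thin = 1),
                 seed = 99, rhat_limit = Inf)
  f2 <- fit_ppmr(g, "R_bio", preset = list(chains = 2, adapt = 300, burn = 100,
                                           sample = 150, thin = 1),
                 seed = 99, rhat_limit = Inf)
  expect_identical(f1$draws, f2$draws)

  # monotone renaming of species keeps the design, and hence the draws, identical
  g3 <- g
  g3$species <- paste0(g3$species, "_x")
  f3 <- fit_ppmr(g3, "R_bio", preset = list(chains = 2, adapt = 300, burn = 100,
                                            sample = 150, thin = 1),
                 seed = 99, rhat_limit = Inf)
  expect_identical(unname(f1$draws), unname(f3$draws))
})

test_that("tidy and glance summarise the fit in broom conventions", {
  fit <- fixture_fit()
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "conf.low", "conf.high")
                  %in% names(td)))
  expect_equal(nrow(td), 19L)  # 3 fixed + 15 sds + residual sd
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_groups, nrow(fit$design$data))
  expect_lt(gl$max_rhat, 1.2)
})

test_that("a REML mixed model corroborates the Bayesian variance estimates", {
  # species-only variance: a classical random-intercept fit is an
  # independent route to the same variance decomposition
  cfg <- sim_config(n_orders = 2, families_per_order = 2, species_per_family = 5,
                    order_effect_sds = c(0, 0, 0), family_effect_sds = c(0, 0, 0),
                    species_effect_sds = c(0.5, 0, 0), region_effect_sds = c(0, 0, 0),
                    subregion_effect_sds = c(0, 0, 0), seed = 88)
  gs <- simulate_group_table(cfg, sigma_resid = 0.1, seed = 88)
  g <- gs$groups
  lx <- log10(g$mean_mass_biow_g)
  d <- data.frame(y = log10(g$R_bio), x = as.numeric(scale(lx)),
                  x2 = as.numeric(scale(lx^2)), species = g$species)
  reml <- lme4::lmer(y ~ x + x2 + (1 | species), data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(reml))

  bayes <- fit_ppmr(g, "R_bio", preset = "fast", seed = 89, rhat_limit = Inf)
  td <- tidy(bayes)
  est <- function(term) td$estimate[td$term == term]

  expect_lt(abs(est("sd_species_intercept") - vc$sdcor[1]) / vc$sdcor[1], 0.2)
  expect_lt(abs(est("sigma_resid") - vc$sdcor[2]) / vc$sdcor[2], 0.2)
  # REML fixed effects fall inside the Bayesian credible intervals
  fx <- td[match(c("b0", "b1_mass", "b2_mass2"), td$term), ]
  fe <- unname(lme4::fixef(reml))
  expect_true(all(fe >= fx$conf.low & fe <= fx$conf.high))
})
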