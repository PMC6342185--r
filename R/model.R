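LEVELS <- c("order", "family", "species", "region", "subregion")

#' Build the design for the hierarchical PPMR model
#'
#' Prepares one response (log10 R_bio or log10 R_num) and its predictors from
#' a group table. The predictor is the log10 weighted mean predator body mass
#' of each group, using the weighting matched to the response (specific-prey-
#' mass weights for `R_bio`, prey-count weights for `R_num`). The linear and
#' quadratic terms are each independently centered and scaled to unit sample
#' sd — the quadratic column is the standardized square of the raw log10
#' mass, not the square of the standardized mass. Nested grouping indices are
#' built with child labels made unique within parents, so two subregions with
#' the same name under different regions are distinct units.
#'
#' @param groups A group table from [ppmr_groups()] (or any table in that
#'   schema, e.g. an archived group-level PPMR table).
#' @param response `"R_bio"` or `"R_num"`.
#' @return A list of class `ppmr_design`: `y`, `X` (n x 3 with intercept),
#'   per-level unit indices and labels, the predictor scaler, and the source
#'   table.
#' @export
build_design <- function(groups, response = c("R_bio", "R_num")) {
  response <- match.arg(response)
  r <- groups[[response]]
  if (any(!is.finite(r) | r <= 0)) {
    abort("Response ratios must be positive and finite.", class = "ppmr_invalid_response")
  }
  mass <- if (response == "R_bio") groups$mean_mass_biow_g else groups$mean_mass_numw_g
  lx <- log10(mass)
  if (length(unique(mass)) < 2) {
    abort("Need at least two distinct predator masses.", class = "ppmr_invalid_design")
  }
  scaler <- list(mean_x = mean(lx), sd_x = sd(lx),
                 mean_x2 = mean(lx^2), sd_x2 = sd(lx^2))
  x <- (lx - scaler$mean_x) / scaler$sd_x
  x2 <- (lx^2 - scaler$mean_x2) / scaler$sd_x2

  lab <- list()
  lab$order <- as.character(groups$order)
  lab$family <- paste(lab$order, groups$family, sep = "/")
  lab$species <- paste(lab$family, groups$species, sep = "/")
  lab$region <- paste(lab$species, groups$region, sep = "/")
  lab$subregion <- paste(lab$region, groups$subregion, sep = "/")

  labels <- lapply(lab, function(v) sort(unique(v)))
  idx <- purrr::map2(lab, labels, match)

  structure(list(
    y = log10(r),
    X = cbind(intercept = 1, x = x, x2 = x2),
    idx = idx, labels = labels,
    scaler = scaler, response = response,
    lx = lx, data = groups
  ), class = "ppmr_design")
}

# Map a scaler over log10 masses -> standardized (x, x2)
apply_scaler <- function(scaler, lx) {
  cbind(1, (lx - scaler$mean_x) / scaler$sd_x,
        (lx^2 - scaler$mean_x2) / scaler$sd_x2)
}

#' MCMC presets for the hierarchical model
#'
#' `"paper-mcmc"` reproduces the published chain settings: 3 chains, 1,550
#' iterations with a 50-iteration burn-in and a thinning interval of 3,
#' yielding 1,500 posterior draws. Those settings suit a Hamiltonian
#' sampler; the Gibbs sampler used here needs a much longer warm-up and
#' heavier thinning to mix the variance components, so `"default"` keeps the
#' same 1,500 kept draws but uses 2,000 adaptation + 2,000 burn-in
#' iterations and a thinning interval of 8. `"fast"` is a shorter preset
#' for interactive checks and tests.
#'
#' @param preset A preset name or a list with elements `chains`, `adapt`,
#'   `burn`, `sample` (kept draws per chain), `thin`.
#' @return A validated preset list.
#' @export
mcmc_preset <- function(preset = "default") {
  if (is.list(preset)) {
    stopifnot(all(c("chains", "adapt", "burn", "sample", "thin") %in% names(preset)))
    return(preset)
  }
  switch(preset,
    "default" = list(chains = 3, adapt = 2000, burn = 2000, sample = 500, thin = 8),
    "paper-mcmc" = list(chains = 3, adapt = 50, burn = 0, sample = 500, thin = 3),
    "fast" = list(chains = 2, adapt = 2000, burn = 2000, sample = 400, thin = 10),
    abort(sprintf("Unknown preset '%s'.", preset), class = "ppmr_invalid_config")
  )
}

jags_model_string <- function(resid_df, resid_scale) {
  lvl_terms <- paste(sprintf(
    "      inprod(b_%s[i_%s[i], ], X[i, ])", LEVELS, LEVELS), collapse = " +\n")
  lvl_blocks <- paste(vapply(LEVELS, function(l) sprintf(
    "  for (j in 1:n_%s) { for (k in 1:3) { b_%s[j, k] ~ dnorm(0, prec_%s[k]) } }\n  for (k in 1:3) {\n    sd_%s[k] ~ dt(0, 0.01, 1) T(0,)\n    prec_%s[k] <- pow(sd_%s[k], -2)\n  }",
    l, l, l, l, l, l), character(1)), collapse = "\n")
  sprintf("model {
  for (i in 1:n) {
    mu[i] <- inprod(beta[], X[i, ]) +
%s
    y[i] ~ dnorm(mu[i], tau)
  }
  for (k in 1:3) { beta[k] ~ dnorm(0, 0.3333333) }
%s
  sigma ~ dt(0, %.10g, %.10g) T(0,)
  tau <- pow(sigma, -2)
}", lvl_terms, lvl_blocks, 1 / resid_scale^2, resid_df)
}

#' Fit the Bayesian nested mixed model of log10 PPMR vs predator mass
#'
#' Fits, by Gibbs sampling (JAGS), a linear mixed model of log10 group-level
#' PPMR on standardized linear and quadratic log10 predator body mass with
#' five nested random-effect levels — order, family-in-order,
#' species-in-family, region-in-species, subregion-in-region — each carrying
#' mutually uncorrelated intercept, linear and quadratic deviations. Priors:
#' fixed effects Normal(0, variance 3); each random-effect sd
#' half-Cauchy(0, 10); residual sd half-Student-t (df 3, scale 10 by
#' default, or the nearly-flat literal half-t(0.001, 0.001) with
#' `prior = "literal"`).
#'
#' Convergence is checked with split chains: the fit errors if any
#' parameter's potential scale reduction factor reaches `rhat_limit`
#' (default 1.2).
#'
#' @param groups Group table ([ppmr_groups()] schema).
#' @param response `"R_bio"` or `"R_num"`.
#' @param preset MCMC preset name or list, see [mcmc_preset()].
#' @param prior `"default"` or `"literal"` residual-sd prior.
#' @param seed Integer; fans out deterministically to the chains.
#' @param rhat_limit Reject the fit when max R-hat is at or above this.
#' @param quiet Suppress JAGS progress output.
#' @return An object of class `ppmr_fit`: posterior draws (matrix, one row
#'   per draw), the design, diagnostics (R-hat and effective sample size per
#'   parameter), and fitting metadata. Methods: [tidy()], [glance()],
#'   [predict_ppmr()], [bayesian_r2()], [autoplot()].
#' @export
fit_ppmr <- function(groups, response = c("R_bio", "R_num"), preset = "default",
                     prior = c("default", "literal"), seed = 1L,
                     rhat_limit = 1.2, quiet = TRUE) {
  response <- match.arg(response)
  prior <- match.arg(prior)
  ps <- mcmc_preset(preset)
  design <- build_design(groups, response)

  resid <- if (prior == "literal") c(df = 0.001, scale = 0.001) else c(df = 3, scale = 10)
  mod_str <- jags_model_string(resid[["df"]], resid[["scale"]])

  dat <- list(n = length(design$y), y = design$y, X = design$X)
  for (l in LEVELS) {
    dat[[paste0("i_", l)]] <- design$idx[[l]]
    dat[[paste0("n_", l)]] <- length(design$labels[[l]])
  }

  inits <- lapply(seq_len(ps$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (as.integer(seed) * 97L + ch * 1009L) %% 2147483562L + 1L)
  })

  run <- function() {
    jm <- rjags::jags.model(textConnection(mod_str), data = dat, inits = inits,
                            n.chains = ps$chains, n.adapt = ps$adapt, quiet = quiet)
    if (ps$burn > 0) update(jm, ps$burn, progress.bar = "none")
    rjags::coda.samples(
      jm,
      variable.names = c("beta", "sigma", paste0("sd_", LEVELS), paste0("b_", LEVELS)),
      n.iter = ps$sample * ps$thin, thin = ps$thin, progress.bar = "none")
  }
  samp <- if (quiet) suppressWarnings(run()) else run()

  # diagnostics on the interpretable parameters (fixed effects, sds, sigma)
  keep <- c("sigma", paste0("beta[", 1:3, "]"),
            as.vector(outer(paste0("sd_", LEVELS), 1:3,
                            function(a, b) paste0(a, "[", b, "]"))))
  diag_tbl <- tibble::tibble(parameter = keep,
                             rhat = NA_real_,
                             ess = as.numeric(coda::effectiveSize(samp[, keep])))
  if (ps$chains >= 2) {
    gd <- coda::gelman.diag(samp[, keep], multivariate = FALSE, autoburnin = FALSE)
    diag_tbl$rhat <- gd$psrf[, 1]
    if (max(diag_tbl$rhat, na.rm = TRUE) >= rhat_limit) {
      abort(sprintf("Chains did not converge: max R-hat %.3f (limit %.2f).",
                    max(diag_tbl$rhat, na.rm = TRUE), rhat_limit),
            class = "ppmr_no_convergence",
            diagnostics = diag_tbl)
    }
  }

  structure(list(
    draws = as.matrix(samp),
    design = design,
    response = response,
    preset = ps, prior = prior, seed = seed,
    diagnostics = diag_tbl
  ), class = "ppmr_fit")
}

#' @export
print.ppmr_fit <- function(x, ...) {
  cat(sprintf("Hierarchical PPMR model fit (%s)\n", x$response))
  cat(sprintf("  groups: %d; draws: %d (%d chains)\n",
              length(x$design$y), nrow(x$draws), x$preset$chains))
  if (!all(is.na(x$diagnostics$rhat))) {
    cat(sprintf("  max R-hat: %.3f; min ESS: %.0f\n",
                max(x$diagnostics$rhat, na.rm = TRUE), min(x$diagnostics$ess)))
  }
  print(tidy(x), n = 10)
  invisible(x)
}

# Extract the three S x n_units deviation matrices for one level.
level_draws <- function(fit, level) {
  n_u <- length(fit$design$labels[[level]])
  lapply(1:3, function(k) {
    cols <- sprintf("b_%s[%d,%d]", level, seq_len(n_u), k)
    fit$draws[, cols, drop = FALSE]
  })
}

hpd <- function(x, prob = 0.95) {
  h <- coda::HPDinterval(coda::as.mcmc(as.numeric(x)), prob = prob)
  c(lower = h[1, "lower"], upper = h[1, "upper"])
}

#' @importFrom generics tidy
#' @export
tidy.ppmr_fit <- function(x, conf.level = 0.95, ...) {
  keep <- x$diagnostics$parameter
  nice <- c("sigma_resid", "b0", "b1_mass", "b2_mass2",
            as.vector(outer(paste0("sd_", LEVELS), c("intercept", "linear", "quadratic"),
                            function(a, b) paste0(a, "_", b))))
  purrr::map2_dfr(keep, nice, function(p, nm) {
    v <- x$draws[, p]
    h <- hpd(v, conf.level)
    tibble::tibble(term = nm, estimate = median(v), std.error = sd(v),
                   conf.low = h[["lower"]], conf.high = h[["upper"]])
  })
}

#' @importFrom generics glance
#' @export
glance.ppmr_fit <- function(x, ...) {
  tibble::tibble(
    n_groups = length(x$design$y),
    n_draws = nrow(x$draws),
    n_chains = x$preset$chains,
    max_rhat = if (all(is.na(x$diagnostics$rhat))) NA_real_ else
      max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess),
    sigma = median(x$draws[, "sigma"])
  )
}

# Per-draw fitted values including random effects down to `depth` levels
# (0 = fixed only). Returns an S x n matrix.
fitted_draws <- function(fit, depth) {
  X <- fit$design$X
  beta <- fit$draws[, sprintf("beta[%d]", 1:3)]
  yhat <- beta %*% t(X)   # S x n
  if (depth > 0) {
    for (l in LEVELS[seq_len(depth)]) {
      bd <- level_draws(fit, l)
      ix <- fit$design$idx[[l]]
      yhat <- yhat + bd[[1]][, ix, drop = FALSE] +
        sweep(bd[[2]][, ix, drop = FALSE], 2, X[, 2], `*`) +
        sweep(bd[[3]][, ix, drop = FALSE], 2, X[, 3], `*`)
    }
  }
  yhat
}

row_vars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  (rowSums(m^2) - n * mu^2) / (n - 1)
}

#' Sequential Bayesian R-squared across nesting levels
#'
#' Computes, per posterior draw, the "explained variance"
#' \eqn{R^2 = Var(\hat y) / (Var(\hat y) + \sigma^2)} using fixed effects
#' only, then adding random-effect coefficients level by level down the
#' nesting (order, family, species, region, subregion). The increase from
#' one row to the next measures how much predictive variance that level
#' contributes.
#'
#' @param fit A [fit_ppmr()] object.
#' @param prob Credible-interval probability for the HPD bounds.
#' @return A tibble of class `ppmr_r2` with `level_set` (ordered factor:
#'   `fixed`, `+order`, ..., `+subregion`), `median`, `hpd_lo`, `hpd_hi`;
#'   the per-draw R-squared matrix is attached as attribute `"draws"`.
#' @export
bayesian_r2 <- function(fit, prob = 0.95) {
  sets <- c("fixed", paste0("+", LEVELS))
  sigma2 <- fit$draws[, "sigma"]^2
  r2 <- sapply(0:5, function(d) {
    v <- row_vars(fitted_draws(fit, d))
    v / (v + sigma2)
  })
  colnames(r2) <- sets
  out <- purrr::map_dfr(seq_along(sets), function(j) {
    h <- hpd(r2[, j], prob)
    tibble::tibble(level_set = sets[j], median = median(r2[, j]),
                   hpd_lo = h[["lower"]], hpd_hi = h[["upper"]])
  })
  out$level_set <- factor(out$level_set, levels = sets)
  attr(out, "draws") <- r2
  class(out) <- c("ppmr_r2", class(out))
  out
}

#' Posterior predictions of group-level PPMR on the ratio scale
#'
#' Builds, per posterior draw, the linear predictor for each requested
#' (species, region, subregion, mass bin) cell — fixed effects plus random
#' effects down to the requested `level` — at the bin midpoint on the log10
#' scale (passed through the stored predictor scaler), then back-transforms
#' as `10^value`. No log-normal bias correction is applied, matching the
#' downstream weighting of predicted ratios.
#'
#' @param fit A [fit_ppmr()] object.
#' @param newdata Tibble with columns `species`, `region`, `subregion`,
#'   `bin_lo_log10g` (and, if taxonomy differs from the training table,
#'   `family`/`order`). Columns above the requested level may be omitted.
#' @param level One of `"subregion"`, `"region"`, `"species"`, `"family"`,
#'   `"order"`, `"fixed"` — the deepest random-effect level to include.
#' @return A draws matrix (rows = posterior draws, columns = rows of
#'   `newdata`), with attribute `"extrapolated"` flagging cells whose mass
#'   midpoint lies outside the observed mass range.
#' @export
predict_ppmr <- function(fit, newdata, level = "subregion") {
  level <- match.arg(level, c("fixed", LEVELS))
  depth <- if (level == "fixed") 0L else match(level, LEVELS)
  tax <- training_taxonomy(fit)

  # resolve taxonomy for the nested labels
  nd <- tibble::as_tibble(newdata)
  if (depth >= 1 && !"order" %in% names(nd)) {
    nd <- resolve_taxonomy(nd, tax, depth)
  }
  lx <- nd$bin_lo_log10g + 0.05
  Xn <- apply_scaler(fit$design$scaler, lx)
  beta <- fit$draws[, sprintf("beta[%d]", 1:3)]
  eta <- beta %*% t(Xn)

  if (depth > 0) {
    labs <- nested_labels(nd)
    for (d in seq_len(depth)) {
      l <- LEVELS[d]
      ix <- match(labs[[l]], fit$design$labels[[l]])
      if (anyNA(ix)) {
        abort(sprintf("Unknown %s label(s): %s", l,
                      paste(unique(labs[[l]][is.na(ix)]), collapse = ", ")),
              class = "ppmr_unknown_group")
      }
      bd <- level_draws(fit, l)
      eta <- eta + bd[[1]][, ix, drop = FALSE] +
        sweep(bd[[2]][, ix, drop = FALSE], 2, Xn[, 2], `*`) +
        sweep(bd[[3]][, ix, drop = FALSE], 2, Xn[, 3], `*`)
    }
  }
  out <- 10^eta
  dimnames(out) <- NULL
  extrap <- lx < min(fit$design$lx) | lx > max(fit$design$lx)
  if (any(extrap)) {
    warn(sprintf("%d cell(s) extrapolate beyond the observed mass range.", sum(extrap)))
  }
  attr(out, "extrapolated") <- extrap
  out
}

# species -> family -> order mapping observed in the training data
training_taxonomy <- function(fit) {
  fit$design$data |>
    dplyr::distinct(.data$species, .data$family, .data$order)
}

resolve_taxonomy <- function(nd, tax, depth) {
  if ("species" %in% names(nd)) {
    nd <- nd |> dplyr::left_join(tax, by = "species")
  }
  if (!"order" %in% names(nd) || (depth >= 1 && anyNA(nd$order))) {
    abort("Cannot resolve order/family for some rows; supply taxonomy columns.",
          class = "ppmr_unknown_group")
  }
  nd
}

# Nested (parent-qualified) labels for rows of a prediction frame.
nested_labels <- function(nd) {
  lab <- list()
  lab$order <- as.character(nd$order)
  lab$family <- if ("family" %in% names(nd)) paste(lab$order, nd$family, sep = "/") else NULL
  lab$species <- if (!is.null(lab$family) && "species" %in% names(nd))
    paste(lab$family, nd$species, sep = "/") else NULL
  lab$region <- if (!is.null(lab$species) && "region" %in% names(nd))
    paste(lab$species, nd$region, sep = "/") else NULL
  lab$subregion <- if (!is.null(lab$region) && "subregion" %in% names(nd))
    paste(lab$region, nd$subregion, sep = "/") else NULL
  lab
}
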