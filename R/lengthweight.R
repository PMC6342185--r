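#' Fit a length-weight power law
#'
#' Fits \eqn{mass = a \cdot length^b} by ordinary least squares on the
#' log10-log10 scale, the standard allometric length-weight relationship used
#' to back-calculate undigested body mass from lengths. No back-transform
#' bias correction is applied. If `data` is grouped (e.g. by taxon and life
#' stage), one model is fitted per group.
#'
#' @param data A data frame with a length column and a mass column. Units are
#'   the caller's convention (mm and g for prey, cm and g for predators); the
#'   fitted `coef_a` absorbs the unit choice.
#' @param length,mass Column names (tidy-eval) holding lengths and masses.
#' @param min_n Minimum number of pairs required (default 10).
#' @return A tibble of class `ppmr_lw` with columns `coef_a`, `exponent_b`,
#'   `n_fit` (plus any grouping columns).
#' @examples
#' d <- data.frame(len = seq(10, 100, 10), mas = 0.01 * seq(10, 100, 10)^3)
#' fit_length_weight(d, len, mas, min_n = 5)
#' @export
fit_length_weight <- function(data, length, mass, min_n = 10) {
  len_q <- rlang::enquo(length)
  mas_q <- rlang::enquo(mass)
  fit_one <- function(df, ...) {
    l <- dplyr::pull(df, !!len_q)
    m <- dplyr::pull(df, !!mas_q)
    keep <- !is.na(l) & !is.na(m)
    l <- l[keep]; m <- m[keep]
    n_pairs <- base::length(l)
    if (n_pairs < min_n) {
      abort(sprintf("Need at least %d length-mass pairs, got %d.", min_n, n_pairs),
            class = "ppmr_insufficient_lw_data")
    }
    if (any(l <= 0) || any(m <= 0)) {
      abort("Lengths and masses must be strictly positive.",
            class = "ppmr_invalid_measurement")
    }
    co <- coef(lm(log10(m) ~ log10(l)))
    tibble::tibble(coef_a = 10^co[[1]], exponent_b = co[[2]], n_fit = n_pairs)
  }
  out <- if (dplyr::is_grouped_df(data)) {
    dplyr::ungroup(dplyr::group_modify(data, fit_one))
  } else {
    fit_one(data)
  }
  class(out) <- c("ppmr_lw", class(out))
  out
}

# Evaluate mass = a * L^b; vectorised over lengths.
lw_mass <- function(length, coef_a, exponent_b) coef_a * length^exponent_b
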