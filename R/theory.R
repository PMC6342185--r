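#' Relative trophic level implied by a community PPMR
#'
#' In equilibrium size-spectrum theory the trophic level of a predator,
#' relative to a small reference size class, is set by how many predator-prey
#' "steps" separate the two masses when each step spans one factor of the
#' community-wide mean PPMR:
#' \deqn{\Delta TL = \log_{10}(M_{target}/M_{ref}) / \log_{10}(PPMR).}
#' A larger PPMR packs the same mass range into fewer trophic steps, so the
#' predicted relative trophic level of a large predator falls as PPMR rises
#' (e.g. moving PPMR from 10^3 to 10^4 lowers the relative trophic level of a
#' 10 kg predator over a 10 g baseline by 0.25).
#'
#' @param target_mass Predator body mass (g).
#' @param ref_mass Reference ("small predator") body mass (g); default 10 g.
#' @param ppmr Community-wide mean predator-prey mass ratio (> 1).
#' @return Dimensionless trophic-level offset (vectorised).
#' @examples
#' relative_trophic_level(1e4, 10, 1e3) # 1
#' relative_trophic_level(1e4, 10, 1e3) - relative_trophic_level(1e4, 10, 1e4)
#' @export
relative_trophic_level <- function(target_mass, ref_mass = 10, ppmr) {
  if (any(ppmr <= 1)) {
    abort("`ppmr` must exceed 1.", class = "ppmr_invalid_ppmr")
  }
  if (any(target_mass <= 0) || any(ref_mass <= 0)) {
    abort("Masses must be positive.", class = "ppmr_invalid_measurement")
  }
  log10(target_mass / ref_mass) / log10(ppmr)
}

#' Convert realized PPMR to an approximate preferred PPMR
#'
#' The mode of a predator's log-normal feeding kernel (its "preferred" PPMR)
#' cannot be read directly from stomach contents, but simulation work with
#' dynamic size-spectrum models suggests it is roughly 60% of the mean
#' realized PPMR. This helper applies that offset.
#'
#' @param realized_ppmr Realized (diet-based) mean PPMR (> 0).
#' @param factor Preferred/realized ratio; default 0.60.
#' @return Approximate preferred PPMR.
#' @examples
#' preferred_from_realized(1000) # 600
#' @export
preferred_from_realized <- function(realized_ppmr, factor = 0.60) {
  if (any(realized_ppmr <= 0)) {
    abort("`realized_ppmr` must be positive.", class = "ppmr_invalid_measurement")
  }
  factor * realized_ppmr
}
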