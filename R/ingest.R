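#' Read and write raw diet-record CSVs
#'
#' The raw format has one row per prey record with the predator's columns
#' repeated: `predator_id, species, family, order, region, subregion,
#' pred_mass_g, pred_length_cm, prey_taxon, life_stage, prey_count,
#' prey_total_mass_g, prey_ind_mass_g, prey_ind_length_mm, pct_intact,
#' prey_group`. The two `prey_ind_*` columns hold semicolon-joined lists of
#' per-individual measurements and are parsed to list-columns `ind_mass_g`
#' and `ind_length_mm`; empty fields become empty numeric vectors.
#'
#' @param path Path to a CSV file (for `write_diet_csv`, the destination).
#' @param diet A diet tibble with `ind_mass_g`/`ind_length_mm` list-columns.
#' @return `read_diet_csv` returns a tibble with list-columns;
#'   `write_diet_csv` returns `path` invisibly.
#' @export
read_diet_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           prey_ind_mass_g = readr::col_character(),
                           prey_ind_length_mm = readr::col_character(),
                           .default = readr::col_guess()
                         ))
  raw |>
    dplyr::mutate(
      ind_mass_g = parse_semicolon_list(.data$prey_ind_mass_g),
      ind_length_mm = parse_semicolon_list(.data$prey_ind_length_mm)
    ) |>
    dplyr::select(-"prey_ind_mass_g", -"prey_ind_length_mm")
}

#' @rdname read_diet_csv
#' @export
write_diet_csv <- function(diet, path) {
  diet |>
    dplyr::mutate(
      prey_ind_mass_g = join_semicolon_list(.data$ind_mass_g),
      prey_ind_length_mm = join_semicolon_list(.data$ind_length_mm)
    ) |>
    dplyr::select(-"ind_mass_g", -"ind_length_mm") |>
    readr::write_csv(path)
  invisible(path)
}

parse_semicolon_list <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
  lapply(out, function(v) as.numeric(v[nzchar(v)]))
}

join_semicolon_list <- function(x) {
  vapply(x, function(v) paste(format(v, trim = TRUE, digits = 15), collapse = ";"),
         character(1))
}

# Per-list summaries used to aggregate equal- or listed-mass prey rows without
# materialising every individual.
list_lengths <- function(x) lengths(x)
list_sums <- function(x) vapply(x, function(v) if (length(v)) sum(v) else NA_real_, numeric(1))
list_invsums <- function(x) vapply(x, function(v) if (length(v)) sum(1 / v) else NA_real_, numeric(1))

#' Reconstruct undigested mass of digested fish and crab prey from lengths
#'
#' Heavily digested prey (`pct_intact` below the threshold) are normally
#' excluded, but fish and crab prey that still have length measurements can
#' have their undigested mass back-calculated from taxon- and life-stage-
#' specific length-weight relationships fitted to largely intact prey.
#' Reconstructed rows gain `mass_reconstructed = TRUE` and are retained by
#' [filter_digestion()]. Rows already flagged are never re-reconstructed.
#'
#' @param diet A diet tibble (see [read_diet_csv()]).
#' @param prey_lw Length-weight table with columns `prey_taxon`, `life_stage`
#'   (`"any"` matches every stage), `coef_a` (g mm^-b), `exponent_b`.
#' @param digestion_threshold Percent-intact threshold (default 75).
#' @return The diet tibble with reconstructed `ind_mass_g` where possible.
#' @export
reconstruct_digested_mass <- function(diet, prey_lw, digestion_threshold = 75) {
  diet <- ensure_flags(diet)
  lw <- normalise_prey_lw(prey_lw)
  cand <- !diet$mass_reconstructed &
    diet$prey_group %in% c("fish", "crab") &
    diet$pct_intact < digestion_threshold &
    lengths(diet$ind_length_mm) > 0
  if (!any(cand)) return(diet)

  key <- match_lw(diet$prey_taxon, diet$life_stage, lw)
  doable <- cand & !is.na(key)
  if (any(doable)) {
    idx <- which(doable)
    a <- lw$coef_a[key[idx]]
    b <- lw$exponent_b[key[idx]]
    diet$ind_mass_g[idx] <- purrr::pmap(
      list(diet$ind_length_mm[idx], a, b),
      function(L, a, b) lw_mass(L, a, b)
    )
    diet$mass_reconstructed[idx] <- TRUE
  }
  diet
}

# Match (taxon, stage) against an LW table, falling back to stage "any".
match_lw <- function(taxon, stage, lw) {
  exact <- match(paste(taxon, stage), paste(lw$prey_taxon, lw$life_stage))
  anyst <- match(paste(taxon, "any"), paste(lw$prey_taxon, lw$life_stage))
  dplyr::coalesce(exact, anyst)
}

normalise_prey_lw <- function(prey_lw) {
  stopifnot(all(c("prey_taxon", "coef_a", "exponent_b") %in% names(prey_lw)))
  if (!"life_stage" %in% names(prey_lw)) prey_lw$life_stage <- "any"
  prey_lw
}

ensure_flags <- function(diet) {
  if (!"mass_reconstructed" %in% names(diet)) diet$mass_reconstructed <- FALSE
  if (!"count_imputed" %in% names(diet)) diet$count_imputed <- FALSE
  if (!"pred_mass_estimated" %in% names(diet)) diet$pred_mass_estimated <- FALSE
  if (!"prey_row_id" %in% names(diet)) {
    diet$prey_row_id <- paste0(diet$predator_id, "#", seq_len(nrow(diet)))
  }
  diet
}

#' Drop prey records that are largely digested and not reconstructable
#'
#' Removes prey rows with `pct_intact` strictly below the threshold unless
#' their mass was reconstructed from length. The boundary value itself (75 by
#' default) is retained. Dropped rows are logged with reason
#' `digested_no_length`.
#'
#' @inheritParams reconstruct_digested_mass
#' @return The filtered diet tibble, with the drop log in attribute
#'   `"drop_log"`.
#' @export
filter_digestion <- function(diet, digestion_threshold = 75) {
  diet <- ensure_flags(diet)
  log <- drop_log(diet)
  drop <- !is.na(diet$pct_intact) &
    diet$pct_intact < digestion_threshold & !diet$mass_reconstructed
  log <- add_drop(log, diet$prey_row_id[drop], "digested_no_length")
  out <- diet[!drop, , drop = FALSE]
  attr(out, "drop_log") <- log
  out
}

#' Pooled mean prey body masses for mass-only records
#'
#' Records holding only a total mass (no count, no individual measurements)
#' need a mean individual body mass to be resolved. Following the convention
#' of pooling all records that report both a total mass and a count, the mean
#' for a key is the summed total mass divided by the summed count. Means are
#' computed at three scopes — (taxon, life stage, region), (taxon, life
#' stage), (taxon) — and [impute_prey_mass()] falls back through them in that
#' order.
#'
#' @param diet A diet tibble.
#' @return A list of three tibbles (`by_region`, `by_stage`, `by_taxon`) each
#'   with a `mean_mass_g` column.
#' @export
mean_mass_table <- function(diet) {
  src <- diet |>
    dplyr::filter(!is.na(.data$prey_count), !is.na(.data$prey_total_mass_g),
                  lengths(.data$ind_mass_g) == 0)
  list(
    by_region = src |>
      dplyr::group_by(.data$prey_taxon, .data$life_stage, .data$region) |>
      dplyr::summarise(mean_mass_g = sum(.data$prey_total_mass_g) / sum(.data$prey_count),
                       .groups = "drop"),
    by_stage = src |>
      dplyr::group_by(.data$prey_taxon, .data$life_stage) |>
      dplyr::summarise(mean_mass_g = sum(.data$prey_total_mass_g) / sum(.data$prey_count),
                       .groups = "drop"),
    by_taxon = src |>
      dplyr::group_by(.data$prey_taxon) |>
      dplyr::summarise(mean_mass_g = sum(.data$prey_total_mass_g) / sum(.data$prey_count),
                       .groups = "drop")
  )
}

#' Resolve per-individual prey masses for every record
#'
#' Fills the per-row aggregation columns `n_ind`, `sum_mass_g` and
#' `sum_invmass` (sum of reciprocal individual masses) from whichever
#' information each record carries, in order of preference:
#' \itemize{
#'   \item individual masses listed: used as-is;
#'   \item count + total mass: each of the `count` individuals gets mass
#'     `total/count` (mass is conserved exactly);
#'   \item total mass only: the count is imputed as
#'     `round(total / mean_mass)` (minimum 1) using the pooled mean-mass
#'     ladder from [mean_mass_table()], each individual gets the table mean;
#'     when the rounded count floors at 1 the single individual keeps the
#'     recorded total mass. Flagged `count_imputed`;
#'   \item count only: each individual gets the table mean mass.
#' }
#' Records resolvable by none of these are dropped with reason
#' `unresolvable_mass`.
#'
#' @param diet A diet tibble.
#' @param mm Optional mean-mass ladder from [mean_mass_table()]; computed
#'   from `diet` itself when omitted.
#' @return The diet tibble with resolution columns, unresolvable rows
#'   removed and logged.
#' @export
impute_prey_mass <- function(diet, mm = NULL) {
  diet <- ensure_flags(diet)
  log <- drop_log(diet)
  mm <- mm %||% mean_mass_table(diet)

  has_list <- lengths(diet$ind_mass_g) > 0
  has_count <- !is.na(diet$prey_count)
  has_total <- !is.na(diet$prey_total_mass_g)

  n_ind <- rep(NA_real_, nrow(diet))
  sum_mass <- rep(NA_real_, nrow(diet))
  sum_inv <- rep(NA_real_, nrow(diet))

  # listed individual masses
  n_ind[has_list] <- list_lengths(diet$ind_mass_g[has_list])
  sum_mass[has_list] <- list_sums(diet$ind_mass_g[has_list])
  sum_inv[has_list] <- list_invsums(diet$ind_mass_g[has_list])

  # case A: count + total -> equal shares, mass conserved
  ca <- !has_list & has_count & has_total
  n_ind[ca] <- diet$prey_count[ca]
  sum_mass[ca] <- diet$prey_total_mass_g[ca]
  sum_inv[ca] <- diet$prey_count[ca]^2 / diet$prey_total_mass_g[ca]

  # cases needing the mean-mass ladder
  need_mm <- !has_list & !ca & (has_total | has_count)
  if (any(need_mm)) {
    mbar <- lookup_mean_mass(diet$prey_taxon[need_mm], diet$life_stage[need_mm],
                             diet$region[need_mm], mm)
    idx <- which(need_mm)
    cb <- has_total[idx] & !is.na(mbar)         # case B: total only
    if (any(cb)) {
      i <- idx[cb]
      tot <- diet$prey_total_mass_g[i]
      cnt <- pmax(1, round(tot / mbar[cb]))
      one <- round(tot / mbar[cb]) < 1
      m_each <- ifelse(one, tot, mbar[cb])
      n_ind[i] <- cnt
      sum_mass[i] <- cnt * m_each
      sum_inv[i] <- cnt / m_each
      diet$count_imputed[i] <- TRUE
    }
    cc <- !has_total[idx] & has_count[idx] & !is.na(mbar)  # count only
    if (any(cc)) {
      i <- idx[cc]
      n_ind[i] <- diet$prey_count[i]
      sum_mass[i] <- diet$prey_count[i] * mbar[cc]
      sum_inv[i] <- diet$prey_count[i] / mbar[cc]
      diet$count_imputed[i] <- TRUE
    }
  }

  bad <- is.na(n_ind)
  log <- add_drop(log, diet$prey_row_id[bad], "unresolvable_mass")
  diet$n_ind <- n_ind
  diet$sum_mass_g <- sum_mass
  diet$sum_invmass <- sum_inv
  out <- diet[!bad, , drop = FALSE]
  attr(out, "drop_log") <- log
  out
}

lookup_mean_mass <- function(taxon, stage, region, mm) {
  k1 <- paste(taxon, stage, region)
  k2 <- paste(taxon, stage)
  m1 <- mm$by_region$mean_mass_g[match(k1, paste(mm$by_region$prey_taxon,
                                                 mm$by_region$life_stage,
                                                 mm$by_region$region))]
  m2 <- mm$by_stage$mean_mass_g[match(k2, paste(mm$by_stage$prey_taxon,
                                                mm$by_stage$life_stage))]
  m3 <- mm$by_taxon$mean_mass_g[match(taxon, mm$by_taxon$prey_taxon)]
  dplyr::coalesce(m1, m2, m3)
}

#' Estimate missing predator body masses from lengths
#'
#' Predators recorded with a length but no mass get their body mass from a
#' species-specific length-weight relationship (lengths in cm, masses in g).
#' Predators with neither a usable mass nor a model are removed and logged
#' with reason `predator_no_mass`. Predators that already carry a body mass
#' are untouched.
#'
#' @param diet A diet tibble.
#' @param pred_lw Length-weight table with columns `species`, `coef_a`
#'   (g cm^-b), `exponent_b`.
#' @return The diet tibble with `pred_mass_g` filled where possible.
#' @export
estimate_predator_mass <- function(diet, pred_lw = NULL) {
  diet <- ensure_flags(diet)
  log <- drop_log(diet)
  need <- is.na(diet$pred_mass_g)
  if (any(need) && !is.null(pred_lw)) {
    k <- match(diet$species, pred_lw$species)
    can <- need & !is.na(diet$pred_length_cm) & !is.na(k)
    if (any(diet$pred_length_cm[can] <= 0)) {
      abort("Predator lengths must be positive.", class = "ppmr_invalid_measurement")
    }
    diet$pred_mass_g[can] <- lw_mass(diet$pred_length_cm[can],
                                     pred_lw$coef_a[k[can]],
                                     pred_lw$exponent_b[k[can]])
    diet$pred_mass_estimated[can] <- TRUE
  }
  bad <- is.na(diet$pred_mass_g)
  log <- add_drop(log, unique(diet$predator_id[bad]), "predator_no_mass")
  out <- diet[!bad, , drop = FALSE]
  attr(out, "drop_log") <- log
  out
}

#' Preprocess raw diet records end to end
#'
#' Runs the full preprocessing chain: length-based mass reconstruction for
#' digested fish/crab prey, digestion filtering, prey-mass resolution and
#' imputation, and predator body-mass estimation. Predators left with zero
#' prey are removed (they carry no PPMR information) and logged. The chain is
#' idempotent: provenance flags prevent any step from being re-applied.
#'
#' @param diet A raw diet tibble from [read_diet_csv()] or
#'   [simulate_diet_data()].
#' @param prey_lw,pred_lw Optional length-weight tables (see
#'   [reconstruct_digested_mass()] and [estimate_predator_mass()]). When
#'   `prey_lw` is omitted it is fitted from the data's largely intact
#'   (`pct_intact >= digestion_threshold`) fish and crab prey that carry both
#'   individual lengths and masses, per (taxon, life stage).
#' @param digestion_threshold Percent-intact exclusion threshold; prey
#'   strictly below it are excluded unless reconstructed (default 75).
#' @param lw_min_n Minimum pairs for an internal length-weight fit.
#' @return A cleaned tibble, one row per retained prey record, with
#'   resolution columns `n_ind`, `sum_mass_g`, `sum_invmass` and provenance
#'   flags; the drop log (one row per excluded record, with reason) is in
#'   attribute `"drop_log"` (see [drop_log()]).
#' @export
preprocess_diet <- function(diet, prey_lw = NULL, pred_lw = NULL,
                            digestion_threshold = 75, lw_min_n = 10) {
  diet <- ensure_flags(diet)
  if (is.null(prey_lw)) {
    prey_lw <- fit_prey_lw_from_data(diet, digestion_threshold, lw_min_n)
  }
  out <- diet |>
    reconstruct_digested_mass(prey_lw, digestion_threshold) |>
    filter_digestion(digestion_threshold) |>
    impute_prey_mass() |>
    estimate_predator_mass(pred_lw)

  log <- drop_log(out)
  kept_pred <- unique(out$predator_id)
  all_pred <- unique(diet$predator_id)
  logged <- unique(log$record_id[log$reason == "predator_no_mass"])
  empty <- setdiff(all_pred, union(kept_pred, logged))
  log <- add_drop(log, empty, "predator_no_prey")
  attr(out, "drop_log") <- log
  out
}

# Fit prey LW models from largely intact prey carrying both lengths and masses.
fit_prey_lw_from_data <- function(diet, digestion_threshold, lw_min_n) {
  src <- diet |>
    dplyr::filter(.data$prey_group %in% c("fish", "crab"),
                  is.na(.data$pct_intact) | .data$pct_intact >= digestion_threshold,
                  lengths(.data$ind_mass_g) > 0,
                  lengths(.data$ind_length_mm) == lengths(.data$ind_mass_g)) |>
    dplyr::select("prey_taxon", "life_stage", "ind_mass_g", "ind_length_mm") |>
    tidyr::unnest(c("ind_mass_g", "ind_length_mm"))
  if (nrow(src) == 0) {
    return(tibble::tibble(prey_taxon = character(), life_stage = character(),
                          coef_a = numeric(), exponent_b = numeric()))
  }
  src |>
    dplyr::group_by(.data$prey_taxon, .data$life_stage) |>
    dplyr::filter(dplyr::n() >= lw_min_n) |>
    fit_length_weight(ind_length_mm, ind_mass_g, min_n = lw_min_n)
}
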