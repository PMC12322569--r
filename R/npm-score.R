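#' Banded points for one nutrient quantity
#'
#' The NPM awards points by comparing a per-100 g quantity against an ordered
#' list of cutpoints: the points attached to the highest cutpoint *strictly*
#' exceeded are awarded, and a value equal to a cutpoint stays in the lower
#' band ("more than X" bands). This is the single place the boundary
#' convention is encoded.
#'
#' @param value Numeric vector of non-negative quantities.
#' @param cutpoints Strictly increasing numeric vector of band cutpoints.
#' @param points Points awarded per band; defaults to `1, 2, ...` (the dense
#'   A-point and fibre/protein bands). Sparse awards such as the
#'   fruit/vegetable/nut `1, 2, 5` bands are passed explicitly.
#' @return Integer vector of points, same length as `value`.
#' @export
#' @examples
#' band_points(c(0, 4.5, 4.6, 100), c(4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45))
#' band_points(75, c(40, 60, 80), points = c(1, 2, 5))
band_points <- function(value, cutpoints, points = seq_along(cutpoints)) {
  stopifnot(length(points) == length(cutpoints), all(diff(cutpoints) > 0))
  if (any(value < 0, na.rm = TRUE)) {
    abort("band_points() requires non-negative values.",
          class = "nutrioverlap_invalid_profile")
  }
  n_exceeded <- rowSums(outer(value, cutpoints, `>`))
  as.integer(c(0, points)[n_exceeded + 1L])
}

# Resolve the per-100 g columns a model variant scores, applying the
# salt<->sodium conversion when only the other basis is present and
# converting a kcal-only energy column to kJ.
resolve_a_fields <- function(profiles, spec) {
  n <- nrow(profiles)
  get <- function(col) if (col %in% names(profiles)) profiles[[col]] else rep(NA_real_, n)

  energy <- get("energy_kj")
  kcal <- get("energy_kcal")
  fill <- is.na(energy) & !is.na(kcal)
  if (any(fill)) {
    energy[fill] <- kcal[fill] * KJ_PER_KCAL
    inform(sprintf("Converted energy from kcal to kJ for %d profile(s).", sum(fill)))
  }

  sugars <- get(spec$sugar_field)

  sodium_mg <- get("sodium_mg")
  salt_g <- get("salt_g")
  if (spec$sodium_field == "sodium_mg") {
    sodium <- sodium_mg
    fill <- is.na(sodium) & !is.na(salt_g)
    if (any(fill)) {
      sodium[fill] <- salt_g[fill] / SODIUM_MG_TO_SALT_G
      inform(sprintf("Converted salt to sodium for %d profile(s).", sum(fill)))
    }
  } else {
    sodium <- salt_g
    fill <- is.na(sodium) & !is.na(sodium_mg)
    if (any(fill)) {
      sodium[fill] <- sodium_mg[fill] * SODIUM_MG_TO_SALT_G
      inform(sprintf("Converted sodium to salt for %d profile(s).", sum(fill)))
    }
  }

  tibble::tibble(
    energy_kj = energy,
    sat_fat_g = get("sat_fat_g"),
    sugars = sugars,
    sodium = sodium
  )
}

# rows whose required A-fields are missing, with a reason string
a_field_exceptions <- function(fields, spec) {
  reason <- character(nrow(fields))
  add <- function(reason, miss, what) {
    ifelse(miss, ifelse(nzchar(reason), paste0(reason, "; missing ", what),
                        paste0("missing ", what)), reason)
  }
  reason <- add(reason, is.na(fields$energy_kj), "energy")
  reason <- add(reason, is.na(fields$sat_fat_g), "saturated fat")
  reason <- add(reason, is.na(fields$sugars), spec$sugar_field)
  reason <- add(reason, is.na(fields$sodium), spec$sodium_field)
  reason
}

#' Score the NPM "A" components
#'
#' Awards banded points for energy (kJ), saturated fat, sugars and
#' sodium/salt per 100 g. Which sugar and sodium column is read depends on
#' the model variant (`spec$sugar_field`, `spec$sodium_field`); salt and
#' sodium are interconverted (salt g = sodium mg x 2.5 / 1000) when only the
#' other is supplied, and a kcal-only energy column is converted at
#' 4.184 kJ/kcal.
#'
#' @param profiles Data frame of per-100 g nutrient profiles (one row per
#'   food); see [read_nutrients()] for the column schema.
#' @param spec An [`npm_model_spec`][load_model_spec].
#' @return A tibble with per-nutrient points `a_energy`, `a_sat_fat`,
#'   `a_sugars`, `a_sodium` (each 0-10) and their sum `a_total` (0-40).
#' @export
score_a_points <- function(profiles, spec) {
  profiles <- as_profile_frame(profiles)
  fields <- resolve_a_fields(profiles, spec)
  reason <- a_field_exceptions(fields, spec)
  if (any(nzchar(reason))) {
    bad <- which(nzchar(reason))
    abort(
      c(sprintf("%d profile(s) lack fields required by %s.", length(bad), spec$name),
        head(sprintf("row %d: %s", bad, reason[bad]), 10)),
      class = "nutrioverlap_missing_nutrient"
    )
  }
  res <- tibble::tibble(
    a_energy = band_points(fields$energy_kj, spec$a_bands$energy_kj),
    a_sat_fat = band_points(fields$sat_fat_g, spec$a_bands$sat_fat_g),
    a_sugars = band_points(fields$sugars, spec$a_bands$sugars_g),
    a_sodium = band_points(fields$sodium, spec$a_bands$sodium)
  )
  res$a_total <- res$a_energy + res$a_sat_fat + res$a_sugars + res$a_sodium
  res
}

#' Score the NPM "C" components
#'
#' Awards banded points for fruit/vegetable/nut content (% by weight), fibre
#' and protein per 100 g. Fibre is scored against the band list matching each
#' profile's declared `fibre_basis` (NSP or AOAC); a basis the model does not
#' define is an error, since NSP and AOAC fibre are not interconvertible.
#'
#' @inheritParams score_a_points
#' @return A tibble with `c_fvn`, `c_fibre`, `c_protein` and the raw sum
#'   `c_total_raw` (before the protein-capping rule, which lives in
#'   [npm_score()]).
#' @export
score_c_points <- function(profiles, spec) {
  profiles <- as_profile_frame(profiles)
  fvn <- profiles$fvn_pct
  if (any(is.na(fvn) | fvn < 0 | fvn > 100)) {
    abort("fvn_pct must be present and within [0, 100] for every profile.",
          class = "nutrioverlap_invalid_profile")
  }
  basis <- as.character(profiles$fibre_basis)
  unknown <- setdiff(unique(basis), names(spec$c_bands$fibre))
  if (length(unknown) > 0) {
    abort(sprintf("Model %s defines no fibre bands for basis: %s.",
                  spec$name, paste(unknown, collapse = ", ")),
          class = "nutrioverlap_fibre_basis")
  }
  c_fibre <- integer(nrow(profiles))
  for (b in unique(basis)) {
    idx <- basis == b
    c_fibre[idx] <- band_points(profiles$fibre_g[idx], spec$c_bands$fibre[[b]])
  }
  res <- tibble::tibble(
    c_fvn = band_points(fvn, spec$c_bands$fvn_pct$cutpoints,
                        spec$c_bands$fvn_pct$points),
    c_fibre = c_fibre,
    c_protein = band_points(profiles$protein_g, spec$c_bands$protein_g)
  )
  res$c_total_raw <- res$c_fvn + res$c_fibre + res$c_protein
  res
}

#' NPM score and HFSS classification
#'
#' Computes the full three-step score: A points, C points, and the
#' subtraction `score = A - C` with the protein-capping rule: when
#' `a_total >= 11` (model-configurable) protein points are not counted
#' unless the fruit/vegetable/nut component scored the maximum 5 points.
#' A food is HFSS when its score reaches the food cutoff (4 under the
#' 2004/05 model); a drink when it reaches the drink cutoff (1).
#'
#' @inheritParams score_a_points
#' @param is_drink Logical, length 1 or `nrow(profiles)`: which cutoff
#'   applies per row.
#' @return A tibble (one row per profile) with per-component points, the
#'   totals, `protein_suppressed`, `score` and `is_hfss`.
#' @export
#' @examples
#' spec <- load_model_spec("NPM2004")
#' sugary <- list(
#'   energy_kj = 1200, sat_fat_g = 2, total_sugars_g = 30, sodium_mg = 100,
#'   fibre_g = 0.5, fibre_basis = "AOAC", protein_g = 2, fvn_pct = 0
#' )
#' npm_score(sugary, is_drink = FALSE, spec = spec)
npm_score <- function(profiles, is_drink, spec) {
  profiles <- as_profile_frame(profiles)
  is_drink <- rep_len(as.logical(is_drink), nrow(profiles))
  validate_profiles(profiles, spec)
  a <- score_a_points(profiles, spec)
  c_ <- score_c_points(profiles, spec)

  suppressed <- a$a_total >= spec$protein_cap$a_threshold &
    c_$c_fvn < spec$protein_cap$exemption_fvn_points
  c_counted <- c_$c_fvn + c_$c_fibre + ifelse(suppressed, 0L, c_$c_protein)
  score <- a$a_total - c_counted
  cutoff <- ifelse(is_drink, spec$cutoffs$drink, spec$cutoffs$food)

  dplyr::bind_cols(a, c_, tibble::tibble(
    protein_suppressed = suppressed,
    c_total_counted = as.integer(c_counted),
    score = as.integer(score),
    is_drink = is_drink,
    is_hfss = score >= cutoff
  ))
}

as_profile_frame <- function(profiles) {
  if (!is.data.frame(profiles)) profiles <- tibble::as_tibble(profiles)
  if (nrow(profiles) == 0) {
    abort("No nutrient profiles supplied.", class = "nutrioverlap_invalid_profile")
  }
  profiles
}

validate_profiles <- function(profiles, spec) {
  nutrient_cols <- intersect(
    c("energy_kj", "energy_kcal", "sat_fat_g", "total_sugars_g", "free_sugars_g",
      "sodium_mg", "salt_g", "fibre_g", "protein_g"),
    names(profiles)
  )
  for (col in nutrient_cols) {
    if (any(profiles[[col]] < 0, na.rm = TRUE)) {
      abort(sprintf("Negative values in '%s'.", col),
            class = "nutrioverlap_invalid_profile")
    }
  }
  needed <- c("fibre_g", "fibre_basis", "protein_g", "fvn_pct")
  missing <- setdiff(needed, names(profiles))
  if (length(missing) > 0) {
    abort(sprintf("Profiles lack required columns: %s.",
                  paste(missing, collapse = ", ")),
          class = "nutrioverlap_invalid_profile")
  }
  invisible(profiles)
}

#' Score every food in a catalog
#'
#' Batch wrapper over [npm_score()]: joins each catalog entry to its
#' nutrient profile by `item_code`, applies the drink cutoff to entries
#' flagged `is_drink`, and returns one row per entry in catalog order.
#' Entries whose profile is missing a field the model requires (for example
#' free sugars under the 2018 variant) are not scored and not silently
#' dropped: they come back with `NA` score and a reason in the `exception`
#' column, and are summarised in the `"exceptions"` attribute.
#'
#' @param catalog Food catalog, as from [read_catalog()].
#' @param nutrients Nutrient table, as from [read_nutrients()].
#' @param spec An [`npm_model_spec`][load_model_spec].
#' @return A tibble keyed by `item_code` with the [npm_score()] columns plus
#'   `exception` (`NA` for scored rows); attribute `exceptions` holds the
#'   offending subset.
#' @export
classify_catalog <- function(catalog, nutrients, spec) {
  if (nrow(catalog) == 0) {
    out <- tibble::tibble(item_code = character(), score = integer(),
                          is_hfss = logical(), exception = character())
    attr(out, "exceptions") <- out[0, c("item_code", "exception")]
    return(out)
  }
  missing_profile <- setdiff(catalog$item_code, nutrients$item_code)
  if (length(missing_profile) > 0) {
    abort(c(sprintf("%d catalog item(s) have no nutrient profile.",
                    length(missing_profile)),
            head(missing_profile, 10)),
          class = "nutrioverlap_missing_nutrient")
  }
  profiles <- dplyr::left_join(
    catalog[, c("item_code", "is_drink")], nutrients, by = "item_code"
  )

  fields <- resolve_a_fields(profiles, spec)
  reason <- a_field_exceptions(fields, spec)
  scorable <- !nzchar(reason)

  out <- tibble::tibble(item_code = profiles$item_code)
  res_cols <- c("a_energy", "a_sat_fat", "a_sugars", "a_sodium", "a_total",
                "c_fvn", "c_fibre", "c_protein", "c_total_raw",
                "protein_suppressed", "c_total_counted", "score", "is_drink",
                "is_hfss")
  for (col in res_cols) out[[col]] <- rep(NA, nrow(out))
  if (any(scorable)) {
    scored <- npm_score(profiles[scorable, , drop = FALSE],
                        profiles$is_drink[scorable], spec)
    for (col in res_cols) out[[col]][scorable] <- scored[[col]]
  }
  out$exception <- ifelse(scorable, NA_character_, reason)
  exceptions <- out[!scorable, c("item_code", "exception")]
  if (nrow(exceptions) > 0) {
    warn(sprintf("%d item(s) could not be scored under %s; see attr(, 'exceptions').",
                 nrow(exceptions), spec$name))
  }
  attr(out, "exceptions") <- exceptions
  out
}
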