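#' Read the four diet-survey tables
#'
#' Plain headered CSV/TSV readers with row-level validation; every problem
#' is reported with its 1-based data-row number and reading aborts if any
#' row is invalid. Column schemas:
#'
#' * **catalog** — `item_code`, `item_name`, `main_group_code`,
#'   `main_group_name`, `subgroup_code`, `subgroup_name`, and logical flags
#'   `is_drink`, `is_toddler_food`, `is_home_prepared`,
#'   `contains_purchased_pastry_or_breadcrumbs_or_margarine`,
#'   `is_alcohol_containing`, `is_supplement`.
#' * **nutrients** — `item_code` plus per-100 g columns `energy_kj`
#'   (and/or `energy_kcal`), `sat_fat_g`, `total_sugars_g`,
#'   `free_sugars_g` (optional), `sodium_mg` and/or `salt_g`, `fibre_g`,
#'   `fibre_basis` (`NSP`/`AOAC`), `protein_g`, `fvn_pct`.
#' * **diary** — `participant_id`, `diary_day`, `item_code`, `grams`,
#'   optional `kcal` (imputed from grams when absent).
#' * **participants** — `participant_id`, `age_years` (>= 1.5), `sex`
#'   (`male`/`female`), `survey_weight` (> 0), optional `wave`.
#'
#' @param path File path.
#' @param delim Field delimiter (default comma; use `"\t"` for TSV).
#' @return A validated tibble.
#' @name readers
NULL

check_file_exists <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File '%s' does not exist.", path),
          class = "nutrioverlap_missing_file")
  }
  invisible(path)
}

read_table_checked <- function(path, delim, col_types) {
  check_file_exists(path)
  x <- readr::read_delim(path, delim = delim, col_types = col_types,
                         progress = FALSE)
  missing <- setdiff(names(col_types$cols), names(x))
  # optional columns are marked by col_skip sentinel handling upstream
  if (length(missing) > 0) {
    abort(sprintf("'%s' lacks required columns: %s.", path,
                  paste(missing, collapse = ", ")),
          class = "nutrioverlap_invalid_input")
  }
  tibble::as_tibble(x)
}

catalog_flag_cols <- c(
  "is_drink", "is_toddler_food", "is_home_prepared",
  "contains_purchased_pastry_or_breadcrumbs_or_margarine",
  "is_alcohol_containing", "is_supplement"
)

#' @rdname readers
#' @export
read_catalog <- function(path, delim = ",") {
  ct <- readr::cols(
    item_code = readr::col_character(),
    item_name = readr::col_character(),
    main_group_code = readr::col_character(),
    main_group_name = readr::col_character(),
    subgroup_code = readr::col_character(),
    subgroup_name = readr::col_character()
  )
  for (f in catalog_flag_cols) ct$cols[[f]] <- readr::col_logical()
  x <- read_table_checked(path, delim, ct)
  validate_catalog(x)
}

validate_catalog <- function(x) {
  problems <- dplyr::bind_rows(
    tibble::tibble(line = which(duplicated(x$item_code)),
                   message = "duplicate item_code"),
    tibble::tibble(line = which(is.na(x$item_code) | !nzchar(x$item_code)),
                   message = "empty item_code"),
    tibble::tibble(line = which(is.na(x$main_group_code) | !nzchar(x$main_group_code)),
                   message = "empty main_group_code"),
    tibble::tibble(line = which(is.na(x$subgroup_code) | !nzchar(x$subgroup_code)),
                   message = "empty subgroup_code"),
    purrr::map_dfr(catalog_flag_cols, function(f) {
      tibble::tibble(line = which(is.na(x[[f]])),
                     message = sprintf("flag '%s' must be TRUE/FALSE", f))
    })
  )
  if (nrow(problems) > 0) {
    abort_problems("Invalid catalog.", problems, "nutrioverlap_invalid_input")
  }
  x
}

#' @rdname readers
#' @export
read_nutrients <- function(path, delim = ",") {
  check_file_exists(path)
  x <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    item_code = readr::col_character(),
    fibre_basis = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  required <- c("item_code", "sat_fat_g", "total_sugars_g", "fibre_g",
                "fibre_basis", "protein_g", "fvn_pct")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(sprintf("'%s' lacks required columns: %s.", path,
                  paste(missing, collapse = ", ")),
          class = "nutrioverlap_invalid_input")
  }
  if (!any(c("energy_kj", "energy_kcal") %in% names(x))) {
    abort(sprintf("'%s' needs 'energy_kj' or 'energy_kcal'.", path),
          class = "nutrioverlap_invalid_input")
  }
  if (!any(c("sodium_mg", "salt_g") %in% names(x))) {
    abort(sprintf("'%s' needs 'sodium_mg' or 'salt_g'.", path),
          class = "nutrioverlap_invalid_input")
  }
  validate_nutrients(tibble::as_tibble(x))
}

validate_nutrients <- function(x) {
  nutrient_cols <- intersect(
    c("energy_kj", "energy_kcal", "sat_fat_g", "total_sugars_g",
      "free_sugars_g", "sodium_mg", "salt_g", "fibre_g", "protein_g"),
    names(x)
  )
  problems <- dplyr::bind_rows(
    tibble::tibble(line = which(duplicated(x$item_code)),
                   message = "duplicate item_code"),
    purrr::map_dfr(nutrient_cols, function(f) {
      tibble::tibble(line = which(!is.na(x[[f]]) & x[[f]] < 0),
                     message = sprintf("negative '%s'", f))
    }),
    tibble::tibble(line = which(is.na(x$fvn_pct) | x$fvn_pct < 0 | x$fvn_pct > 100),
                   message = "fvn_pct must be in [0, 100]"),
    tibble::tibble(line = which(!x$fibre_basis %in% c("NSP", "AOAC")),
                   message = "fibre_basis must be NSP or AOAC"),
    tibble::tibble(
      line = which(
        (is.na(x$sodium_mg %||% rep(NA_real_, nrow(x)))) &
          (is.na(x$salt_g %||% rep(NA_real_, nrow(x))))
      ),
      message = "needs sodium_mg or salt_g"
    )
  )
  if (nrow(problems) > 0) {
    abort_problems("Invalid nutrient table.", problems, "nutrioverlap_invalid_input")
  }
  x
}

#' @rdname readers
#' @export
read_diary <- function(path, delim = ",") {
  check_file_exists(path)
  x <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    participant_id = readr::col_character(),
    diary_day = readr::col_integer(),
    item_code = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  required <- c("participant_id", "diary_day", "item_code", "grams")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(sprintf("'%s' lacks required columns: %s.", path,
                  paste(missing, collapse = ", ")),
          class = "nutrioverlap_invalid_input")
  }
  if (!"kcal" %in% names(x)) x$kcal <- NA_real_
  validate_diary(tibble::as_tibble(x))
}

validate_diary <- function(x) {
  problems <- dplyr::bind_rows(
    tibble::tibble(line = which(is.na(x$grams) | x$grams <= 0),
                   message = "grams must be > 0"),
    tibble::tibble(line = which(!is.na(x$kcal) & x$kcal < 0),
                   message = "kcal must be >= 0"),
    tibble::tibble(line = which(is.na(x$diary_day) | x$diary_day < 1),
                   message = "diary_day must be a positive integer")
  )
  if (nrow(problems) > 0) {
    abort_problems("Invalid diary.", problems, "nutrioverlap_invalid_input")
  }
  x
}

#' @rdname readers
#' @export
read_participants <- function(path, delim = ",") {
  check_file_exists(path)
  x <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    participant_id = readr::col_character(),
    sex = readr::col_character(),
    wave = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  required <- c("participant_id", "age_years", "sex", "survey_weight")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(sprintf("'%s' lacks required columns: %s.", path,
                  paste(missing, collapse = ", ")),
          class = "nutrioverlap_invalid_input")
  }
  validate_participants(tibble::as_tibble(x))
}

validate_participants <- function(x) {
  problems <- dplyr::bind_rows(
    tibble::tibble(line = which(duplicated(x$participant_id)),
                   message = "duplicate participant_id"),
    tibble::tibble(line = which(is.na(x$age_years) | x$age_years < 1.5),
                   message = "age_years must be >= 1.5"),
    tibble::tibble(line = which(!x$sex %in% c("male", "female")),
                   message = "sex must be 'male' or 'female'"),
    tibble::tibble(line = which(is.na(x$survey_weight) | x$survey_weight <= 0),
                   message = "survey_weight must be > 0")
  )
  if (nrow(problems) > 0) {
    abort_problems("Invalid participant table.", problems,
                   "nutrioverlap_invalid_input")
  }
  x
}

#' Analysis age bands
#'
#' The five reporting bands, read as whole completed years and encoded
#' closed-open on integer boundaries: \[1.5, 4), \[4, 11), \[11, 19),
#' \[19, 65), \[65, Inf).
#'
#' @return Character vector of the five band labels in order.
#' @export
age_bands <- function() c("1.5-3", "4-10", "11-18", "19-64", "65+")

#' @describeIn age_bands Map ages in years to their band label.
#' @param age_years Numeric vector of ages, all >= 1.5.
#' @export
#' @examples
#' assign_age_band(c(2, 10.9, 65))
assign_age_band <- function(age_years) {
  if (any(is.na(age_years) | age_years < 1.5)) {
    abort("Ages must be >= 1.5 years.", class = "nutrioverlap_invalid_input")
  }
  cut(age_years, breaks = c(1.5, 4, 11, 19, 65, Inf), labels = age_bands(),
      right = FALSE, include.lowest = TRUE)
}

#' Join diary, catalog, nutrients and participants into an event stream
#'
#' Produces one enriched row per diary row — repeat consumptions stay
#' repeated, which is what weights the food-level analysis by consumption
#' frequency. Event energy (`kcal`) is imputed as
#' `grams * energy_kcal_per_100g / 100` when the diary leaves it blank; when
#' both are recorded and disagree by more than 0.5 kcal the recorded value
#' wins and the event is flagged (`kcal_flagged`) with a warning, since such
#' disagreements occur in real survey data and should not halt an analysis.
#' Unresolved item or participant codes are listed exhaustively and abort.
#'
#' @param catalog,nutrients,diary,participants Tibbles as returned by the
#'   [readers].
#' @return A tibble with one row per diary row: diary columns, `kcal`
#'   (complete), `kcal_flagged`, catalog group columns and flags, and
#'   participant `age_years`, `age_band`, `sex`, `survey_weight`.
#' @export
build_event_stream <- function(catalog, nutrients, diary, participants) {
  bad_items <- unique(diary$item_code[!diary$item_code %in% catalog$item_code])
  bad_nutr <- unique(diary$item_code[!diary$item_code %in% nutrients$item_code])
  bad_parts <- unique(
    diary$participant_id[!diary$participant_id %in% participants$participant_id]
  )
  if (length(bad_items) + length(bad_nutr) + length(bad_parts) > 0) {
    abort(
      c("Unresolved foreign keys in diary.",
        if (length(bad_items)) sprintf("item codes not in catalog: %s",
                                       paste(bad_items, collapse = ", ")),
        if (length(bad_nutr)) sprintf("item codes not in nutrient table: %s",
                                      paste(bad_nutr, collapse = ", ")),
        if (length(bad_parts)) sprintf("participants not in participant table: %s",
                                       paste(bad_parts, collapse = ", "))),
      class = "nutrioverlap_unresolved_keys"
    )
  }
  if (!"kcal" %in% names(diary)) diary$kcal <- NA_real_

  energy_kcal_100 <- nutrients$energy_kcal %||%
    (nutrients$energy_kj / KJ_PER_KCAL)
  energy_tab <- tibble::tibble(item_code = nutrients$item_code,
                               energy_kcal_per_100g = energy_kcal_100)

  events <- diary |>
    dplyr::left_join(
      catalog[, c("item_code", "main_group_code", "main_group_name",
                  "subgroup_code", "subgroup_name", "is_drink")],
      by = "item_code"
    ) |>
    dplyr::left_join(energy_tab, by = "item_code") |>
    dplyr::left_join(
      participants[, c("participant_id", "age_years", "sex", "survey_weight")],
      by = "participant_id"
    )

  expected <- events$grams * events$energy_kcal_per_100g / 100
  impute <- is.na(events$kcal)
  events$kcal[impute] <- expected[impute]
  events$kcal_flagged <- !impute & !is.na(expected) &
    abs(events$kcal - expected) > 0.5
  if (any(events$kcal_flagged)) {
    warn(sprintf(
      "%d event(s) have recorded kcal inconsistent with grams x energy density (> 0.5 kcal); recorded kcal kept.",
      sum(events$kcal_flagged)
    ))
  }
  events$age_band <- assign_age_band(events$age_years)
  events
}
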