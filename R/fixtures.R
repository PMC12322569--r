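# tiny hand-readable datasets with worked expected outputs, for docs/tests

fixture_catalog_row <- function(item_code, main = "MG01", sub = "SG001",
                                is_drink = FALSE, toddler = FALSE,
                                home = FALSE, pastry = FALSE) {
  tibble::tibble(
    item_code = item_code,
    item_name = paste("Fixture", item_code),
    main_group_code = main,
    main_group_name = paste("Group", main),
    subgroup_code = sub,
    subgroup_name = paste("Subgroup", sub),
    is_drink = is_drink,
    is_toddler_food = toddler,
    is_home_prepared = home,
    contains_purchased_pastry_or_breadcrumbs_or_margarine = pastry,
    is_alcohol_containing = FALSE,
    is_supplement = FALSE
  )
}

fixture_profile_row <- function(item_code, energy_kj = 0, sat_fat_g = 0,
                                total_sugars_g = 0, sodium_mg = 0,
                                fibre_g = 0, protein_g = 0, fvn_pct = 0) {
  tibble::tibble(
    item_code = item_code,
    energy_kj = energy_kj,
    energy_kcal = energy_kj / KJ_PER_KCAL,
    sat_fat_g = sat_fat_g,
    total_sugars_g = total_sugars_g,
    free_sugars_g = total_sugars_g,
    sodium_mg = sodium_mg,
    salt_g = sodium_mg * SODIUM_MG_TO_SALT_G,
    fibre_g = fibre_g,
    fibre_basis = "AOAC",
    protein_g = protein_g,
    fvn_pct = fvn_pct
  )
}

fixture_registry <- function() {
  list(
    # one event in each overlap category; count-basis partition 25/25/25/25
    four_corners = function() {
      catalog <- dplyr::bind_rows(
        fixture_catalog_row("F001"), fixture_catalog_row("F002"),
        fixture_catalog_row("F003", main = "MG02", sub = "SG002"),
        fixture_catalog_row("F004", main = "MG02", sub = "SG002")
      )
      nutrients <- dplyr::bind_rows(
        # 800 kJ = 2 A points everywhere; 50 g sugars adds 10 for the HFSS pair
        fixture_profile_row("F001", energy_kj = 800, total_sugars_g = 50),
        fixture_profile_row("F002", energy_kj = 800, total_sugars_g = 50),
        fixture_profile_row("F003", energy_kj = 800),      # score 2: not HFSS
        fixture_profile_row("F004", energy_kj = 800)       # score 2: not HFSS
      )
      nova_rules <- validate_nova_rules(tibble::tibble(
        level = "item",
        code = c("F001", "F002", "F003", "F004"),
        nova_group = c(4L, 1L, 4L, 1L)   # F001 both, F002 HFSS only, ...
      ))
      diary <- tibble::tibble(
        participant_id = "P1", diary_day = 1L,
        item_code = c("F001", "F002", "F003", "F004"),
        grams = 100, kcal = NA_real_
      )
      participants <- tibble::tibble(
        participant_id = "P1", age_years = 30, sex = "female",
        survey_weight = 1, wave = "W01"
      )
      list(
        catalog = catalog, nutrients = nutrients, diary = diary,
        participants = participants, nova_rules = nova_rules,
        expected = list(count_partition = c(
          pct_hfss_only = 25, pct_upf_only = 25, pct_both = 25, pct_neither = 25
        ))
      )
    },

    # a drink whose score lands exactly on the drink cutoff of 1
    drink_threshold = function() {
      catalog <- fixture_catalog_row("D001", is_drink = TRUE)
      nutrients <- fixture_profile_row("D001", energy_kj = 336)  # > 335: 1 A point
      nova_rules <- validate_nova_rules(tibble::tibble(
        level = "item", code = "D001", nova_group = 3L
      ))
      list(
        catalog = catalog, nutrients = nutrients,
        diary = tibble::tibble(participant_id = "P1", diary_day = 1L,
                               item_code = "D001", grams = 250, kcal = NA_real_),
        participants = tibble::tibble(participant_id = "P1", age_years = 8,
                                      sex = "male", survey_weight = 1,
                                      wave = "W01"),
        nova_rules = nova_rules,
        expected = list(score = 1L, is_hfss = TRUE)
      )
    },

    # home-prepared dish with purchased pastry: override beats the
    # main-group rule (which says minimally processed)
    pastry_override = function() {
      catalog <- fixture_catalog_row("H001", home = TRUE, pastry = TRUE)
      nutrients <- fixture_profile_row("H001", energy_kj = 800, protein_g = 5)
      nova_rules <- validate_nova_rules(tibble::tibble(
        level = "main_group", code = "MG01", nova_group = 1L
      ))
      list(
        catalog = catalog, nutrients = nutrients,
        diary = tibble::tibble(participant_id = "P1", diary_day = 1L,
                               item_code = "H001", grams = 150, kcal = NA_real_),
        participants = tibble::tibble(participant_id = "P1", age_years = 40,
                                      sex = "female", survey_weight = 1,
                                      wave = "W01"),
        nova_rules = nova_rules,
        expected = list(nova_group = 4L, is_upf = TRUE,
                        resolution_level = "override")
      )
    }
  )
}

#' Bundled worked micro-fixtures
#'
#' Three hand-readable datasets, each small enough to verify on paper:
#' `"four_corners"` (four events, one per overlap category),
#' `"drink_threshold"` (a beverage scoring exactly 1, hence HFSS under the
#' drink cutoff) and `"pastry_override"` (a home-prepared dish with
#' purchased pastry, ultra-processed by override despite a minimally
#' processed main-group rule).
#'
#' @param name Fixture name.
#' @return A list with `catalog`, `nutrients`, `diary`, `participants`,
#'   `nova_rules` and `expected` (the worked expected outputs).
#' @export
#' @examples
#' fx <- make_fixture("four_corners")
#' fx$expected$count_partition
make_fixture <- function(name) {
  registry <- fixture_registry()
  if (!name %in% names(registry)) {
    abort(c(sprintf("Unknown fixture '%s'.", name),
            sprintf("Available: %s.", paste(names(registry), collapse = ", "))),
          class = "nutrioverlap_unknown_fixture")
  }
  registry[[name]]()
}
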