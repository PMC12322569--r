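#' Read a Nova rule table
#'
#' Nova groups are assigned hierarchically: a rule can cover a whole main
#' food group, a subgroup, or an individual item. The table is a CSV with
#' columns `level` (one of `main_group`, `subgroup`, `item`), `code` (the
#' group/subgroup/item code the rule covers) and `nova_group` (1-4).
#'
#' The package ships no reconstruction of any survey's full item coding;
#' rule tables are input data supplied by the analyst (the synthetic
#' generator emits one for its own catalog).
#'
#' @param path CSV file path.
#' @param delim Field delimiter (default comma).
#' @return A tibble of class `nova_rule_table`.
#' @export
read_nova_rules <- function(path, delim = ",") {
  rules <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    level = readr::col_character(),
    code = readr::col_character(),
    nova_group = readr::col_integer()
  ), progress = FALSE)
  validate_nova_rules(rules)
}

validate_nova_rules <- function(rules) {
  required <- c("level", "code", "nova_group")
  missing <- setdiff(required, names(rules))
  if (length(missing) > 0) {
    abort(sprintf("Nova rule table lacks columns: %s.", paste(missing, collapse = ", ")),
          class = "nutrioverlap_invalid_rules")
  }
  problems <- dplyr::bind_rows(
    tibble::tibble(
      line = which(!rules$level %in% c("main_group", "subgroup", "item")),
      message = "level must be main_group, subgroup or item"
    ),
    tibble::tibble(
      line = which(is.na(rules$nova_group) | !rules$nova_group %in% 1:4),
      message = "nova_group must be 1, 2, 3 or 4"
    ),
    tibble::tibble(
      line = which(duplicated(rules[, c("level", "code")])),
      message = "duplicate rule for this (level, code)"
    )
  )
  if (nrow(problems) > 0) {
    abort_problems("Invalid Nova rule table.", problems, "nutrioverlap_invalid_rules")
  }
  rules <- tibble::as_tibble(rules)
  rules$nova_group <- as.integer(rules$nova_group)
  class(rules) <- c("nova_rule_table", class(rules))
  rules
}

# Override predicates, evaluated in fixed order before any table lookup:
#   1. toddler food                             -> Nova 4
#   2. home-prepared containing purchased/retailed/frozen pastry,
#      breadcrumbs or margarine                 -> Nova 4
#   3. home-prepared from unprocessed or minimally processed ingredients
#      (i.e. without those components)          -> Nova 1
nova_overrides <- function(catalog) {
  pastry <- catalog$contains_purchased_pastry_or_breadcrumbs_or_margarine
  dplyr::case_when(
    catalog$is_toddler_food ~ "toddler_food",
    catalog$is_home_prepared & pastry ~ "home_prepared_with_purchased_pastry",
    catalog$is_home_prepared ~ "home_prepared_minimally_processed",
    TRUE ~ NA_character_
  )
}

override_nova_group <- c(
  toddler_food = 4L,
  home_prepared_with_purchased_pastry = 4L,
  home_prepared_minimally_processed = 1L
)

# most specific applicable source per entry, without erroring on gaps
resolve_nova <- function(catalog, rules) {
  lookup <- function(level, codes) {
    tab <- rules[rules$level == level, ]
    tab$nova_group[match(codes, tab$code)]
  }
  override <- nova_overrides(catalog)
  by_item <- lookup("item", catalog$item_code)
  by_subgroup <- lookup("subgroup", catalog$subgroup_code)
  by_main <- lookup("main_group", catalog$main_group_code)

  level <- dplyr::case_when(
    !is.na(override) ~ "override",
    !is.na(by_item) ~ "item",
    !is.na(by_subgroup) ~ "subgroup",
    !is.na(by_main) ~ "main_group",
    TRUE ~ NA_character_
  )
  nova <- dplyr::case_when(
    level == "override" ~ unname(override_nova_group[override]),
    level == "item" ~ by_item,
    level == "subgroup" ~ by_subgroup,
    level == "main_group" ~ by_main,
    TRUE ~ NA_integer_
  )
  rule_id <- dplyr::case_when(
    level == "override" ~ paste0("override:", override),
    level == "item" ~ paste0("item:", catalog$item_code),
    level == "subgroup" ~ paste0("subgroup:", catalog$subgroup_code),
    level == "main_group" ~ paste0("main_group:", catalog$main_group_code),
    TRUE ~ NA_character_
  )
  tibble::tibble(
    item_code = catalog$item_code,
    nova_group = unname(nova),
    resolution_level = level,
    rule_id = rule_id
  )
}

#' Assign Nova groups to a catalog
#'
#' Resolution precedence per entry: override predicates (toddler food;
#' home-prepared dishes, with the purchased pastry/breadcrumbs/margarine
#' escalation) first, then the most specific table rule — item, then
#' subgroup, then main food group. An entry no rule covers is an error
#' listing the uncovered items: defaulting silently would bias every overlap
#' statistic downstream.
#'
#' @param catalog Food catalog, as from [read_catalog()].
#' @param rules A [`nova_rule_table`][read_nova_rules].
#' @return A tibble with `item_code`, `nova_group`, `resolution_level`
#'   (`override`/`item`/`subgroup`/`main_group`), `rule_id` and `is_upf`
#'   (`nova_group == 4`).
#' @export
assign_nova <- function(catalog, rules) {
  res <- resolve_nova(catalog, rules)
  uncovered <- res$item_code[is.na(res$nova_group)]
  if (length(uncovered) > 0) {
    abort(
      c(sprintf("%d catalog item(s) are not covered by any Nova rule.",
                length(uncovered)),
        head(uncovered, 10),
        "Add item/subgroup/main_group rules before running the analysis."),
      class = "nutrioverlap_unclassified",
      uncovered = uncovered
    )
  }
  res$is_upf <- res$nova_group == 4L
  res
}

#' Exclude alcohol-containing products and supplements
#'
#' Dietary supplements sit outside the Nova system and alcohol-containing
#' products are conventionally excluded from this analysis; both are dropped
#' before classification, with counts by reason.
#'
#' @param catalog Food catalog, as from [read_catalog()].
#' @return A list: `catalog` (entries retained) and `report` (a tibble of
#'   `reason` in `alcohol`/`supplement` and `n` removed; an item flagged for
#'   both counts once, as alcohol).
#' @export
apply_exclusions <- function(catalog) {
  alcohol <- catalog$is_alcohol_containing
  supplement <- catalog$is_supplement & !alcohol
  list(
    catalog = catalog[!(alcohol | supplement), , drop = FALSE],
    report = tibble::tibble(
      reason = c("alcohol", "supplement"),
      n = c(sum(alcohol), sum(supplement))
    )
  )
}

#' Check that every catalog entry is covered by a Nova rule
#'
#' Reporting companion to [assign_nova()]: instead of erroring, returns the
#' resolution for every entry, with the uncovered subset in the
#' `"uncovered"` attribute. The analysis pipeline refuses to run while any
#' item is uncovered.
#'
#' @inheritParams assign_nova
#' @return A tibble as from [resolve_nova] with `covered` flag; attribute
#'   `uncovered` holds the uncovered item codes (character, possibly empty).
#' @export
validate_rule_coverage <- function(catalog, rules) {
  res <- resolve_nova(catalog, rules)
  res$covered <- !is.na(res$nova_group)
  attr(res, "uncovered") <- res$item_code[!res$covered]
  res
}
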