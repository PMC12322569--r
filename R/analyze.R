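#' Run the full HFSS x UPF overlap analysis
#'
#' End-to-end pipeline: exclude alcohol-containing products and supplements,
#' verify Nova rule coverage (refusing to run while any retained item is
#' uncovered), score every item with the chosen NPM variant (aborting if any
#' item cannot be scored), assign Nova groups, build the enriched event
#' stream, and compute on each requested basis the food-level partition,
#' survey-weighted person-level estimates, optional age-band x sex subgroup
#' tables, and the top contributing main food groups per category.
#'
#' @param catalog,nutrients,diary,participants The four input tables (see
#'   [readers]).
#' @param model NPM variant name or an [`npm_model_spec`][load_model_spec].
#' @param nova_rules A [`nova_rule_table`][read_nova_rules].
#' @param basis Bases to analyse (default all three).
#' @param subgroups Compute age-band x sex subgroup estimates (default TRUE).
#' @param k Rows per top-contributor table (default 10).
#' @param conf Confidence level for person-level intervals.
#' @return A list of class `overlap_analysis`: `partitions` (one row per
#'   basis), `person_level`, `subgroups` (or NULL), `contributors` (keyed by
#'   category and basis), `events` (the enriched stream), `scores`,
#'   `nova`, `exclusions`, `model`.
#' @export
analyze_diet <- function(catalog, nutrients, diary, participants,
                         model = "NPM2004", nova_rules,
                         basis = bases(), subgroups = TRUE, k = 10,
                         conf = 0.95) {
  basis <- match.arg(basis, bases(), several.ok = TRUE)
  spec <- if (inherits(model, "npm_model_spec")) model else load_model_spec(model)

  excl <- apply_exclusions(catalog)
  catalog <- excl$catalog
  diary <- diary[diary$item_code %in% catalog$item_code, , drop = FALSE]
  if (nrow(diary) == 0) {
    abort("No diary events remain after exclusions.",
          class = "nutrioverlap_invalid_input")
  }

  coverage <- validate_rule_coverage(catalog, nova_rules)
  uncovered <- attr(coverage, "uncovered")
  if (length(uncovered) > 0) {
    abort(c(sprintf("%d item(s) lack a Nova rule; analysis refused.",
                    length(uncovered)),
            head(uncovered, 10)),
          class = "nutrioverlap_unclassified", uncovered = uncovered)
  }

  scores <- classify_catalog(catalog, nutrients, spec)
  if (nrow(attr(scores, "exceptions")) > 0) {
    abort(c("Some items could not be scored; analysis refused.",
            head(attr(scores, "exceptions")$item_code, 10)),
          class = "nutrioverlap_missing_nutrient",
          exceptions = attr(scores, "exceptions"))
  }
  nova <- assign_nova(catalog, nova_rules)

  events <- build_event_stream(catalog, nutrients, diary, participants)
  flags <- dplyr::left_join(
    scores[, c("item_code", "is_hfss")],
    nova[, c("item_code", "is_upf")],
    by = "item_code"
  )
  events <- dplyr::left_join(events, flags, by = "item_code")
  events$category <- categorize(events$is_hfss, events$is_upf)

  partitions <- purrr::map_dfr(basis, function(b) food_level_partition(events, b))
  person_level <- purrr::map_dfr(
    basis, function(b) person_level_estimates(events, participants, b, conf)
  )
  sub <- NULL
  if (isTRUE(subgroups)) {
    sub <- purrr::map_dfr(
      basis, function(b) subgroup_analysis(events, participants, b, conf = conf)
    )
  }
  contributors <- purrr::map_dfr(basis, function(b) {
    purrr::map_dfr(category_levels(), function(cl) {
      tab <- top_contributors(events, cl, b, k = k)
      if (nrow(tab) == 0) return(tab[0, ])
      dplyr::bind_cols(tibble::tibble(category = cl, basis = b), tab)
    })
  })

  structure(
    list(partitions = partitions, person_level = person_level,
         subgroups = sub, contributors = contributors, events = events,
         scores = scores, nova = nova, exclusions = excl$report,
         model = spec$name),
    class = "overlap_analysis"
  )
}

#' @export
print.overlap_analysis <- function(x, ...) {
  cat(sprintf("<overlap_analysis> model %s, %d events, %d participants\n",
              x$model, nrow(x$events), length(unique(x$events$participant_id))))
  cat("Food-level partition (% of basis mass):\n")
  print(as.data.frame(x$partitions), digits = 3)
  invisible(x)
}
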