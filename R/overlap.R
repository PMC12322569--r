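#' Overlap category labels
#'
#' The two binary classifications partition foods into four categories.
#'
#' @return Character vector `c("HFSS_only", "UPF_only", "BOTH", "NEITHER")`.
#' @export
category_levels <- function() c("HFSS_only", "UPF_only", "BOTH", "NEITHER")

#' @describeIn category_levels Map the two flags to a category factor.
#' @param is_hfss,is_upf Logical vectors (recycled to common length).
#' @export
#' @examples
#' categorize(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
categorize <- function(is_hfss, is_upf) {
  n <- max(length(is_hfss), length(is_upf))
  is_hfss <- rep_len(is_hfss, n)
  is_upf <- rep_len(is_upf, n)
  lab <- dplyr::case_when(
    is_hfss & is_upf ~ "BOTH",
    is_hfss & !is_upf ~ "HFSS_only",
    !is_hfss & is_upf ~ "UPF_only",
    TRUE ~ "NEITHER"
  )
  factor(lab, levels = category_levels())
}

#' Bases on which percentages are computed
#' @return `c("count", "energy_kcal", "weight_g")`.
#' @export
bases <- function() c("count", "energy_kcal", "weight_g")

event_mass <- function(events, basis) {
  switch(basis,
    count = rep(1, nrow(events)),
    energy_kcal = events$kcal,
    weight_g = events$grams,
    abort(sprintf("Unknown basis '%s'.", basis), class = "nutrioverlap_invalid_input")
  )
}

ensure_category <- function(events) {
  if (!"category" %in% names(events)) {
    if (!all(c("is_hfss", "is_upf") %in% names(events))) {
      abort("Events need either a 'category' column or 'is_hfss' and 'is_upf'.",
            class = "nutrioverlap_invalid_input")
    }
    events$category <- categorize(events$is_hfss, events$is_upf)
  }
  events
}

new_partition <- function(basis, shares) {
  # shares: named numeric over the four category levels, summing to 100
  both <- shares[["BOTH"]]
  all_hfss <- shares[["HFSS_only"]] + both
  all_upf <- shares[["UPF_only"]] + both
  tibble::tibble(
    basis = basis,
    pct_hfss_only = shares[["HFSS_only"]],
    pct_upf_only = shares[["UPF_only"]],
    pct_both = both,
    pct_neither = shares[["NEITHER"]],
    pct_all_hfss = all_hfss,
    pct_all_upf = all_upf,
    pct_upf_also_hfss = if (all_upf > 0) 100 * both / all_upf else NA_real_
  )
}

#' Food-level overlap partition
#'
#' Shares of total basis mass (event count, energy in kcal, or food weight
#' in grams) falling in each of the four categories, over all consumption
#' events with repeats counted every time they occur. No survey weights are
#' applied at food level: events are weighted purely by occurrence.
#'
#' @param events Enriched event stream carrying `category` (or `is_hfss` and
#'   `is_upf`), plus `kcal`/`grams` for the non-count bases.
#' @param basis One of [bases()].
#' @return A one-row tibble: `basis`, the four category percentages
#'   (summing to 100), the `pct_all_hfss`/`pct_all_upf` marginals, and
#'   `pct_upf_also_hfss` (= 100 * both / all UPF, `NA` when nothing is UPF).
#' @export
food_level_partition <- function(events, basis = "count") {
  basis <- match.arg(basis, bases())
  if (nrow(events) == 0) {
    abort("Empty event stream.", class = "nutrioverlap_invalid_input")
  }
  events <- ensure_category(events)
  mass <- event_mass(events, basis)
  total <- sum(mass)
  if (!is.finite(total) || total <= 0) {
    abort(sprintf("Total %s mass must be positive.", basis),
          class = "nutrioverlap_invalid_input")
  }
  by_cat <- tapply(mass, events$category, sum, default = 0)
  new_partition(basis, 100 * by_cat[category_levels()] / total)
}

#' Partition identities from printed marginal percentages
#'
#' Completes a four-category partition from its three published marginals:
#' `pct_neither = 100 - (pct_all_hfss + pct_all_upf - pct_both)`
#' (inclusion-exclusion) and
#' `pct_upf_also_hfss = 100 * pct_both / pct_all_upf`. Useful for desk
#' checks of published Venn figures, where only the marginals and the
#' overlap are printed.
#'
#' @param pct_all_hfss,pct_all_upf,pct_both Percentages in \[0, 100\] with
#'   `pct_both <= min(pct_all_hfss, pct_all_upf)`.
#' @param basis Label carried through to the output.
#' @return A one-row tibble in the [food_level_partition()] layout.
#' @export
#' @examples
#' partition_from_marginals(33.4, 36.2, 20.1, basis = "count")
partition_from_marginals <- function(pct_all_hfss, pct_all_upf, pct_both,
                                     basis = "count") {
  stopifnot(pct_both <= min(pct_all_hfss, pct_all_upf) + 1e-9,
            pct_all_hfss >= 0, pct_all_upf >= 0, pct_both >= 0)
  shares <- c(
    HFSS_only = pct_all_hfss - pct_both,
    UPF_only = pct_all_upf - pct_both,
    BOTH = pct_both,
    NEITHER = 100 - (pct_all_hfss + pct_all_upf - pct_both)
  )
  new_partition(basis, shares)
}

#' Weighted mean with a two-sided normal confidence interval
#'
#' Survey-weighted (Hajek ratio) mean with its Taylor-linearised variance,
#' `sum(w_i^2 (x_i - m)^2) / (sum w_i)^2`, and normal quantiles. No
#' clustering or finite-population correction is applied.
#'
#' @param x Numeric values (one per participant).
#' @param w Positive weights, same length.
#' @param conf Confidence level (default 0.95).
#' @return A one-row tibble: `point`, `ci_low`, `ci_high`, `n`.
#' @export
weighted_mean_ci <- function(x, w, conf = 0.95) {
  stopifnot(length(x) == length(w), length(x) >= 1, all(w > 0))
  m <- sum(w * x) / sum(w)
  se <- sqrt(sum(w^2 * (x - m)^2)) / sum(w)
  z <- qnorm(1 - (1 - conf) / 2)
  tibble::tibble(point = m, ci_low = m - z * se, ci_high = m + z * se,
                 n = length(x))
}

person_measure_order <- c("neither", "all_upf", "upf_only", "all_hfss",
                          "hfss_only", "both", "upf_also_hfss")

# per-participant percentages of their own basis mass, diary days pooled
person_shares <- function(events, basis) {
  events <- ensure_category(events)
  mass <- event_mass(events, basis)
  wide <- tibble::tibble(
    participant_id = events$participant_id,
    category = events$category,
    mass = mass
  ) |>
    dplyr::count(.data$participant_id, .data$category, wt = .data$mass,
                 name = "mass") |>
    tidyr::pivot_wider(names_from = "category", values_from = "mass",
                       values_fill = 0, names_expand = TRUE)
  total <- wide$HFSS_only + wide$UPF_only + wide$BOTH + wide$NEITHER
  zero <- total <= 0
  if (any(zero)) {
    warn(sprintf("%d participant(s) with zero %s mass excluded.", sum(zero), basis))
    wide <- wide[!zero, , drop = FALSE]
    total <- total[!zero]
  }
  per <- tibble::tibble(
    participant_id = wide$participant_id,
    hfss_only = 100 * wide$HFSS_only / total,
    upf_only = 100 * wide$UPF_only / total,
    both = 100 * wide$BOTH / total,
    neither = 100 * wide$NEITHER / total
  )
  per$all_hfss <- per$hfss_only + per$both
  per$all_upf <- per$upf_only + per$both
  per$upf_also_hfss <- ifelse(per$all_upf > 0,
                              100 * per$both / per$all_upf, NA_real_)
  per
}

#' Survey-weighted person-level estimates
#'
#' Computes, per participant, the percentage of their own basis mass (all
#' diary days pooled) in each category, then the survey-weighted mean of
#' those within-person percentages across participants with a two-sided
#' 95% CI ([weighted_mean_ci()]). Measures mirror the published table rows:
#' neither, all UPF, UPF only, all HFSS, HFSS only, both, and "UPF that is
#' also HFSS" (the within-person share of UPF mass that is HFSS; persons
#' consuming no UPF contribute nothing to that row).
#'
#' @param events Enriched event stream (must carry `participant_id` and, if
#'   `participants` is not supplied, `survey_weight`).
#' @param participants Optional participant table supplying
#'   `survey_weight`; if `NULL`, weights are taken from the events.
#' @param basis One of [bases()].
#' @param conf Confidence level (default 0.95).
#' @return A tibble with one row per measure: `measure`, `basis`, `point`,
#'   `ci_low`, `ci_high`, `n`.
#' @export
person_level_estimates <- function(events, participants = NULL,
                                   basis = "count", conf = 0.95) {
  basis <- match.arg(basis, bases())
  if (nrow(events) == 0) {
    abort("Empty event stream.", class = "nutrioverlap_invalid_input")
  }
  per <- person_shares(events, basis)
  if (is.null(participants)) {
    wtab <- events |>
      dplyr::distinct(.data$participant_id, .data$survey_weight)
  } else {
    wtab <- participants[, c("participant_id", "survey_weight")]
  }
  per <- dplyr::left_join(per, wtab, by = "participant_id")
  if (any(is.na(per$survey_weight))) {
    abort("Every contributing participant needs a survey weight.",
          class = "nutrioverlap_invalid_input")
  }
  purrr::map_dfr(person_measure_order, function(meas) {
    x <- per[[meas]]
    keep <- !is.na(x)
    est <- if (any(keep)) {
      weighted_mean_ci(x[keep], per$survey_weight[keep], conf = conf)
    } else {
      # e.g. "UPF that is also HFSS" when nobody consumed UPF: undefined
      tibble::tibble(point = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                     n = 0L)
    }
    dplyr::bind_cols(tibble::tibble(measure = meas, basis = basis), est)
  })
}

#' Person-level estimates by age band and sex
#'
#' Splits participants into the five analysis [age_bands()] crossed with
#' sex, rescales survey weights within each subgroup to sum to the subgroup
#' sample size (preserving relative weights), and runs
#' [person_level_estimates()] on each. Empty subgroups are omitted with a
#' warning.
#'
#' @inheritParams person_level_estimates
#' @param participants Participant table with `age_years`, `sex`,
#'   `survey_weight`.
#' @param bands,sexes Subsets of bands/sexes to report (defaults: all).
#' @return A tibble keyed by `age_band`, `sex`, `measure`, `basis`.
#' @export
subgroup_analysis <- function(events, participants, basis = "count",
                              bands = age_bands(),
                              sexes = c("male", "female"), conf = 0.95) {
  basis <- match.arg(basis, bases())
  participants$age_band <- assign_age_band(participants$age_years)
  out <- list()
  for (band in bands) {
    for (sx in sexes) {
      sub <- participants[participants$age_band == band & participants$sex == sx, ,
                          drop = FALSE]
      ev <- events[events$participant_id %in% sub$participant_id, , drop = FALSE]
      if (nrow(sub) == 0 || nrow(ev) == 0) {
        warn(sprintf("Subgroup %s/%s is empty; omitted.", band, sx))
        next
      }
      sub$survey_weight <- sub$survey_weight * nrow(sub) / sum(sub$survey_weight)
      est <- person_level_estimates(ev, sub, basis = basis, conf = conf)
      out[[paste(band, sx)]] <- dplyr::bind_cols(
        tibble::tibble(age_band = band, sex = sx), est
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Top contributing main food groups within a category
#'
#' For one overlap category and basis, the share of the category's basis
#' mass contributed by each main food group, sorted descending (ties broken
#' by group name, ascending) and truncated to the top `k`.
#'
#' @inheritParams food_level_partition
#' @param category One of [category_levels()].
#' @param k Number of rows to keep (default 10).
#' @return A tibble `main_group_name`, `pct_contribution`; zero rows when
#'   the category has no mass.
#' @export
top_contributors <- function(events, category, basis = "count", k = 10) {
  basis <- match.arg(basis, bases())
  category <- match.arg(category, category_levels())
  events <- ensure_category(events)
  events$..mass <- event_mass(events, basis)
  inside <- events[events$category == category, , drop = FALSE]
  if (nrow(inside) == 0 || sum(inside$..mass) <= 0) {
    return(tibble::tibble(main_group_name = character(),
                          pct_contribution = numeric()))
  }
  inside |>
    dplyr::group_by(.data$main_group_name) |>
    dplyr::summarise(mass = sum(.data$..mass), .groups = "drop") |>
    dplyr::mutate(pct_contribution = 100 * .data$mass / sum(.data$mass)) |>
    dplyr::arrange(dplyr::desc(.data$pct_contribution), .data$main_group_name) |>
    dplyr::select("main_group_name", "pct_contribution") |>
    head(k)
}
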