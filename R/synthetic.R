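#' Configuration for the synthetic diet-survey generator
#'
#' Describes an NDNS-like survey: a food catalog organised as main food
#' groups > subgroups > items, per-100 g nutrient profiles, participants
#' with survey weights in the five analysis age bands, and 3-4 diary days
#' of consumption events per person. Classification structure is
#' controllable: `hfss_prob` and `upf_prob` (scalar or one value per main
#' group) set the probability that an item is generated inside the HFSS
#' score region and in Nova group 4 respectively, so prevalence in the
#' generated population is known by construction.
#'
#' Defaults are a scaled-down survey (50 items, 200 participants) sized so
#' a full pipeline run takes seconds; the full-survey shape is
#' `n_main_groups = 56, n_subgroups = 136, n_items = 4555` with a few
#' thousand participants. Item prevalences default to the vicinity of the
#' food-level shares observed in UK consumption (about a third of items
#' HFSS, a third UPF); diary intensity defaults to 3-4 days of roughly 30
#' events per day, matching a survey where ~15,000 participants report
#' ~1.7 million foods.
#'
#' @param seed Integer; fully determines the generated data.
#' @param n_main_groups,n_subgroups,n_items Catalog shape
#'   (`n_main_groups <= n_subgroups <= n_items`; every group gets at least
#'   one subgroup, every subgroup at least one item).
#' @param n_participants Number of participants.
#' @param age_band_probs Probabilities over the five [age_bands()].
#' @param prop_male Probability a participant is male.
#' @param diary_days Candidate diary lengths, sampled uniformly per person.
#' @param events_per_day_mean Poisson mean of events per diary day (min 1).
#' @param hfss_prob,upf_prob Per-main-group (recycled) probabilities of an
#'   item being HFSS / Nova 4.
#' @param rule_level_probs Probabilities that a main group's Nova coding is
#'   resolved at main-group, subgroup or item level.
#' @param drink_group_frac Fraction of main groups that are drink groups.
#' @param toddler_prob,home_prepared_prob,pastry_prob_given_home Flag rates
#'   driving the Nova override predicates.
#' @param alcohol_prob,supplement_prob Rates of excluded items.
#' @param weight_meanlog,weight_sdlog Log-normal survey-weight parameters.
#' @param model NPM variant the generator inverts (default `"NPM2004"`).
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(seed = 1,
                             n_main_groups = 10,
                             n_subgroups = 20,
                             n_items = 50,
                             n_participants = 200,
                             age_band_probs = c(0.09, 0.19, 0.21, 0.39, 0.12),
                             prop_male = 0.46,
                             diary_days = c(3, 4),
                             events_per_day_mean = 30,
                             hfss_prob = 0.33,
                             upf_prob = 0.36,
                             rule_level_probs = c(0.5, 0.25, 0.25),
                             drink_group_frac = 0.2,
                             toddler_prob = 0.02,
                             home_prepared_prob = 0.08,
                             pastry_prob_given_home = 0.3,
                             alcohol_prob = 0.03,
                             supplement_prob = 0.02,
                             weight_meanlog = 0,
                             weight_sdlog = 0.5,
                             model = "NPM2004") {
  cfg <- as.list(environment())
  stopifnot(
    n_main_groups >= 1, n_subgroups >= n_main_groups, n_items >= n_subgroups,
    n_participants >= 1, length(age_band_probs) == 5,
    abs(sum(age_band_probs) - 1) < 1e-6,
    all(diary_days >= 1), events_per_day_mean > 0,
    all(hfss_prob >= 0 & hfss_prob <= 1), all(upf_prob >= 0 & upf_prob <= 1),
    length(rule_level_probs) == 3, all(rule_level_probs >= 0),
    prop_male >= 0, prop_male <= 1
  )
  structure(cfg, class = "generator_config")
}

resample <- function(x, n = 1, ...) x[sample.int(length(x), n, ...)]

# uniform draw from the open value band that awards exactly `idx`-th entry
# of `points` (idx 0 = below the first cutpoint); `top` bounds the last band
band_value <- function(idx, cutpoints, top = NULL) {
  k <- length(cutpoints)
  if (idx == 0) return(runif(1, 0, 0.999 * cutpoints[1]))
  if (idx < k) {
    lo <- cutpoints[idx]
    hi <- cutpoints[idx + 1]
    return(runif(1, lo + 0.001 * (hi - lo), hi))
  }
  hi <- top %||% (cutpoints[k] * 1.5 + 1)
  runif(1, cutpoints[k] + 0.001 * (hi - cutpoints[k]), hi)
}

# Choose consistent (A, C) point vectors realising `target_hfss` under
# `spec`, then sample nutrient values inside the chosen bands. Inverts the
# band tables instead of rejection-sampling nutrient space.
sample_profile_points <- function(target_hfss, is_drink, spec) {
  cutoff <- if (is_drink) spec$cutoffs$drink else spec$cutoffs$food
  score <- if (target_hfss) resample(cutoff:(cutoff + 8)) else
    resample((cutoff - 8):(cutoff - 1))

  fvn_choices <- c(0, spec$c_bands$fvn_pct$points)
  thresh <- spec$protein_cap$a_threshold
  exempt <- spec$protein_cap$exemption_fvn_points

  # enumerate every (fvn, fibre, protein) point combination and keep those
  # for which an A total in [0, 40] consistent with the protein rule exists
  grid <- expand.grid(f = fvn_choices, fb = 0:5, p = 0:5)
  a_counted <- score + grid$f + grid$fb + grid$p
  ok_counted <- a_counted >= 0 & a_counted <= 40 &
    (a_counted < thresh | grid$f >= exempt)
  a_supp <- score + grid$f + grid$fb
  ok_supp <- a_supp >= thresh & grid$f < exempt & a_supp <= 40
  feasible <- ok_counted | ok_supp
  if (!any(feasible)) {
    abort(sprintf("Infeasible score target %d.", score),
          class = "nutrioverlap_infeasible_config")
  }
  # favour nutrient-poor C profiles, as most supermarket foods are
  wf <- c(0.55, 0.2, 0.15, 0.1)[match(grid$f, fvn_choices)]
  wfb <- c(0.35, 0.25, 0.15, 0.1, 0.1, 0.05)[grid$fb + 1]
  wp <- c(0.3, 0.2, 0.15, 0.15, 0.1, 0.1)[grid$p + 1]
  pick <- resample(which(feasible), prob = (wf * wfb * wp)[feasible])
  a <- if (ok_counted[pick]) a_counted[pick] else a_supp[pick]
  list(score = score, a = a, fvn = grid$f[pick], fibre = grid$fb[pick],
       protein = grid$p[pick])
}

split_a_points <- function(a) {
  rem <- a
  p <- integer(4)
  for (j in 1:3) {
    left <- 4 - j  # components still to fill, 10 points capacity each
    p[j] <- resample(max(0, rem - 10 * left):min(10, rem))
    rem <- rem - p[j]
  }
  p[4] <- rem
  p
}

sample_nutrient_row <- function(item_code, target_hfss, is_drink, spec) {
  pts <- sample_profile_points(target_hfss, is_drink, spec)
  a <- split_a_points(pts$a)
  energy_kj <- band_value(a[1], spec$a_bands$energy_kj)
  sat_fat <- band_value(a[2], spec$a_bands$sat_fat_g)
  sugars <- band_value(a[3], spec$a_bands$sugars_g)
  sodium <- band_value(a[4], spec$a_bands$sodium)
  fvn_idx <- match(pts$fvn, spec$c_bands$fvn_pct$points)
  fvn <- band_value(if (is.na(fvn_idx)) 0 else fvn_idx,
                    spec$c_bands$fvn_pct$cutpoints, top = 100)
  fibre <- band_value(pts$fibre, spec$c_bands$fibre$AOAC)
  protein <- band_value(pts$protein, spec$c_bands$protein_g)
  tibble::tibble(
    item_code = item_code,
    energy_kj = energy_kj,
    energy_kcal = energy_kj / KJ_PER_KCAL,
    sat_fat_g = sat_fat,
    total_sugars_g = sugars,
    free_sugars_g = sugars * runif(1, 0.5, 1),
    sodium_mg = sodium,
    salt_g = sodium * SODIUM_MG_TO_SALT_G,
    fibre_g = fibre,
    fibre_basis = "AOAC",
    protein_g = protein,
    fvn_pct = fvn
  )
}

#' Generate a synthetic diet survey with known ground truth
#'
#' Emits the four analysis tables plus a Nova rule table covering every
#' item, and a ground-truth record of each item's intended HFSS flag and
#' Nova group together with the exact food-level category shares implied by
#' the emitted event stream (accumulated directly from the generator's own
#' flags, independent of the analysis pipeline). Nutrient values are drawn
#' by first fixing each item's NPM score region and then sampling values
#' inside the corresponding threshold bands, so scoring the emitted
#' nutrients under the configured model reproduces the intended flags.
#'
#' @param config A [generator_config()].
#' @return A list of class `diet_sim`: `catalog`, `nutrients`, `diary`,
#'   `participants`, `nova_rules`, `ground_truth` (with `items` and
#'   `shares`), and the `config`. Identical seeds give identical output.
#' @export
#' @examples
#' sim <- generate_diet_data(generator_config(seed = 7, n_participants = 20))
#' sim$ground_truth$shares
generate_diet_data <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  spec <- load_model_spec(config$model)
  with_seed(config$seed, {
    m <- config$n_main_groups
    drink_groups <- sample.int(m, max(1, round(config$drink_group_frac * m)))

    sg_main <- sort(rep_len(seq_len(m), config$n_subgroups))
    item_sg <- sort(rep_len(seq_len(config$n_subgroups), config$n_items))

    catalog <- tibble::tibble(
      item_code = sprintf("I%04d", seq_len(config$n_items)),
      item_name = sprintf("Synthetic item %04d", seq_len(config$n_items)),
      main_group_code = sprintf("MG%02d", sg_main[item_sg]),
      main_group_name = sprintf("Main group %02d", sg_main[item_sg]),
      subgroup_code = sprintf("SG%03d", item_sg),
      subgroup_name = sprintf("Subgroup %03d", item_sg),
      is_drink = sg_main[item_sg] %in% drink_groups,
      is_toddler_food = runif(config$n_items) < config$toddler_prob,
      is_home_prepared = runif(config$n_items) < config$home_prepared_prob,
      is_alcohol_containing = runif(config$n_items) < config$alcohol_prob,
      is_supplement = runif(config$n_items) < config$supplement_prob
    )
    catalog$contains_purchased_pastry_or_breadcrumbs_or_margarine <-
      catalog$is_home_prepared &
      runif(config$n_items) < config$pastry_prob_given_home
    catalog$is_supplement <- catalog$is_supplement & !catalog$is_alcohol_containing
    catalog <- catalog[, c("item_code", "item_name", "main_group_code",
                           "main_group_name", "subgroup_code", "subgroup_name",
                           catalog_flag_cols)]

    # Nova table rules, resolved at a per-group level of specificity
    upf_p <- rep_len(config$upf_prob, m)
    level_by_group <- resample(c("main_group", "subgroup", "item"), m,
                               replace = TRUE, prob = config$rule_level_probs)
    draw_nova <- function(p4, n) {
      ifelse(runif(n) < p4, 4L, resample(1:3, n, replace = TRUE))
    }
    rules <- list()
    item_table_nova <- integer(config$n_items)
    item_main <- sg_main[item_sg]
    for (g in seq_len(m)) {
      in_g <- item_main == g
      lvl <- level_by_group[g]
      if (lvl == "main_group") {
        nv <- draw_nova(upf_p[g], 1)
        rules[[length(rules) + 1]] <- tibble::tibble(
          level = "main_group", code = sprintf("MG%02d", g), nova_group = nv)
        item_table_nova[in_g] <- nv
      } else if (lvl == "subgroup") {
        sgs <- unique(item_sg[in_g])
        nv <- draw_nova(upf_p[g], length(sgs))
        rules[[length(rules) + 1]] <- tibble::tibble(
          level = "subgroup", code = sprintf("SG%03d", sgs), nova_group = nv)
        item_table_nova[in_g] <- nv[match(item_sg[in_g], sgs)]
      } else {
        nv <- draw_nova(upf_p[g], sum(in_g))
        rules[[length(rules) + 1]] <- tibble::tibble(
          level = "item", code = catalog$item_code[in_g], nova_group = nv)
        item_table_nova[in_g] <- nv
      }
    }
    nova_rules <- validate_nova_rules(dplyr::bind_rows(rules))

    # ground-truth Nova: override predicates take precedence over the table
    override <- nova_overrides(catalog)
    true_nova <- ifelse(is.na(override), item_table_nova,
                        override_nova_group[override])

    # HFSS targets and band-inverted nutrient profiles
    hfss_p <- rep_len(config$hfss_prob, m)
    true_hfss <- runif(config$n_items) < hfss_p[item_main]
    nutrients <- purrr::map_dfr(seq_len(config$n_items), function(i) {
      sample_nutrient_row(catalog$item_code[i], true_hfss[i],
                          catalog$is_drink[i], spec)
    })

    # participants
    band_idx <- resample(1:5, config$n_participants, replace = TRUE,
                         prob = config$age_band_probs)
    lo <- c(1.5, 4, 11, 19, 65)[band_idx]
    hi <- c(3.99, 10.99, 18.99, 64.99, 89.99)[band_idx]
    participants <- tibble::tibble(
      participant_id = sprintf("P%04d", seq_len(config$n_participants)),
      age_years = round(runif(config$n_participants, lo, hi), 2),
      sex = ifelse(runif(config$n_participants) < config$prop_male,
                   "male", "female"),
      survey_weight = rlnorm(config$n_participants, config$weight_meanlog,
                             config$weight_sdlog),
      wave = sprintf("W%02d", resample(1:11, config$n_participants,
                                       replace = TRUE))
    )

    # diary: per person 3-4 days, ~Poisson events/day, item popularity skewed
    popularity <- rexp(config$n_items)
    days <- resample(config$diary_days, config$n_participants, replace = TRUE)
    per_day <- purrr::map2_dfr(
      participants$participant_id, days,
      function(pid, d) tibble::tibble(participant_id = pid, diary_day = seq_len(d))
    )
    per_day$n_events <- pmax(1L, rpois(nrow(per_day), config$events_per_day_mean))
    idx <- resample(seq_len(config$n_items), sum(per_day$n_events),
                    replace = TRUE, prob = popularity)
    diary <- tibble::tibble(
      participant_id = rep(per_day$participant_id, per_day$n_events),
      diary_day = rep(per_day$diary_day, per_day$n_events),
      item_code = catalog$item_code[idx]
    )
    meanlog <- ifelse(catalog$is_drink[idx], log(200), log(80))
    sdlog <- ifelse(catalog$is_drink[idx], 0.35, 0.6)
    diary$grams <- rlnorm(nrow(diary), meanlog, sdlog)
    diary$kcal <- diary$grams * nutrients$energy_kcal[idx] / 100

    ground_truth <- list(
      items = tibble::tibble(
        item_code = catalog$item_code,
        is_hfss = true_hfss,
        nova_group = as.integer(true_nova),
        is_upf = true_nova == 4L,
        excluded = catalog$is_alcohol_containing | catalog$is_supplement
      )
    )
    ground_truth$shares <- ground_truth_shares(diary, nutrients, ground_truth$items)

    structure(
      list(catalog = catalog, nutrients = nutrients, diary = diary,
           participants = participants, nova_rules = nova_rules,
           ground_truth = ground_truth, config = config),
      class = "diet_sim"
    )
  })
}

# exact food-level shares implied by the emitted stream and intended flags;
# deliberately plain base-R accumulation, not the pipeline functions
ground_truth_shares <- function(diary, nutrients, items) {
  keep <- !items$excluded[match(diary$item_code, items$item_code)]
  d <- diary[keep, , drop = FALSE]
  hf <- items$is_hfss[match(d$item_code, items$item_code)]
  up <- items$is_upf[match(d$item_code, items$item_code)]
  cat4 <- ifelse(hf & up, "BOTH", ifelse(hf, "HFSS_only",
                 ifelse(up, "UPF_only", "NEITHER")))
  out <- lapply(bases(), function(b) {
    mass <- switch(b, count = rep(1, nrow(d)), energy_kcal = d$kcal,
                   weight_g = d$grams)
    tot <- sum(mass)
    pct <- vapply(category_levels(),
                  function(cl) 100 * sum(mass[cat4 == cl]) / tot, numeric(1))
    tibble::tibble(basis = b, pct_hfss_only = pct[["HFSS_only"]],
                   pct_upf_only = pct[["UPF_only"]], pct_both = pct[["BOTH"]],
                   pct_neither = pct[["NEITHER"]])
  })
  dplyr::bind_rows(out)
}

#' Write a simulated survey to CSV files
#'
#' @param sim A [`diet_sim`][generate_diet_data] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written
#'   (`catalog.csv`, `nutrients.csv`, `diary.csv`, `participants.csv`,
#'   `nova_rules.csv`).
#' @export
write_diet_data <- function(sim, dir) {
  stopifnot(inherits(sim, "diet_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("catalog", "nutrients", "diary", "participants", "nova_rules")
  paths <- stats::setNames(file.path(dir, paste0(tables, ".csv")), tables)
  for (t in tables) readr::write_csv(sim[[t]], paths[[t]], progress = FALSE)
  invisible(paths)
}

#' @export
print.diet_sim <- function(x, ...) {
  cat(sprintf(
    "<diet_sim> seed %d: %d items / %d participants / %d events\n",
    x$config$seed, nrow(x$catalog), nrow(x$participants), nrow(x$diary)))
  invisible(x)
}
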