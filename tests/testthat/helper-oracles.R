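# Independent brute-force oracles. These deliberately share no code with the
# package internals: banded points are found by linearly scanning the band
# list, and partitions by accumulating sums in an explicit loop.

oracle_band_points <- function(value, cutpoints, points = seq_along(cutpoints)) {
  best <- 0
  for (i in seq_along(cutpoints)) {
    if (value > cutpoints[i]) best <- points[i]
  }
  best
}

# full NPM score for a single profile row (a one-row list or data frame)
oracle_npm_score <- function(p, is_drink, spec) {
  energy <- p$energy_kj
  if (is.null(energy) || is.na(energy)) energy <- p$energy_kcal * 4.184
  sugars <- p[[spec$sugar_field]]
  if (spec$sodium_field == "sodium_mg") {
    sodium <- p$sodium_mg
    if (is.null(sodium) || is.na(sodium)) sodium <- p$salt_g * 1000 / 2.5
  } else {
    sodium <- p$salt_g
    if (is.null(sodium) || is.na(sodium)) sodium <- p$sodium_mg * 2.5 / 1000
  }
  a <- oracle_band_points(energy, spec$a_bands$energy_kj) +
    oracle_band_points(p$sat_fat_g, spec$a_bands$sat_fat_g) +
    oracle_band_points(sugars, spec$a_bands$sugars_g) +
    oracle_band_points(sodium, spec$a_bands$sodium)
  fvn <- oracle_band_points(p$fvn_pct, spec$c_bands$fvn_pct$cutpoints,
                            spec$c_bands$fvn_pct$points)
  fibre <- oracle_band_points(p$fibre_g, spec$c_bands$fibre[[p$fibre_basis]])
  protein <- oracle_band_points(p$protein_g, spec$c_bands$protein_g)
  counted <- fvn + fibre
  suppressed <- a >= spec$protein_cap$a_threshold &&
    fvn < spec$protein_cap$exemption_fvn_points
  if (!suppressed) counted <- counted + protein
  score <- a - counted
  cutoff <- if (is_drink) spec$cutoffs$drink else spec$cutoffs$food
  list(a_total = a, c_total_counted = counted, score = score,
       protein_suppressed = suppressed, is_hfss = score >= cutoff)
}

# brute-force four-category shares of an event stream on one basis
oracle_partition <- function(events, basis) {
  totals <- c(HFSS_only = 0, UPF_only = 0, BOTH = 0, NEITHER = 0)
  for (i in seq_len(nrow(events))) {
    mass <- switch(basis, count = 1, energy_kcal = events$kcal[i],
                   weight_g = events$grams[i])
    cat <- if (events$is_hfss[i] && events$is_upf[i]) "BOTH"
      else if (events$is_hfss[i]) "HFSS_only"
      else if (events$is_upf[i]) "UPF_only"
      else "NEITHER"
    totals[cat] <- totals[cat] + mass
  }
  100 * totals / sum(totals)
}

# brute-force per-main-group contributions within one category
oracle_contributions <- function(events, category, basis) {
  acc <- list()
  for (i in seq_len(nrow(events))) {
    cat <- if (events$is_hfss[i] && events$is_upf[i]) "BOTH"
      else if (events$is_hfss[i]) "HFSS_only"
      else if (events$is_upf[i]) "UPF_only"
      else "NEITHER"
    if (cat != category) next
    mass <- switch(basis, count = 1, energy_kcal = events$kcal[i],
                   weight_g = events$grams[i])
    g <- events$main_group_name[i]
    acc[[g]] <- (acc[[g]] %||% 0) + mass
  }
  if (length(acc) == 0) return(numeric())
  v <- unlist(acc)
  sort(100 * v / sum(v), decreasing = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random nutrient profiles spanning all bands of both model variants
random_profiles <- function(n) {
  tibble::tibble(
    energy_kj = runif(n, 0, 4000),
    sat_fat_g = runif(n, 0, 12),
    total_sugars_g = runif(n, 0, 60),
    free_sugars_g = runif(n, 0, 60),
    sodium_mg = runif(n, 0, 1200),
    salt_g = runif(n, 0, 3),
    fibre_g = runif(n, 0, 8),
    fibre_basis = sample(c("NSP", "AOAC"), n, replace = TRUE),
    protein_g = runif(n, 0, 12),
    fvn_pct = runif(n, 0, 100)
  )
}

# a minimal enriched event stream straight from flag/mass vectors
make_events <- function(is_hfss, is_upf, kcal = NULL, grams = NULL,
                        participant_id = NULL, survey_weight = NULL,
                        main_group_name = NULL) {
  n <- length(is_hfss)
  tibble::tibble(
    participant_id = participant_id %||% rep("P1", n),
    item_code = sprintf("I%03d", seq_len(n)),
    is_hfss = is_hfss,
    is_upf = is_upf,
    kcal = kcal %||% rep(100, n),
    grams = grams %||% rep(100, n),
    survey_weight = survey_weight %||% rep(1, n),
    main_group_name = main_group_name %||% rep("G", n)
  )
}
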