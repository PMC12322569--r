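test_that("the four categories partition the flag space", {
  expect_identical(as.character(categorize(TRUE, TRUE)), "BOTH")
  expect_identical(as.character(categorize(FALSE, FALSE)), "NEITHER")
  expect_identical(as.character(categorize(TRUE, FALSE)), "HFSS_only")
  expect_identical(as.character(categorize(FALSE, TRUE)), "UPF_only")
  expect_identical(levels(categorize(TRUE, TRUE)), category_levels())
})

test_that("food-level partition: symmetry, proportions and identities", {
  ev <- make_events(is_hfss = c(TRUE, TRUE, FALSE, FALSE),
                    is_upf = c(TRUE, FALSE, TRUE, FALSE))
  p <- food_level_partition(ev, "count")
  expect_equal(unlist(p[, c("pct_hfss_only", "pct_upf_only", "pct_both",
                            "pct_neither")], use.names = FALSE),
               c(25, 25, 25, 25))

  # energy basis weights by kcal: 300 BOTH vs 100 NEITHER
  ev2 <- make_events(is_hfss = c(TRUE, FALSE), is_upf = c(TRUE, FALSE),
                     kcal = c(300, 100))
  p2 <- food_level_partition(ev2, "energy_kcal")
  expect_equal(p2$pct_both, 75)
  expect_equal(p2$pct_neither, 25)
  expect_equal(p2$pct_upf_also_hfss, 100)

  expect_error(food_level_partition(ev[0, ], "count"),
               class = "nutrioverlap_invalid_input")
})

test_that("partition closure, inclusion-exclusion and overlap bound hold on random streams", {
  withr::local_seed(11)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    ev <- make_events(is_hfss = runif(n) < runif(1),
                      is_upf = runif(n) < runif(1),
                      kcal = runif(n, 1, 500), grams = runif(n, 1, 400))
    for (b in bases()) {
      p <- food_level_partition(ev, b)
      expect_equal(p$pct_hfss_only + p$pct_upf_only + p$pct_both + p$pct_neither,
                   100, tolerance = 1e-12)
      expect_equal(p$pct_neither,
                   100 - (p$pct_all_hfss + p$pct_all_upf - p$pct_both),
                   tolerance = 1e-12)
      expect_lte(p$pct_both, min(p$pct_all_hfss, p$pct_all_upf) + 1e-12)
      # brute-force accumulator agreement
      o <- oracle_partition(ev, b)
      expect_equal(unlist(p[, c("pct_hfss_only", "pct_upf_only", "pct_both",
                                "pct_neither")], use.names = FALSE),
                   unname(o), tolerance = 1e-12)
    }
  }
})

test_that("duplicating events leaves shares unchanged; duplicating BOTH raises pct_both", {
  withr::local_seed(12)
  ev <- make_events(is_hfss = runif(30) < 0.4, is_upf = runif(30) < 0.5,
                    kcal = runif(30, 10, 500), grams = runif(30, 10, 400))
  doubled <- dplyr::bind_rows(ev, ev)
  both_idx <- which(ev$is_hfss & ev$is_upf)[1]
  plus_one <- dplyr::bind_rows(ev, ev[both_idx, ])
  for (b in bases()) {
    expect_equal(food_level_partition(doubled, b),
                 food_level_partition(ev, b), tolerance = 1e-12)
    expect_gte(food_level_partition(plus_one, b)$pct_both,
               food_level_partition(ev, b)$pct_both)
  }
})

test_that("partition identities reproduce derived values from marginals", {
  p <- partition_from_marginals(40, 50, 20)
  expect_equal(p$pct_neither, 30)
  expect_equal(p$pct_upf_also_hfss, 40)
  expect_equal(p$pct_hfss_only + p$pct_upf_only + p$pct_both + p$pct_neither, 100)
  expect_error(partition_from_marginals(10, 10, 20))  # both > marginals
})

test_that("weighted mean and CI behave as the survey estimator", {
  est <- weighted_mean_ci(c(20, 60), c(1, 3))
  expect_equal(est$point, 50)  # (1*20 + 3*60) / 4
  expect_lte(est$ci_low, est$point)
  expect_gte(est$ci_high, est$point)

  # equal weights reduce to the unweighted mean
  x <- c(10, 30, 50, 90)
  expect_equal(weighted_mean_ci(x, rep(2, 4))$point, mean(x))
  expect_error(weighted_mean_ci(x, c(1, 1, 1, 0)))
})

test_that("person-level estimates: degenerate cases and hand-checked weighting", {
  # single participant, weight 1: point equals their food-level share
  ev <- make_events(is_hfss = c(TRUE, TRUE, FALSE, FALSE),
                    is_upf = c(TRUE, FALSE, TRUE, FALSE))
  est <- person_level_estimates(ev, basis = "count")
  p <- food_level_partition(ev, "count")
  expect_equal(est$point[est$measure == "both"], p$pct_both)
  expect_equal(est$point[est$measure == "neither"], p$pct_neither)
  expect_true(all(est$n == 1))

  # two participants, BOTH shares 20% and 60%, weights 1 and 3 -> 50%
  ev2 <- make_events(
    is_hfss = c(TRUE, rep(FALSE, 4), rep(TRUE, 3), rep(FALSE, 2)),
    is_upf = c(TRUE, rep(FALSE, 4), rep(TRUE, 3), rep(FALSE, 2)),
    participant_id = rep(c("A", "B"), each = 5),
    survey_weight = rep(c(1, 3), each = 5)
  )
  est2 <- person_level_estimates(ev2, basis = "count")
  expect_equal(est2$point[est2$measure == "both"], 50)
  expect_equal(est2$n[est2$measure == "both"], 2L)

  # all weights equal: point equals unweighted mean of per-person shares
  ev3 <- make_events(
    is_hfss = runif(40) < 0.5, is_upf = runif(40) < 0.5,
    participant_id = rep(sprintf("P%d", 1:4), each = 10),
    survey_weight = rep(2, 40)
  )
  est3 <- person_level_estimates(ev3, basis = "count")
  shares <- nutrioverlap:::person_shares(ev3, "count")
  expect_equal(est3$point[est3$measure == "all_upf"], mean(shares$all_upf))
})

test_that("participants consuming no UPF drop out of the UPF-also-HFSS ratio", {
  ev <- make_events(
    is_hfss = c(TRUE, FALSE, TRUE, TRUE),
    is_upf = c(FALSE, FALSE, TRUE, TRUE),
    participant_id = c("A", "A", "B", "B")
  )
  est <- person_level_estimates(ev, basis = "count")
  row <- est[est$measure == "upf_also_hfss", ]
  expect_identical(row$n, 1L)       # only B consumed UPF
  expect_equal(row$point, 100)      # all of B's UPF is HFSS
})

test_that("subgroup analysis rescales weights and recovers subgroup structure", {
  withr::local_seed(21)
  # identical diets across subgroups -> identical estimates in every cell
  participants <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:10),
    age_years = rep(c(2, 7, 15, 40, 70), 2),
    sex = rep(c("male", "female"), each = 5),
    survey_weight = runif(10, 0.5, 2)
  )
  # every participant eats the same two-event diet: one BOTH, one NEITHER
  ev <- make_events(
    is_hfss = rep(c(TRUE, FALSE), 10),
    is_upf = rep(c(TRUE, FALSE), 10),
    participant_id = rep(participants$participant_id, each = 2)
  )
  ev <- dplyr::left_join(ev[, setdiff(names(ev), "survey_weight")],
                         participants[, c("participant_id", "survey_weight")],
                         by = "participant_id")
  sub <- subgroup_analysis(ev, participants, basis = "count")
  expect_true(all(vapply(split(sub$point, sub$measure), function(v) {
    diff(range(v)) < 1e-9
  }, logical(1))))

  # a lone subgroup equals person_level_estimates on that subset
  only <- subgroup_analysis(ev, participants, basis = "count",
                            bands = "1.5-3", sexes = "male")
  sub_p <- participants[participants$age_years < 4 &
                          participants$sex == "male", ]
  sub_p$survey_weight <- sub_p$survey_weight * nrow(sub_p) / sum(sub_p$survey_weight)
  direct <- person_level_estimates(
    ev[ev$participant_id %in% sub_p$participant_id, ], sub_p, "count")
  expect_equal(only$point, direct$point)
  expect_equal(only$ci_low, direct$ci_low)

  # empty subgroups are omitted with a warning
  expect_warning(
    res <- subgroup_analysis(ev, participants[participants$sex == "male", ],
                             basis = "count", bands = "1.5-3"),
    "empty"
  )
  expect_true(all(res$sex == "male"))
})

test_that("band-specific UPF prevalence ordering is recovered from generated data", {
  sim <- generate_diet_data(generator_config(
    seed = 31, n_participants = 150,
    upf_prob = c(0.9, 0.9, 0.9, 0.9, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05)
  ))
  an <- analyze_diet(sim$catalog, sim$nutrients, sim$diary, sim$participants,
                     nova_rules = sim$nova_rules, subgroups = FALSE)
  # groups 1-4 are heavily UPF; their realized share must exceed the others'
  upf_groups <- sprintf("MG%02d", 1:4)
  ev <- an$events
  share_hi <- mean(ev$is_upf[ev$main_group_code %in% upf_groups])
  share_lo <- mean(ev$is_upf[!ev$main_group_code %in% upf_groups])
  expect_gt(share_hi, share_lo)
})

test_that("top contributors match the brute-force group accumulator", {
  ev <- make_events(
    is_hfss = rep(TRUE, 4), is_upf = rep(TRUE, 4),
    kcal = c(300, 100, 50, 50),
    main_group_name = c("A", "B", "A", "C")
  )
  tab <- top_contributors(ev, "BOTH", "energy_kcal")
  expect_equal(tab$main_group_name, c("A", "B", "C"))
  expect_equal(tab$pct_contribution, c(70, 20, 10))
  expect_equal(sum(tab$pct_contribution), 100)

  # single group -> 100%; masses 3:1 -> 75/25
  one <- top_contributors(make_events(TRUE, TRUE), "BOTH", "count")
  expect_equal(one$pct_contribution, 100)
  duo <- top_contributors(
    make_events(rep(TRUE, 4), rep(TRUE, 4),
                main_group_name = c("X", "X", "X", "Y")),
    "BOTH", "count")
  expect_equal(duo$pct_contribution, c(75, 25))

  # empty category -> empty table
  none <- top_contributors(make_events(FALSE, FALSE), "BOTH", "count")
  expect_identical(nrow(none), 0L)

  # randomized streams against the oracle, including truncation and tie-break
  withr::local_seed(33)
  for (rep in 1:10) {
    n <- sample(20:80, 1)
    ev <- make_events(
      is_hfss = runif(n) < 0.5, is_upf = runif(n) < 0.5,
      kcal = runif(n, 1, 400), grams = runif(n, 1, 300),
      main_group_name = sample(LETTERS[1:6], n, replace = TRUE)
    )
    for (b in bases()) {
      o <- oracle_contributions(ev, "BOTH", b)
      got <- top_contributors(ev, "BOTH", b, k = 10)
      expect_equal(got$pct_contribution, unname(o[got$main_group_name]),
                   tolerance = 1e-12)
      expect_identical(nrow(got), as.integer(min(10, length(o))))
      expect_true(all(diff(got$pct_contribution) <= 1e-12))
    }
  }
})
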