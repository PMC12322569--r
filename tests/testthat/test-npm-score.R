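spec04 <- load_model_spec("NPM2004")
spec18 <- load_model_spec("NPM2018")

zero_profile <- function(...) {
  out <- list(energy_kj = 0, sat_fat_g = 0, total_sugars_g = 0,
              free_sugars_g = 0, sodium_mg = 0, salt_g = 0, fibre_g = 0,
              fibre_basis = "AOAC", protein_g = 0, fvn_pct = 0)
  utils::modifyList(out, list(...))
}

test_that("band scoring uses strict exceedance at every configured boundary", {
  for (spec in list(spec04, spec18)) {
    all_bands <- c(spec$a_bands,
                   list(spec$c_bands$fvn_pct$cutpoints,
                        spec$c_bands$protein_g),
                   unname(spec$c_bands$fibre))
    for (cuts in all_bands) {
      for (i in seq_along(cuts)) {
        at <- band_points(cuts[i], cuts)
        above <- band_points(cuts[i] + 1e-9, cuts)
        expect_identical(at, i - 1L)   # on the boundary: lower band
        expect_identical(above, i)     # just above: higher band
      }
    }
  }
  expect_identical(band_points(0, c(1, 2, 3)), 0L)
  expect_identical(band_points(1e6, c(1, 2, 3)), 3L)
  # sparse fruit/veg/nut awards
  expect_identical(band_points(c(40, 41, 61, 81), c(40, 60, 80),
                               points = c(1, 2, 5)),
                   c(0L, 1L, 2L, 5L))
})

test_that("A points follow the configured band tables", {
  expect_equal(score_a_points(zero_profile(), spec04)$a_total, 0L)
  maxed <- zero_profile(energy_kj = 3360, sat_fat_g = 11, total_sugars_g = 46,
                        sodium_mg = 910)
  expect_equal(score_a_points(maxed, spec04)$a_total, 40L)
  one <- zero_profile(energy_kj = 335.1)
  expect_equal(score_a_points(one, spec04)$a_total, 1L)
})

test_that("C points saturate and respect the component maxima", {
  expect_equal(score_c_points(zero_profile(), spec04)$c_total_raw, 0L)
  expect_equal(score_c_points(zero_profile(fvn_pct = 100), spec04)$c_fvn, 5L)
  expect_equal(score_c_points(zero_profile(protein_g = 8.01), spec04)$c_protein, 5L)
  # NSP and AOAC fibre are scored against different cutpoints
  nsp <- zero_profile(fibre_g = 3.6, fibre_basis = "NSP")
  aoac <- zero_profile(fibre_g = 3.6, fibre_basis = "AOAC")
  expect_equal(score_c_points(nsp, spec04)$c_fibre, 5L)
  expect_equal(score_c_points(aoac, spec04)$c_fibre, 3L)
  expect_error(score_c_points(nsp, spec18), class = "nutrioverlap_fibre_basis")
})

test_that("HFSS cutoffs: foods at 4, drinks at 1", {
  expect_false(npm_score(zero_profile(), FALSE, spec04)$is_hfss)
  expect_false(npm_score(zero_profile(), TRUE, spec04)$is_hfss)
  # a_total 4, no C points: food exactly on the cutoff
  four <- zero_profile(energy_kj = 1341)  # 4 energy points
  res <- npm_score(four, FALSE, spec04)
  expect_identical(res$score, 4L)
  expect_true(res$is_hfss)
  three <- npm_score(zero_profile(energy_kj = 1006), FALSE, spec04)
  expect_identical(three$score, 3L)
  expect_false(three$is_hfss)
  # drink with score exactly 1 is HFSS; the same item as a food is not
  one <- zero_profile(energy_kj = 336)
  expect_true(npm_score(one, TRUE, spec04)$is_hfss)
  expect_false(npm_score(one, FALSE, spec04)$is_hfss)
})

test_that("protein points are capped at 11 A points without 5 fvn points", {
  # a_total 11: energy 10 points + sat fat 1 point; protein 5 points; fvn 0
  p <- zero_profile(energy_kj = 3360, sat_fat_g = 1.5, protein_g = 9)
  res <- npm_score(p, FALSE, spec04)
  expect_identical(res$a_total, 11L)
  expect_identical(res$c_protein, 5L)
  expect_true(res$protein_suppressed)
  expect_identical(res$c_total_counted, 0L)
  expect_identical(res$score, 11L)
  # maximum fvn points lift the suppression
  lifted <- npm_score(utils::modifyList(p, list(fvn_pct = 85)), FALSE, spec04)
  expect_false(lifted$protein_suppressed)
  expect_identical(lifted$c_total_counted, 10L)  # 5 fvn + 5 protein
  expect_identical(lifted$score, 1L)
  # one A point below the threshold, protein counts
  below <- npm_score(utils::modifyList(p, list(sat_fat_g = 0)), FALSE, spec04)
  expect_identical(below$a_total, 10L)
  expect_false(below$protein_suppressed)
  expect_identical(below$score, 5L)
})

test_that("score identity and determinism hold on random profiles", {
  withr::local_seed(101)
  profs <- random_profiles(300)
  res <- npm_score(profs, FALSE, spec04)
  expect_identical(res$score, res$a_total - res$c_total_counted)
  expect_true(all(res$a_total >= 0 & res$a_total <= 40))
  expect_true(all(res$c_total_counted >= 0 & res$c_total_counted <= 15))
  expect_identical(res, npm_score(profs, FALSE, spec04))
})

test_that("score is monotone in A nutrients and antitone in fibre and fvn", {
  withr::local_seed(202)
  profs <- random_profiles(100)
  base <- npm_score(profs, FALSE, spec04)$score
  bump <- function(col, delta) {
    p2 <- profs
    p2[[col]] <- p2[[col]] + delta
    npm_score(p2, FALSE, spec04)$score
  }
  expect_true(all(bump("total_sugars_g", 10) >= base))
  expect_true(all(bump("sodium_mg", 200) >= base))
  expect_true(all(bump("sat_fat_g", 3) >= base))
  expect_true(all(bump("energy_kj", 800) >= base))
  expect_true(all(bump("fibre_g", 2) <= base))
  p2 <- profs
  p2$fvn_pct <- pmin(100, p2$fvn_pct + 30)
  expect_true(all(npm_score(p2, FALSE, spec04)$score <= base))
  # protein points themselves are monotone even though the final score is not
  p3 <- profs
  p3$protein_g <- p3$protein_g + 3
  expect_true(all(score_c_points(p3, spec04)$c_protein >=
                    score_c_points(profs, spec04)$c_protein))
})

test_that("scorer agrees with the brute-force band-scan oracle", {
  withr::local_seed(303)
  profs <- random_profiles(500)
  drinks <- runif(500) < 0.3
  res <- npm_score(profs, drinks, spec04)
  for (i in seq_len(nrow(profs))) {
    o <- oracle_npm_score(as.list(profs[i, ]), drinks[i], spec04)
    expect_identical(res$score[i], as.integer(o$score))
    expect_identical(res$is_hfss[i], o$is_hfss)
    expect_identical(res$protein_suppressed[i], o$protein_suppressed)
  }
  # 2018 variant (AOAC fibre only)
  profs$fibre_basis <- "AOAC"
  res18 <- npm_score(profs, drinks, spec18)
  for (i in seq_len(nrow(profs))) {
    o <- oracle_npm_score(as.list(profs[i, ]), drinks[i], spec18)
    expect_identical(res18$score[i], as.integer(o$score))
  }
})

test_that("salt/sodium and kcal/kJ conversions fill missing fields", {
  p_sodium <- zero_profile(sodium_mg = 500)
  p_salt <- utils::modifyList(zero_profile(sodium_mg = NA_real_),
                              list(salt_g = 500 * 2.5 / 1000))
  expect_message(
    res_salt <- score_a_points(p_salt, spec04),
    "Converted sodium|Converted salt"
  )
  expect_identical(score_a_points(p_sodium, spec04)$a_sodium, res_salt$a_sodium)

  p_kcal <- utils::modifyList(zero_profile(energy_kj = NA_real_),
                              list(energy_kcal = 1341 / 4.184))
  expect_message(res_kcal <- score_a_points(p_kcal, spec04), "kcal to kJ")
  expect_identical(res_kcal$a_energy, 4L)
})

test_that("missing free sugars fail loudly under the 2018 model", {
  p <- zero_profile(free_sugars_g = NA_real_)
  expect_error(npm_score(p, FALSE, spec18),
               class = "nutrioverlap_missing_nutrient")
})

test_that("classify_catalog preserves order and reports exceptions", {
  fx <- make_fixture("four_corners")
  empty <- classify_catalog(fx$catalog[0, ], fx$nutrients, spec04)
  expect_identical(nrow(empty), 0L)

  res <- classify_catalog(fx$catalog, fx$nutrients, spec04)
  expect_identical(res$item_code, fx$catalog$item_code)
  expect_identical(res$is_hfss, c(TRUE, TRUE, FALSE, FALSE))
  # elementwise equality with single-profile scoring
  for (i in seq_len(nrow(fx$catalog))) {
    single <- npm_score(fx$nutrients[i, ], fx$catalog$is_drink[i], spec04)
    expect_identical(res$score[i], single$score)
  }

  # an item without free sugars becomes an exception under 2018, not a drop
  nutr <- fx$nutrients
  nutr$free_sugars_g[2] <- NA_real_
  expect_warning(res18 <- classify_catalog(fx$catalog, nutr, spec18),
                 "could not be scored")
  expect_identical(nrow(res18), nrow(fx$catalog))
  expect_identical(attr(res18, "exceptions")$item_code, "F002")
  expect_true(is.na(res18$score[2]))
})
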