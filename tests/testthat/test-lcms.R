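test_that("neutral candidates subtract adduct deltas and drop non-positives", {
  nc <- neutral_candidates(661.5175, default_adducts("[M+K]+"))
  expect_equal(nc$neutral, 622.5543, tolerance = 1e-4)
  # proton m/z of nothing: neutral 0 is dropped
  expect_equal(nrow(neutral_candidates(1.0072765, default_adducts("[M+H]+"))), 0L)
  all4 <- neutral_candidates(661.5175)
  expect_lte(nrow(all4), 4L)
  # deltas increase monotonically, so neutrals ordered by delta decrease
  o <- order(default_adducts()$delta_mass[match(all4$adduct,
                                                default_adducts()$label)])
  expect_true(all(diff(all4$neutral[o]) < 0))
})

test_that("adduct-switch cross-matching recovers the shared neutral", {
  dg_k <- adduct_mz(622.55362, "[M+K]+")     # MALDI side
  dg_nh4 <- adduct_mz(622.55362, "[M+NH4]+") # LC-MS side
  feats <- list(lcms_feature(dg_nh4, rt_min = 10, intensity = 1e5))
  hit <- cross_match(dg_k, lcms_features = feats, tolerance_ppm = 2.5)
  expect_false(is.null(hit))
  expect_equal(hit$msi_adduct, "[M+K]+")
  expect_equal(hit$lcms_adduct, "[M+NH4]+")
  expect_equal(hit$neutral_mass, 622.55362, tolerance = 1e-5)
  expect_equal(hit$ppm_error, 0, tolerance = 1e-6)
  # empty feature list and out-of-tolerance features give no hit
  expect_null(cross_match(dg_k, lcms_features = list(), tolerance_ppm = 2.5))
  off <- list(lcms_feature(dg_nh4 * (1 + 5e-6)))
  expect_null(cross_match(dg_k, lcms_features = off, tolerance_ppm = 2.5))
})

test_that("cross-matching is symmetric in platform order", {
  m1 <- adduct_mz(622.55362, "[M+K]+")
  m2 <- adduct_mz(622.55362, "[M+NH4]+")
  h12 <- cross_match(m1, lcms_features = list(lcms_feature(m2)))
  h21 <- cross_match(m2, lcms_features = list(lcms_feature(m1)))
  expect_equal(h12$neutral_mass, h21$neutral_mass, tolerance = 1e-9)
  expect_equal(abs(h12$ppm_error), abs(h21$ppm_error), tolerance = 1e-9)
})

test_that("diagnostic fragment counting follows acyl neutral losses and head groups", {
  db <- read_lipid_db()
  dg <- db[db$name == "DG(36:1)", ]
  prec <- adduct_mz(dg$neutral_mass, "[M+NH4]+")
  # stearic acid loss: 640.58744 - 284.27153 = 356.31591
  expect_equal(fragment_support(dg, NULL, prec, 356.31591), 1L)
  expect_equal(fragment_support(dg, NULL, prec, numeric(0)), 0L)
  # both acyl losses observed
  frags <- prec - c(fatty_acid_mass(18, 0), fatty_acid_mass(18, 1))
  expect_equal(fragment_support(dg, NULL, prec, frags), 2L)
  # PC head group fragment
  pc <- db[db$name == "PC(37:1)", ]
  expect_gte(fragment_support(pc, NULL, adduct_mz(pc$neutral_mass, "[M+H]+"),
                              184.0733), 1L)
  # unknown class warns and returns 0
  odd <- data.frame(name = "?", class = "CAR", formula = "C10H20O2",
                    acyls = NA_character_)
  expect_warning(n <- fragment_support(odd, NULL, 500, 184.0733), "CAR")
  expect_equal(n, 0L)
})

test_that("evidence tiers follow the cross-match and fragment rules", {
  fake_match <- data.frame(feature_mz = 661.5175, lipid_name = "DG(36:1)")
  cross <- data.frame(lcms_index = 1L, ppm_error = 0.1)
  expect_equal(assign_tier(fake_match, cross, 2, min_frags = 1)$tier, "identified")
  expect_equal(assign_tier(fake_match, cross, 0, min_frags = 1)$tier, "annotated")
  expect_equal(assign_tier(fake_match, NULL, 3, min_frags = 1)$tier, "unmatched")
  # monotone in evidence: more fragments never demote identified
  for (f in 1:5) {
    expect_equal(assign_tier(fake_match, cross, f, min_frags = 1)$tier,
                 "identified")
  }
})

test_that("LC-MS tables round trip through TSV including fragment lists", {
  feats <- list(
    lcms_feature(640.58744, 10.5, 2e5, c(356.31591, 358.33156)),
    lcms_feature(802.63203, 12.0, 1e5, numeric(0)))
  f <- tempfile(fileext = ".tsv")
  write_lcms_table(feats, f)
  back <- read_lcms_table(f)
  expect_length(back, 2L)
  expect_equal(back[[1]]$mz, feats[[1]]$mz)
  expect_equal(back[[1]]$fragments, feats[[1]]$fragments, tolerance = 1e-5)
  expect_length(back[[2]]$fragments, 0L)
})

test_that("synthetic LC-MS tables drive both evidence tiers on the phantom", {
  sim <- generate_phantom(small_phantom_config(seed = 8))
  # all lipid-backed markers fragmented -> all identified
  all_frag <- generate_lcms_tables(sim$truth, fragment_fraction = 1)
  expect_true(all(vapply(all_frag, function(f) length(f$fragments) > 0,
                         logical(1))))
  # none fragmented -> all annotated downstream
  no_frag <- generate_lcms_tables(sim$truth, fragment_fraction = 0)
  expect_true(all(vapply(no_frag, function(f) length(f$fragments) == 0,
                         logical(1))))
  # DG(36:1) appears at its ammoniated m/z (up to ppm jitter)
  mzs <- vapply(no_frag, `[[`, numeric(1), "mz")
  expect_true(any(abs(mzs - 640.5874) / 640.5874 * 1e6 < 5))
})
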