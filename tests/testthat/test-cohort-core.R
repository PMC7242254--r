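test_that("derived indices follow the defining ratios and differences", {
  rec <- make_record(tlc_pct = 100, dlco_pct = 50, sat0 = 95.8, sat6 = 89.1)
  idx <- derive_indices(rec)
  expect_equal(idx$tlc_dlco, 2.0)
  expect_equal(idx$desaturation, 6.7)

  # group-level means pushed through the ratio (differs from the printed
  # mean-of-ratios 1.86 by Jensen's inequality, intentionally)
  idx_b <- derive_indices(make_record(tlc_pct = 91.9, dlco_pct = 54.8))
  expect_equal(idx_b$tlc_dlco, 1.677, tolerance = 5e-4)

  # vc_dlco tracks vc_pct presence
  expect_true(is.na(idx$vc_dlco))
  with_vc <- derive_indices(make_record(vc_pct = 90, dlco_pct = 60))
  expect_equal(with_vc$vc_dlco, 1.5)
})

test_that("derived ratios are scale-equivariant in DLCO", {
  rec <- make_record(tlc_pct = 91.9, dlco_pct = 54.8)
  base <- derive_indices(rec)$tlc_dlco
  for (k in c(0.5, 2, 3.7)) {
    scaled <- rec
    scaled$dlco_pct <- rec$dlco_pct * k
    expect_equal(derive_indices(scaled)$tlc_dlco, base / k)
  }
})

test_that("derive_indices rejects impossible inputs by name", {
  bad <- make_record()
  bad$dlco_pct <- -1
  expect_error(derive_indices(bad), "dlco_pct")
  bad2 <- make_record()
  bad2$sat0 <- NA_real_
  expect_error(derive_indices(bad2), "sat0")
  expect_error(patient_record(id = "x", age = 50, sex = "male",
                              diagnosis = "IPF", pack_years = 0,
                              six_mwd = 500, sat0 = 90, sat6 = 95,
                              fev1_fvc = 78, fvc_pct = 95, tlc_pct = 95,
                              dlco_pct = 70, ntprobnp = 50),
               "sat6 > sat0")
})

test_that("echo probability bands match the 2009 criteria", {
  expect_equal(as.character(classify_echo_probability(trv = 2.5)), "unlikely")
  expect_equal(as.character(classify_echo_probability(trv = 3.0)), "possible")
  expect_equal(as.character(
    classify_echo_probability(trv = 3.5, additional_signs = TRUE)), "likely")
  # bottom band with additional signs is upgraded to possible
  expect_equal(as.character(
    classify_echo_probability(trv = 2.8, additional_signs = TRUE)), "possible")
  # PASP-only assessments classify on their own
  expect_equal(as.character(classify_echo_probability(pasp = 30)), "unlikely")
  expect_equal(as.character(classify_echo_probability(pasp = 45)), "possible")
  expect_equal(as.character(classify_echo_probability(pasp = 55)), "likely")
  # disagreeing parallel criteria: higher category wins
  expect_equal(as.character(
    classify_echo_probability(trv = 2.0, pasp = 55)), "likely")
  expect_error(classify_echo_probability(), "at least one")
  expect_error(classify_echo_probability(trv = -1), "> 0")
})

test_that("echo classification is total and monotone in TRV", {
  trvs <- seq(0.5, 5, by = 0.05)
  for (signs in c(FALSE, TRUE)) {
    cats <- classify_echo_probability(trv = trvs, additional_signs = signs)
    expect_false(anyNA(cats))
    expect_true(all(diff(as.integer(cats)) >= 0))
  }
})

test_that("dichotomization is strict at the cutoff in both directions", {
  spec_up <- threshold_spec("tlc_dlco", 1.67, "above_is_risk")
  expect_true(dichotomize(make_record(tlc_pct = 84, dlco_pct = 50), spec_up))
  expect_false(dichotomize(make_record(tlc_pct = 83.5, dlco_pct = 50), spec_up))

  spec_dn <- threshold_spec("six_mwd", 507.5, "below_is_risk")
  expect_false(dichotomize(make_record(six_mwd = 507.5), spec_dn))
  expect_true(dichotomize(make_record(six_mwd = 507.4), spec_dn))

  # reversed directions never both flag the same value
  set.seed(41)
  for (i in 1:50) {
    v <- sample(c(400, 507.5, 600, 507.4, 507.6), 1)
    rec <- make_record(six_mwd = v)
    up <- dichotomize(rec, threshold_spec("six_mwd", 507.5, "above_is_risk"))
    dn <- dichotomize(rec, threshold_spec("six_mwd", 507.5, "below_is_risk"))
    expect_false(up && dn)
  }

  expect_error(dichotomize(make_record(), threshold_spec("bogus", 1)),
               "unknown variable")
  rec_na <- make_record()
  rec_na$ntprobnp <- NA_real_
  expect_error(dichotomize(rec_na, threshold_spec("ntprobnp", 38)),
               "missing")
})
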