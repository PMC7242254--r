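test_that("the composite score follows the published point assignment", {
  w <- score_weights()
  expect_equal(sum(w$items$points), 10L)

  all_hit <- make_record(age = 60, tlc_pct = 93, dlco_pct = 50, # ratio 1.86
                         six_mwd = 478, sat6 = 89, sat0 = 95)
  expect_equal(composite_score(all_hit, w), 10L)

  none <- make_record(age = 40, tlc_pct = 84, dlco_pct = 70, # ratio 1.2
                      six_mwd = 600, sat6 = 97, sat0 = 98)
  expect_equal(composite_score(none, w), 0L)

  # strictness: sat6 = 93 fails "< 93"; age 54 passes "> 53"
  mid <- make_record(age = 54, tlc_pct = 75, dlco_pct = 50, # ratio 1.5
                     six_mwd = 500, sat6 = 93, sat0 = 96)
  expect_equal(composite_score(mid, w), 5L)
})

test_that("the decision rule is score >= 6", {
  expect_true(classify_score(6))
  expect_false(classify_score(5))
  expect_true(classify_score(10))
})

test_that("exactly the scores {0,2,3,4,5,6,7,8,10} are attainable", {
  w <- score_weights()
  combos <- expand.grid(a = c(FALSE, TRUE), t = c(FALSE, TRUE),
                        m = c(FALSE, TRUE), s = c(FALSE, TRUE))
  scores <- apply(combos, 1, function(f) {
    rec <- make_record(age = if (f["a"]) 60 else 40,
                       tlc_pct = 90, dlco_pct = if (f["t"]) 45 else 90,
                       six_mwd = if (f["m"]) 400 else 600,
                       sat0 = 98, sat6 = if (f["s"]) 90 else 97)
    composite_score(rec, w)
  })
  expect_setequal(scores, c(0, 2, 3, 4, 5, 6, 7, 8, 10))
  expect_false(any(scores %in% c(1, 9)))
})

test_that("worsening one variable across its threshold never lowers the score", {
  base <- make_record(age = 40, tlc_pct = 90, dlco_pct = 90,
                      six_mwd = 600, sat0 = 98, sat6 = 97)
  s0 <- composite_score(base)
  worse <- list(
    within(base, age <- 60),
    within(base, dlco_pct <- 45),
    within(base, six_mwd <- 400),
    within(base, sat6 <- 90)
  )
  for (rec in worse) expect_gte(composite_score(rec), s0)
})

test_that("confusion metrics and their reconstruction are consistent", {
  m <- confusion_metrics(tp = 27, fp = 3, fn = 14, tn = 49)
  expect_equal(m$ppv, 0.90)
  expect_equal(m$npv, 49 / 63, tolerance = 1e-12)

  perfect <- confusion_metrics(tp = 10, fp = 0, fn = 0, tn = 12)
  expect_equal(unlist(perfect), c(sensitivity = 1, specificity = 1,
                                  ppv = 1, npv = 1))

  # an empty predicted-positive margin leaves PPV flagged undefined
  expect_true(is.na(confusion_metrics(tp = 0, fp = 0, fn = 5, tn = 5)$ppv))

  cm <- reconstruct_confusion(0.66, 0.94, 41, 52)
  expect_equal(unlist(cm), c(tp = 27, fp = 3, fn = 14, tn = 49))
  cm2 <- reconstruct_confusion(0.65, 0.92, 41, 52)
  expect_equal(unlist(cm2), c(tp = 27, fp = 4, fn = 14, tn = 48))
  cm3 <- reconstruct_confusion(1, 1, 7, 9)
  expect_equal(cm3$fn + cm3$fp, 0)

  # round trip: rates recovered within the integer-rounding bound
  set.seed(401)
  for (i in 1:100) {
    n_pos <- sample(5:60, 1); n_neg <- sample(5:60, 1)
    sens <- round(runif(1), 2); spec <- round(runif(1), 2)
    cm <- reconstruct_confusion(sens, spec, n_pos, n_neg)
    m <- confusion_metrics(cm)
    bound <- 1 / (2 * min(n_pos, n_neg)) + 1e-12
    expect_lte(abs(m$sensitivity - sens), bound)
    expect_lte(abs(m$specificity - spec), bound)
  }
})

test_that("cohort-level score evaluation wires the components together", {
  # hand-built separable cohort: every B record scores 10, every A scores 0
  mk <- function(hit, group, i) {
    make_record(id = paste0(group, i),
                age = if (hit) 60 else 40,
                tlc_pct = 90, dlco_pct = if (hit) 45 else 90,
                six_mwd = if (hit) 400 else 600,
                sat0 = 98, sat6 = if (hit) 90 else 97,
                ph_group = group)
  }
  cohort <- do.call(rbind, c(lapply(1:6, function(i) mk(FALSE, "A_low", i)),
                             lapply(1:5, function(i) mk(TRUE, "B_increased", i))))
  sm <- suppressWarnings(evaluate_score_on_cohort(cohort))
  expect_equal(sm$auc_result$auc, 1)
  expect_equal(sm$at_cutoff$sensitivity, 1)
  expect_equal(sm$at_cutoff$specificity, 1)
  expect_equal(sm$confusion$tp, 5)

  # default synthetic cohort separates the strata
  co <- generate_cohort(default_params(seed = 1))
  sm2 <- evaluate_score_on_cohort(co)
  expect_gt(sm2$auc_result$auc, 0.5)

  # permutation null: scores carry no signal about shuffled labels
  set.seed(402)
  null_auc <- replicate(100, {
    shuffled <- co
    shuffled$ph_group <- sample(co$ph_group)
    evaluate_score_on_cohort(shuffled)$auc_result$auc
  })
  expect_lt(abs(mean(null_auc) - 0.5), 0.03)
})
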