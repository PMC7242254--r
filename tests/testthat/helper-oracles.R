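# Brute-force oracles and tiny random-instance generators shared across
# the suite.  Oracles are deliberately naive (pair loops, exhaustive
# threshold scans) and independent of the package's own code paths.

# U statistic by direct pair counting: #{a_i > b_j} + 1/2 #{a_i == b_j}.
brute_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# AUC as the probability a positive outranks a negative.
brute_auc <- function(pos, neg) brute_u(pos, neg) / (length(pos) * length(neg))

# Best Youden J over every real threshold, by scanning a dense candidate
# grid (all observed values and midpoints, rule value > t).
brute_best_j <- function(pos, neg) {
  sv <- sort(unique(c(pos, neg)))
  cand <- c(-Inf, sv, (sv[-1] + sv[-length(sv)]) / 2, Inf)
  best <- -Inf
  for (t in cand) {
    j <- mean(pos > t) + mean(neg <= t) - 1
    if (j > best) best <- j
  }
  best
}

# Small two-class instance with heavy ties (values on a coarse grid).
rand_tied_instance <- function(max_n = 12) {
  n_pos <- sample(2:max_n, 1)
  n_neg <- sample(2:max_n, 1)
  grid <- seq(0, 5, by = 0.5)
  list(pos = sample(grid, n_pos, replace = TRUE) + sample(0:2, 1),
       neg = sample(grid, n_neg, replace = TRUE))
}

# A quick validated single record for threshold/score tests.
make_record <- function(age = 50, six_mwd = 550, sat0 = 96, sat6 = 94,
                        tlc_pct = 95, dlco_pct = 70, fvc_pct = 95,
                        vc_pct = NA_real_, ntprobnp = 60,
                        ph_group = NA_character_, id = "p1") {
  patient_record(id = id, age = age, sex = "male", diagnosis = "sarcoidosis",
                 pack_years = 5, six_mwd = six_mwd, sat0 = sat0, sat6 = sat6,
                 fev1_fvc = 78, fvc_pct = fvc_pct, vc_pct = vc_pct,
                 tlc_pct = tlc_pct, dlco_pct = dlco_pct,
                 ntprobnp = ntprobnp, ph_group = ph_group)
}
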