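#' @keywords internal
"_PACKAGE"

# Column schema for a patient cohort.  A cohort is a plain data.frame with
# one row per patient; these are the columns the pipeline knows about.
COHORT_COLUMNS <- c(
  "id", "age", "sex", "diagnosis", "pack_years", "six_mwd",
  "sat0", "sat6", "fev1_fvc", "fvc_pct", "vc_pct", "tlc_pct",
  "dlco_pct", "ntprobnp", "ph_group"
)

PH_GROUP_LEVELS <- c("A_low", "B_increased")
SEX_LEVELS <- c("male", "female")
DIAGNOSIS_LEVELS <- c("sarcoidosis", "HP", "IPF", "other-IIP")

#' Construct a single patient record
#'
#' Builds a validated one-row cohort data.frame.  Units: `age` in years,
#' `six_mwd` in metres, `sat0`/`sat6` in % oxygen saturation, `fev1_fvc`
#' the FEV1/FVC ratio times 100, the `_pct` fields in % of the predicted
#' value (DLCO haemoglobin-corrected), `ntprobnp` in pg/ml.
#'
#' @param id opaque identifier.
#' @param age age in years (>= 18).
#' @param sex `"male"` or `"female"`.
#' @param diagnosis one of `"sarcoidosis"`, `"HP"`, `"IPF"`, `"other-IIP"`.
#' @param pack_years smoking exposure in pack-years (>= 0).
#' @param six_mwd six-minute walk distance in metres (>= 0).
#' @param sat0,sat6 room-air oxygen saturation at baseline and at the sixth
#'   minute of the walk test; must satisfy `0 < sat6 <= sat0 <= 100`.
#' @param fev1_fvc FEV1/FVC ratio expressed as a percentage.
#' @param fvc_pct,tlc_pct,dlco_pct percent-predicted lung function values.
#' @param vc_pct optional percent-predicted vital capacity (`NA` if absent).
#' @param ntprobnp NT-proBNP concentration in pg/ml (>= 0).
#' @param ph_group echocardiographic PH-probability stratum, `"A_low"` or
#'   `"B_increased"`; may be `NA` when raw echo measurements are carried
#'   separately.
#' @return a one-row data.frame with the cohort schema.
#' @examples
#' patient_record(id = "p1", age = 57, sex = "male", diagnosis = "IPF",
#'                pack_years = 20, six_mwd = 480, sat0 = 95, sat6 = 89,
#'                fev1_fvc = 76, fvc_pct = 95, tlc_pct = 92, dlco_pct = 55,
#'                ntprobnp = 150, ph_group = "B_increased")
#' @export
patient_record <- function(id, age, sex, diagnosis, pack_years, six_mwd,
                           sat0, sat6, fev1_fvc, fvc_pct, tlc_pct, dlco_pct,
                           ntprobnp, vc_pct = NA_real_,
                           ph_group = NA_character_) {
  rec <- data.frame(
    id = as.character(id), age = as.numeric(age),
    sex = as.character(sex), diagnosis = as.character(diagnosis),
    pack_years = as.numeric(pack_years), six_mwd = as.numeric(six_mwd),
    sat0 = as.numeric(sat0), sat6 = as.numeric(sat6),
    fev1_fvc = as.numeric(fev1_fvc), fvc_pct = as.numeric(fvc_pct),
    vc_pct = as.numeric(vc_pct), tlc_pct = as.numeric(tlc_pct),
    dlco_pct = as.numeric(dlco_pct), ntprobnp = as.numeric(ntprobnp),
    ph_group = as.character(ph_group),
    stringsAsFactors = FALSE
  )
  bad <- validate_cohort_rows(rec)
  if (length(bad$reasons[[1]]) > 0) {
    stop("invalid patient record: ", paste(bad$reasons[[1]], collapse = "; "),
         call. = FALSE)
  }
  rec
}

# Row-wise invariant check.  Returns list(ok = logical vector,
# reasons = list of character vectors), one entry per row.
validate_cohort_rows <- function(df) {
  n <- nrow(df)
  reasons <- vector("list", n)
  chk <- function(cond, msg) {
    # cond TRUE means violation; NA never flags here (missingness is
    # handled separately by the operations that need each field)
    idx <- which(!is.na(cond) & cond)
    for (i in idx) reasons[[i]] <<- c(reasons[[i]], msg)
  }
  chk(df$age < 18, "age < 18")
  chk(df$sat0 > 100, "sat0 > 100")
  chk(df$sat6 <= 0, "sat6 <= 0")
  chk(df$sat6 > df$sat0, "sat6 > sat0")
  chk(df$six_mwd < 0, "six_mwd < 0")
  chk(df$pack_years < 0, "pack_years < 0")
  chk(df$ntprobnp < 0, "ntprobnp < 0")
  for (v in c("fvc_pct", "vc_pct", "tlc_pct", "dlco_pct", "fev1_fvc")) {
    if (v %in% names(df)) chk(df[[v]] <= 0, paste0(v, " <= 0"))
  }
  if ("sex" %in% names(df)) {
    chk(!is.na(df$sex) & !(df$sex %in% SEX_LEVELS), "unknown sex")
  }
  if ("ph_group" %in% names(df)) {
    chk(!is.na(df$ph_group) & !(df$ph_group %in% PH_GROUP_LEVELS),
        "unknown ph_group")
  }
  list(ok = lengths(reasons) == 0, reasons = reasons)
}

#' Derived pulmonary-function and walk-test indices
#'
#' Computes the dimensionless ratios of percent-predicted values,
#' `tlc_dlco = tlc_pct / dlco_pct` (the TLC/DLCO index: a disproportionate
#' DLCO reduction relative to lung volume suggests pulmonary vascular
#' disease), `fvc_dlco`, `vc_dlco` (only where `vc_pct` is present), and
#' the walk-test desaturation `sat0 - sat6` in percentage points.
#'
#' @param cohort a cohort data.frame (see [patient_record()]).
#' @return data.frame with columns `tlc_dlco`, `fvc_dlco`, `vc_dlco`,
#'   `desaturation`, one row per patient.
#' @examples
#' rec <- patient_record(id = "p1", age = 57, sex = "male",
#'                       diagnosis = "IPF", pack_years = 20, six_mwd = 480,
#'                       sat0 = 95.8, sat6 = 89.1, fev1_fvc = 76,
#'                       fvc_pct = 95, tlc_pct = 100, dlco_pct = 50,
#'                       ntprobnp = 150)
#' derive_indices(rec) # tlc_dlco = 2, desaturation = 6.7
#' @export
derive_indices <- function(cohort) {
  for (v in c("tlc_pct", "dlco_pct", "fvc_pct", "sat0", "sat6")) {
    if (!v %in% names(cohort)) {
      stop("cohort lacks required column '", v, "'", call. = FALSE)
    }
  }
  if (any(is.na(cohort$dlco_pct)) || any(cohort$dlco_pct <= 0)) {
    stop("dlco_pct must be present and > 0 for every record", call. = FALSE)
  }
  if (any(is.na(cohort$sat0)) || any(is.na(cohort$sat6))) {
    stop("sat0 and sat6 must be present for every record", call. = FALSE)
  }
  if (any(cohort$sat6 > cohort$sat0)) {
    stop("sat6 > sat0 on some record(s)", call. = FALSE)
  }
  vc <- if ("vc_pct" %in% names(cohort)) cohort$vc_pct else NA_real_
  data.frame(
    tlc_dlco = cohort$tlc_pct / cohort$dlco_pct,
    fvc_dlco = cohort$fvc_pct / cohort$dlco_pct,
    vc_dlco = vc / cohort$dlco_pct,
    desaturation = cohort$sat0 - cohort$sat6
  )
}

#' Echocardiographic PH-probability categories (2009 ESC/ERS bands)
#'
#' Maps tricuspid regurgitant velocity (TRV, m/s), estimated pulmonary
#' arterial systolic pressure (PASP, mmHg) and the presence of additional
#' echocardiographic signs of PH to a probability category.  Bands:
#' TRV <= 2.8 (PASP <= 36) without signs is `unlikely`, with signs
#' `possible`; TRV in (2.8, 3.4] (PASP in (36, 50]) is `possible`
#' regardless of signs; TRV > 3.4 (PASP > 50) is `likely`.  When both TRV
#' and PASP are given and disagree, the higher category wins (screening
#' favours sensitivity).
#'
#' @param trv peak tricuspid regurgitant jet velocity, m/s (`NA` if absent).
#' @param pasp estimated pulmonary arterial systolic pressure, mmHg
#'   (`NA` if absent).  At least one of `trv`, `pasp` must be present.
#' @param additional_signs logical; further echo signs suggestive of PH.
#' @return factor with levels `unlikely < possible < likely` (ordered).
#' @examples
#' classify_echo_probability(trv = 2.5, additional_signs = FALSE) # unlikely
#' classify_echo_probability(trv = 3.0, additional_signs = FALSE) # possible
#' classify_echo_probability(trv = 3.5, additional_signs = TRUE)  # likely
#' @export
classify_echo_probability <- function(trv = NA_real_, pasp = NA_real_,
                                      additional_signs = FALSE) {
  n <- max(length(trv), length(pasp), length(additional_signs))
  trv <- rep_len(as.numeric(trv), n)
  pasp <- rep_len(as.numeric(pasp), n)
  signs <- rep_len(as.logical(additional_signs), n)
  if (any(is.na(trv) & is.na(pasp))) {
    stop("at least one of trv, pasp must be present", call. = FALSE)
  }
  if (any(!is.na(trv) & trv <= 0) || any(!is.na(pasp) & pasp <= 0)) {
    stop("trv and pasp must be > 0 when present", call. = FALSE)
  }
  band <- function(x, lo, hi) {
    # 0 = bottom band, 1 = middle (half-open (lo, hi]), 2 = top
    ifelse(is.na(x), 0L, ifelse(x > hi, 2L, ifelse(x > lo, 1L, 0L)))
  }
  b <- pmax(band(trv, 2.8, 3.4), band(pasp, 36, 50))
  cat_idx <- ifelse(b == 2L, 3L, ifelse(b == 1L | signs, 2L, 1L))
  factor(c("unlikely", "possible", "likely")[cat_idx],
         levels = c("unlikely", "possible", "likely"), ordered = TRUE)
}

#' Declare a dichotomization threshold
#'
#' @param variable name of a cohort column or derived index
#'   (see [derive_indices()]).
#' @param cutoff cutpoint, in the variable's units.
#' @param direction `"above_is_risk"` (flag when value > cutoff) or
#'   `"below_is_risk"` (flag when value < cutoff).  Always explicit, never
#'   inferred.
#' @return an object of class `"threshold_spec"`.
#' @examples
#' threshold_spec("tlc_dlco", 1.67, "above_is_risk")
#' @export
threshold_spec <- function(variable, cutoff,
                           direction = c("above_is_risk", "below_is_risk")) {
  direction <- match.arg(direction)
  stopifnot(is.character(variable), length(variable) == 1L)
  if (!is.finite(cutoff)) stop("cutoff must be finite", call. = FALSE)
  structure(list(variable = variable, cutoff = as.numeric(cutoff),
                 direction = direction),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  op <- if (x$direction == "above_is_risk") ">" else "<"
  cat(sprintf("threshold: %s %s %g is at-risk\n", x$variable, op, x$cutoff))
  invisible(x)
}

# Fetch a variable from the cohort, deriving ratio indices on demand.
cohort_variable <- function(cohort, variable) {
  if (variable %in% names(cohort)) return(cohort[[variable]])
  derived <- c("tlc_dlco", "fvc_dlco", "vc_dlco", "desaturation")
  if (variable %in% derived) return(derive_indices(cohort)[[variable]])
  stop("unknown variable '", variable, "'", call. = FALSE)
}

#' Dichotomize a cohort variable at a threshold
#'
#' Strict inequalities throughout: a value exactly at the cutoff is never
#' at-risk, matching the published wording ("exceeding", ">", "<").
#'
#' @param cohort a cohort data.frame.
#' @param spec a [threshold_spec()].
#' @return logical vector, `TRUE` where the record is at-risk.
#' @examples
#' rec <- patient_record(id = "p1", age = 57, sex = "male",
#'                       diagnosis = "IPF", pack_years = 20, six_mwd = 480,
#'                       sat0 = 95.8, sat6 = 89.1, fev1_fvc = 76,
#'                       fvc_pct = 95, tlc_pct = 92, dlco_pct = 55,
#'                       ntprobnp = 150)
#' dichotomize(rec, threshold_spec("tlc_dlco", 1.67, "above_is_risk"))
#' @export
dichotomize <- function(cohort, spec) {
  stopifnot(inherits(spec, "threshold_spec"))
  x <- cohort_variable(cohort, spec$variable)
  if (any(is.na(x))) {
    stop("missing values in '", spec$variable,
         "'; exclude such records upstream", call. = FALSE)
  }
  if (spec$direction == "above_is_risk") x > spec$cutoff else x < spec$cutoff
}
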