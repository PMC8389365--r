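#' Reason codes of the verification rule engine
#'
#' Machine-readable causes attached to a [validation_verdict]. Codes fall into
#' two classes: *blocking* codes make a request unreportable (a new sample is
#' needed), *consultation* codes require clarification with the sender before
#' a (possibly corrected) score can be released.
#'
#' @format character vector of all defined codes, in canonical evaluation
#'   order.
#' @export
reason_codes <- c(
  # order integrity
  "MATERIAL_ERROR", "SPLIT_ORDER", "MISSING_DIALYSIS_STATUS",
  # preanalytics
  "PROLONGED_PREANALYTIC", "LATE_LAB_ENTRANCE", "UNDERFILLED_CITRATE",
  "CITRATE_CLOTTED", "PATIENT_MISIDENTIFICATION", "PELD_REQUIRED",
  # clotting
  "INR_UNDETERMINABLE",
  # dialysis plausibility
  "DIALYSIS_CRITERIA_NOT_MET", "ALBUMIN_DIALYSIS_NOT_RRT",
  "DIALYSIS_IMPLAUSIBLE", "DIALYSIS_STATUS_CORRECTED",
  # anticoagulation and delta check
  "ANTICOAGULATION_INR_IMPACT", "DELTA_CHECK_FAIL")

# Codes that make a request unreportable outright.
blocking_codes <- c("MATERIAL_ERROR", "SPLIT_ORDER", "PROLONGED_PREANALYTIC",
                    "LATE_LAB_ENTRANCE", "UNDERFILLED_CITRATE", "CITRATE_CLOTTED",
                    "PATIENT_MISIDENTIFICATION", "PELD_REQUIRED",
                    "ANTICOAGULATION_INR_IMPACT")

# Codes that route to consultation with the sender.
consultation_codes <- c("MISSING_DIALYSIS_STATUS", "DIALYSIS_CRITERIA_NOT_MET",
                        "ALBUMIN_DIALYSIS_NOT_RRT", "DIALYSIS_IMPLAUSIBLE",
                        "DELTA_CHECK_FAIL", "INR_UNDETERMINABLE")

find_specimen <- function(request, tube) {
  for (sp in request$specimens) if (sp$tube_type == tube) return(sp)
  NULL
}

#' Order-integrity check
#'
#' The MELD parameters must be ordered within the same laboratory order and
#' sent in at the same time: a serum and a citrate tube, drawn together, with
#' the dialysis status stated on the electronic order.
#'
#' @param request a [meld_request()].
#' @param config a [verification_config()].
#' @return character vector of reason codes (possibly empty).
#' @export
check_order_integrity <- function(request, config = verification_config()) {
  codes <- character(0)
  tubes <- vapply(request$specimens, `[[`, "", "tube_type")
  if (any(tubes %in% c("lithium_heparin", "ascites")) ||
      !all(c("serum", "citrate") %in% tubes)) {
    codes <- c(codes, "MATERIAL_ERROR")
  }
  serum <- find_specimen(request, "serum")
  citrate <- find_specimen(request, "citrate")
  if (!is.null(serum) && !is.null(citrate)) {
    spread_min <- abs(as.numeric(citrate$draw_time) - as.numeric(serum$draw_time)) / 60
    if (is.finite(spread_min) && spread_min > config$codraw_tolerance_min) {
      codes <- c(codes, "SPLIT_ORDER")
    }
  }
  if (is.null(request$stated_dialysis) || is.na(request$stated_dialysis$mode)) {
    codes <- c(codes, "MISSING_DIALYSIS_STATUS")
  }
  codes
}

#' Preanalytical checks
#'
#' Flags prolonged draw-to-lab intervals (> 4 h by default), late laboratory
#' entrance after order creation, underfilled or clotted citrate tubes,
#' mislabelled specimens, and patients under the MELD age limit (PELD
#' required).
#'
#' @inheritParams check_order_integrity
#' @return character vector of reason codes.
#' @export
check_preanalytics <- function(request, config = verification_config()) {
  codes <- character(0)
  required <- Filter(function(sp) sp$tube_type %in% c("serum", "citrate"),
                     request$specimens)
  hours <- function(a, b) (as.numeric(a) - as.numeric(b)) / 3600
  if (any(vapply(required, function(sp)
    isTRUE(hours(sp$lab_arrival_time, sp$draw_time) > config$preanalytic_max_h),
    logical(1)))) {
    codes <- c(codes, "PROLONGED_PREANALYTIC")
  }
  if (any(vapply(required, function(sp)
    isTRUE(hours(sp$lab_arrival_time, request$request_time) > config$late_entrance_max_h),
    logical(1)))) {
    codes <- c(codes, "LATE_LAB_ENTRANCE")
  }
  citrate <- find_specimen(request, "citrate")
  if (!is.null(citrate)) {
    if (isTRUE(citrate$fill_ratio < config$underfill_min_ratio)) {
      codes <- c(codes, "UNDERFILLED_CITRATE")
    }
    if (isTRUE(citrate$clotted)) codes <- c(codes, "CITRATE_CLOTTED")
  }
  labels <- vapply(request$specimens, `[[`, "", "labeled_patient_id")
  if (any(labels != request$patient_id)) {
    codes <- c(codes, "PATIENT_MISIDENTIFICATION")
  }
  draw <- if (length(required)) required[[1]]$draw_time else request$request_time
  if (age_years(request$birth_date, draw) < config$min_age_years) {
    codes <- c(codes, "PELD_REQUIRED")
  }
  codes
}

#' Dialysis-plausibility check
#'
#' Validates the stated dialysis status against the regulatory criteria
#' (>= 2 intermittent sessions or >= 24 h CVVHD within the prior week) and
#' against the laboratory picture: renal replacement with a near-normal serum
#' creatinine, or with a steep creatinine rise since the last validated
#' result, is implausible and triggers consultation. Albumin dialysis is not a
#' kidney replacement method.
#'
#' @inheritParams check_order_integrity
#' @param history a [patient_history()] or `NULL`.
#' @return character vector of reason codes.
#' @export
check_dialysis <- function(request, history = NULL,
                           config = verification_config()) {
  dial <- request$stated_dialysis
  if (is.null(dial) || is.na(dial$mode) || dial$mode == "none") return(character(0))
  codes <- character(0)
  if ((dial$mode == "intermittent" && dial$sessions_prior_week < 2) ||
      (dial$mode == "cvvhd" && dial$cvvhd_hours_prior_week < 24)) {
    codes <- c(codes, "DIALYSIS_CRITERIA_NOT_MET")
  }
  if (dial$mode == "albumin_dialysis") {
    codes <- c(codes, "ALBUMIN_DIALYSIS_NOT_RRT")
  } else {
    implausible <- request$panel$creatinine < config$dialysis_min_creatinine_umol
    pr <- history_before(history, request$request_time)
    if (!implausible && !is.null(pr) && nrow(pr) > 0) {
      last <- pr[nrow(pr), ]
      days <- (as.numeric(request$request_time) - as.numeric(last$timestamp)) / 86400
      if (days <= config$delta_lookback_days && is.finite(last$creatinine)) {
        rise <- (request$panel$creatinine - last$creatinine) / last$creatinine
        implausible <- rise > config$dialysis_max_rise
      }
    }
    if (implausible) codes <- c(codes, "DIALYSIS_IMPLAUSIBLE")
  }
  codes
}

# Most recent prior validated result without anticoagulation, or NULL.
anticoag_baseline <- function(history, time) {
  pr <- history_before(history, time)
  if (is.null(pr) || nrow(pr) == 0) return(NULL)
  pr <- pr[pr$anticoagulation %in% "none" & is.finite(pr$inr), , drop = FALSE]
  if (nrow(pr) == 0) return(NULL)
  pr[nrow(pr), ]
}

#' Anticoagulation influence on the INR
#'
#' Vitamin K antagonists and direct oral anticoagulants raise the INR
#' independently of liver synthesis, inflating the MELD score. Stated VKA/DOAC
#' therapy with an INR above the impact threshold blocks reporting. Unstated
#' anticoagulation is unravelled heuristically: an INR clearly above the
#' patient's non-anticoagulated baseline while the liver synthesis markers
#' (albumin, fibrinogen, cholinesterase) are unchanged points to a drug
#' effect, not to deteriorating synthesis. Heparin with an unchanged INR is
#' not blocking.
#'
#' @inheritParams check_dialysis
#' @return character vector of reason codes.
#' @export
check_anticoagulation <- function(request, history = NULL,
                                  config = verification_config()) {
  inr <- request$panel$inr
  if (is.na(inr)) return(character(0))
  base <- anticoag_baseline(history, request$request_time)
  over_baseline <- !is.null(base) &&
    inr > config$anticoag_baseline_ratio * base$inr
  ac <- request$stated_anticoagulation
  if (ac %in% c("vka", "doac")) {
    if (inr > config$anticoag_inr_abs || over_baseline) {
      return("ANTICOAGULATION_INR_IMPACT")
    }
    return(character(0))
  }
  # unstated / heparin: an INR rise with unchanged synthesis markers
  if (over_baseline) {
    tol <- config$synthesis_tolerance
    markers <- c("albumin", "fibrinogen", "cholinesterase")
    now <- unlist(request$panel[markers])
    then <- unlist(base[markers])
    comparable <- is.finite(now) & is.finite(then)
    if (any(comparable)) {
      unchanged <- abs(now[comparable] / then[comparable] - 1) <= tol
      if (all(unchanged)) return("ANTICOAGULATION_INR_IMPACT")
    }
  }
  character(0)
}

#' Delta check against the previous validated result
#'
#' An improbable change in creatinine, bilirubin or INR relative to the most
#' recent prior validated result within the lookback window (default 7 days)
#' triggers consultation. With no usable prior result the check passes.
#'
#' @param panel an [analyte_panel()].
#' @param history a [patient_history()] or `NULL`.
#' @param at time of the current request (used against history timestamps).
#' @param config a [verification_config()].
#' @return character vector of reason codes.
#' @export
delta_check <- function(panel, history, at, config = verification_config()) {
  pr <- history_before(history, at)
  if (is.null(pr) || nrow(pr) == 0) return(character(0))
  last <- pr[nrow(pr), ]
  days <- (as.numeric(at) - as.numeric(last$timestamp)) / 86400
  if (days > config$delta_lookback_days) return(character(0))
  th <- config$delta_thresholds
  rel <- function(new, old) if (is.finite(old) && old > 0 && is.finite(new))
    abs(new - old) / old else 0
  if (rel(panel$creatinine, last$creatinine) > th[["creatinine"]] ||
      rel(panel$bilirubin, last$bilirubin) > th[["bilirubin"]] ||
      rel(panel$inr, last$inr) > th[["inr"]]) {
    return("DELTA_CHECK_FAIL")
  }
  character(0)
}

#' Resolve an undeterminable INR
#'
#' When the coagulometer detects no clot within its timeout the INR cannot be
#' measured. The resolution policy decides what, if anything, is reported:
#' `"last_determinable"` accepts the patient's most recent prior measured INR
#' (the advisory-committee practice), `"table_max"` reports the INR at the
#' maximum of the instrument's prothrombin-time conversion table, `"block"`
#' refuses to report. A manual interpretation of the clotting curve yields a
#' usable INR but is still flagged for laboratory-physician review.
#'
#' @param clotting a [clotting_result()].
#' @param history a [patient_history()] or `NULL`.
#' @param policy resolution policy, see [verification_config()].
#' @param config a [verification_config()] (supplies the conversion-table
#'   maximum and the default policy).
#' @return list with elements `inr` (numeric or `NA`), `blocked` (logical)
#'   and `codes` (character vector).
#' @export
resolve_inr <- function(clotting, history = NULL, policy = NULL,
                        config = verification_config()) {
  if (is.null(policy)) policy <- config$inr_policy
  policy <- match.arg(policy, c("last_determinable", "table_max", "block"))
  if (clotting$status == "clot_detected") {
    return(list(inr = clotting$inr, blocked = FALSE, codes = character(0)))
  }
  if (clotting$status == "manual_curve_read") {
    return(list(inr = clotting$inr, blocked = FALSE, codes = "INR_UNDETERMINABLE",
                note = "INR from manual interpretation of the clotting curve"))
  }
  # no clot within timeout
  if (policy == "table_max") {
    return(list(inr = config$conversion_table_max_inr, blocked = FALSE,
                codes = "INR_UNDETERMINABLE",
                note = "INR from conversion-table maximum"))
  }
  if (policy == "last_determinable") {
    pr <- if (!is.null(history)) history$prior else NULL
    if (!is.null(pr) && nrow(pr) > 0) {
      inr_prior <- pr$inr[is.finite(pr$inr)]
      if (length(inr_prior) > 0) {
        return(list(inr = inr_prior[length(inr_prior)], blocked = FALSE,
                    codes = "INR_UNDETERMINABLE",
                    note = "last determinable INR carried forward"))
      }
    }
    return(list(inr = NA_real_, blocked = TRUE, codes = "INR_UNDETERMINABLE"))
  }
  list(inr = NA_real_, blocked = TRUE, codes = "INR_UNDETERMINABLE")
}
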