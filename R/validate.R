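new_verdict <- function(disposition, reasons, corrections = list(),
                        result = NULL, provisional = NULL, narrative = "") {
  structure(
    list(disposition = disposition, reasons = reasons, corrections = corrections,
         result = result, provisional = provisional, narrative = narrative),
    class = "validation_verdict")
}

verdict_narrative <- function(disposition, reasons) {
  switch(disposition,
         VALID = "MELD diagnostic fulfilled all quality criteria; score released.",
         CORRECTED_VALID = paste("Score released after correction;",
                                 paste(reasons, collapse = ", ")),
         INVALID = paste("MELD score not reportable:",
                         paste(reasons, collapse = ", ")),
         NEEDS_CONSULTATION = paste("Consultation with sender required:",
                                    paste(reasons, collapse = ", ")))
}

#' Validate one MELD request
#'
#' Runs the full verification sequence: order integrity, preanalytics, INR
#' resolution, dialysis plausibility, anticoagulation influence, delta check
#' (in that fixed order), then maps the collected reason codes to a
#' disposition. Blocking codes (material or preanalytical errors, patient
#' misidentification, PELD routing, anticoagulation impact, an unresolvable
#' INR) yield `INVALID`: no score is released and a new sample is required.
#' Dialysis findings, delta-check failures and resolved-but-flagged INRs yield
#' `NEEDS_CONSULTATION`; [apply_correction()] can then release a corrected
#' score. A request without findings is `VALID` and carries the computed
#' [compute_meld()] result (with MELD-Na when sodium was measured).
#'
#' @param request a [meld_request()].
#' @param history a [patient_history()] of prior validated results, or `NULL`.
#' @param config a [verification_config()].
#' @return a `validation_verdict`: `disposition`, ordered `reasons`,
#'   `corrections`, `result` (only for `VALID`/`CORRECTED_VALID`),
#'   `provisional` (the not-yet-releasable score of consultation cases) and a
#'   `narrative`.
#' @export
validate_request <- function(request, history = NULL,
                             config = verification_config()) {
  stopifnot(inherits(request, "meld_request"))
  snapshot <- NULL
  if (!is.null(history)) {
    stopifnot(inherits(history, "patient_history"))
    pr <- history_before(history, request$request_time)
    snapshot <- structure(list(patient_id = history$patient_id, prior = pr),
                          class = "patient_history")
  }

  codes <- check_order_integrity(request, config)
  codes <- c(codes, check_preanalytics(request, config))

  res_inr <- resolve_inr(request$clotting, snapshot, config = config)
  codes <- c(codes, res_inr$codes)

  panel <- request$panel
  panel$inr <- res_inr$inr

  if (!is.null(request$stated_dialysis) && !is.na(request$stated_dialysis$mode)) {
    codes <- c(codes, check_dialysis(request, snapshot, config))
  }
  req_resolved <- request
  req_resolved$panel <- panel
  codes <- c(codes, check_anticoagulation(req_resolved, snapshot, config))
  codes <- c(codes, delta_check(panel, snapshot, request$request_time, config))
  codes <- unique(codes)

  score_now <- function() {
    dial <- request$stated_dialysis
    if (is.null(dial) || is.na(dial$mode)) dial <- dialysis_status("none")
    m <- compute_meld(panel, dial, config$coefficients)
    compute_meld_na(m, panel$sodium, config$coefficients)
  }

  if (res_inr$blocked || any(codes %in% blocking_codes)) {
    return(new_verdict("INVALID", codes,
                       narrative = verdict_narrative("INVALID", codes)))
  }
  if (any(codes %in% consultation_codes)) {
    return(new_verdict("NEEDS_CONSULTATION", codes, provisional = score_now(),
                       narrative = verdict_narrative("NEEDS_CONSULTATION", codes)))
  }
  new_verdict("VALID", character(0), result = score_now(),
              narrative = verdict_narrative("VALID", character(0)))
}

#' Validate a whole cohort
#'
#' @param requests list of [meld_request()] objects, or a `cohort_bundle` from
#'   [simulate_cohort()].
#' @param histories named list of [patient_history()] objects keyed by patient
#'   id (ignored when a bundle is given).
#' @param config a [verification_config()].
#' @return list of `validation_verdict` objects, one per request.
#' @export
validate_cohort <- function(requests, histories = NULL,
                            config = verification_config()) {
  if (inherits(requests, "cohort_bundle")) {
    histories <- requests$histories
    requests <- requests$requests
  }
  lapply(requests, function(rq) {
    validate_request(rq, histories[[rq$patient_id]], config)
  })
}

same_dialysis <- function(a, b) {
  identical(a$mode, b$mode) &&
    isTRUE(a$sessions_prior_week == b$sessions_prior_week) &&
    isTRUE(a$cvvhd_hours_prior_week == b$cvvhd_hours_prior_week)
}

#' Release a corrected score after dialysis consultation
#'
#' When consultation with the sender (and the dialysis unit) establishes the
#' true renal-replacement status, the request is re-scored with the confirmed
#' status. A confirmed status that itself fails the regulatory criteria keeps
#' the request in consultation; a confirmed status identical to the stated one
#' returns the verdict unchanged.
#'
#' @param request the original [meld_request()].
#' @param verdict its `NEEDS_CONSULTATION` verdict carrying a dialysis reason.
#' @param confirmed_dialysis the [dialysis_status()] established in
#'   consultation (use mode `"none"` when dialysis was not performed as
#'   required).
#' @param history,config as in [validate_request()].
#' @return an updated `validation_verdict`, `CORRECTED_VALID` on success, with
#'   the corrections map recording the stated and confirmed status and
#'   `DIALYSIS_STATUS_CORRECTED` appended to the reasons.
#' @export
apply_correction <- function(request, verdict, confirmed_dialysis,
                             history = NULL, config = verification_config()) {
  stopifnot(inherits(verdict, "validation_verdict"),
            inherits(confirmed_dialysis, "dialysis_status"))
  dialysis_reasons <- c("MISSING_DIALYSIS_STATUS", "DIALYSIS_CRITERIA_NOT_MET",
                        "DIALYSIS_IMPLAUSIBLE", "ALBUMIN_DIALYSIS_NOT_RRT")
  if (verdict$disposition != "NEEDS_CONSULTATION" ||
      !any(verdict$reasons %in% dialysis_reasons)) {
    stop("apply_correction() expects a NEEDS_CONSULTATION verdict with a ",
         "dialysis reason", call. = FALSE)
  }
  stated <- request$stated_dialysis
  if (!is.null(stated) && !is.na(stated$mode) &&
      same_dialysis(stated, confirmed_dialysis)) {
    return(verdict)
  }
  if (confirmed_dialysis$mode != "none" && !dialysis_qualifies(confirmed_dialysis) &&
      confirmed_dialysis$mode != "albumin_dialysis") {
    verdict$narrative <- paste("Confirmed dialysis status still fails the",
                               "official criteria; consultation continues.")
    return(verdict)
  }
  if (confirmed_dialysis$mode == "albumin_dialysis") {
    confirmed_dialysis <- dialysis_status("none")  # not a renal replacement
  }
  panel <- request$panel
  if (is.na(panel$inr) && !is.null(verdict$provisional)) {
    panel$inr <- verdict$provisional$inr_used
  }
  m <- compute_meld(panel, confirmed_dialysis, config$coefficients)
  m <- compute_meld_na(m, panel$sodium, config$coefficients)
  reasons <- c(setdiff(verdict$reasons, "DIALYSIS_STATUS_CORRECTED"),
               "DIALYSIS_STATUS_CORRECTED")
  corr <- list(stated_dialysis = list(
    old = if (is.null(stated) || is.na(stated$mode)) "not stated" else stated$mode,
    new = confirmed_dialysis$mode))
  new_verdict("CORRECTED_VALID", reasons, corrections = corr, result = m,
              provisional = verdict$provisional,
              narrative = verdict_narrative("CORRECTED_VALID", reasons))
}

#' @export
print.validation_verdict <- function(x, ...) {
  cat(sprintf("<%s>", x$disposition))
  if (length(x$reasons)) cat(" ", paste(x$reasons, collapse = ", "))
  cat("\n", x$narrative, "\n", sep = "")
  if (!is.null(x$result)) print(x$result)
  invisible(x)
}
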