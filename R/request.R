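#' @keywords internal
parse_ts <- function(x, what = "timestamp") {
  if (inherits(x, "POSIXct")) return(x)
  if (length(x) == 0 || is.na(x) || !nzchar(x)) return(as.POSIXct(NA))
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"),
                    optional = TRUE)
  if (is.na(out)) stop("unparseable ", what, ": '", x, "'", call. = FALSE)
  out
}

format_ts <- function(x) {
  if (is.null(x) || is.na(x)) return(NA_character_)
  format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

#' One blood specimen of a MELD order
#'
#' MELD diagnostics require a serum tube (bilirubin, creatinine, sodium) and a
#' citrate tube (prothrombin time / INR). Lithium-heparin or ascites material
#' is not acceptable. The citrate fill ratio matters because underfilling
#' distorts the citrate-to-blood mixing ratio and falsely raises the INR.
#'
#' @param specimen_id specimen barcode.
#' @param tube_type one of `"serum"`, `"citrate"`, `"lithium_heparin"`,
#'   `"ascites"`, `"other"`.
#' @param labeled_patient_id patient id printed on the tube.
#' @param draw_time,lab_arrival_time ISO-8601 timestamps (single-site clock).
#' @param fill_ratio fraction of nominal tube volume (citrate tubes).
#' @param clotted logical, visible clot in the citrate tube.
#' @return an object of class `specimen`.
#' @export
specimen <- function(specimen_id, tube_type, labeled_patient_id,
                     draw_time, lab_arrival_time,
                     fill_ratio = NA_real_, clotted = FALSE) {
  tube_type <- match.arg(tube_type,
                         c("serum", "citrate", "lithium_heparin", "ascites", "other"))
  draw_time <- parse_ts(draw_time, paste0("draw_time of specimen ", specimen_id))
  lab_arrival_time <- parse_ts(lab_arrival_time,
                               paste0("lab_arrival_time of specimen ", specimen_id))
  if (!is.na(draw_time) && !is.na(lab_arrival_time) && lab_arrival_time < draw_time) {
    stop("specimen ", specimen_id, ": lab_arrival_time precedes draw_time",
         call. = FALSE)
  }
  if (!is.na(fill_ratio) && (fill_ratio < 0 || fill_ratio > 1.2)) {
    stop("fill_ratio must lie in [0, 1.2]", call. = FALSE)
  }
  structure(
    list(specimen_id = as.character(specimen_id), tube_type = tube_type,
         labeled_patient_id = as.character(labeled_patient_id),
         draw_time = draw_time, lab_arrival_time = lab_arrival_time,
         fill_ratio = as.numeric(fill_ratio), clotted = isTRUE(clotted)),
    class = "specimen")
}

#' Raw clotting (prothrombin time) result
#'
#' In advanced liver failure the coagulometer may detect no clot within its
#' timeout (default 315 s); the INR is then undeterminable and must be resolved
#' by policy ([resolve_inr()]). A manual interpretation of the clotting curve
#' by the laboratory physician yields an INR but is flagged for review.
#'
#' @param status `"clot_detected"`, `"no_clot_within_timeout"` or
#'   `"manual_curve_read"`.
#' @param pt_seconds measured prothrombin time in seconds (`NA` on timeout).
#' @param inr derived INR; must be absent on timeout, present on manual read.
#' @param timeout_seconds instrument waiting time for the clotting reaction.
#' @return an object of class `clotting_result`.
#' @export
clotting_result <- function(status = "clot_detected", pt_seconds = NA_real_,
                            inr = NA_real_, timeout_seconds = 315) {
  status <- match.arg(status,
                      c("clot_detected", "no_clot_within_timeout", "manual_curve_read"))
  if (status == "no_clot_within_timeout" && !is.na(inr)) {
    stop("no clot within timeout implies an absent INR", call. = FALSE)
  }
  if (status == "manual_curve_read" && is.na(inr)) {
    stop("a manual curve read must supply an INR", call. = FALSE)
  }
  structure(
    list(status = status, pt_seconds = as.numeric(pt_seconds),
         inr = as.numeric(inr), timeout_seconds = as.numeric(timeout_seconds)),
    class = "clotting_result")
}

#' One electronically ordered MELD diagnostic
#'
#' @param order_id laboratory order id (unique per request).
#' @param patient_id administrative patient id.
#' @param birth_date patient date of birth (`Date` or `"YYYY-MM-DD"`).
#' @param sex `"f"` or `"m"`.
#' @param request_time ISO-8601 time of electronic order creation.
#' @param specimens list of [specimen()] objects.
#' @param panel an [analyte_panel()].
#' @param clotting a [clotting_result()]; when omitted it is inferred from the
#'   panel INR (clot detected when the INR is present).
#' @param stated_dialysis a [dialysis_status()], or `NULL`/`mode = NA` when the
#'   sender did not state the status.
#' @param stated_anticoagulation one of `"none"`, `"heparin"`, `"vka"`,
#'   `"doac"`, `"fondaparinux"`, `"unknown"`.
#' @param anticoagulant_drug optional free-text drug name.
#' @return an object of class `meld_request`.
#' @export
meld_request <- function(order_id, patient_id, birth_date, sex, request_time,
                         specimens, panel, clotting = NULL,
                         stated_dialysis = dialysis_status("none"),
                         stated_anticoagulation = "none",
                         anticoagulant_drug = NA_character_) {
  stopifnot(inherits(panel, "analyte_panel"))
  stated_anticoagulation <- match.arg(
    stated_anticoagulation,
    c("none", "heparin", "vka", "doac", "fondaparinux", "unknown"))
  if (is.null(clotting)) {
    clotting <- if (is.na(panel$inr)) {
      clotting_result("no_clot_within_timeout")
    } else {
      clotting_result("clot_detected", pt_seconds = 12 * panel$inr, inr = panel$inr)
    }
  }
  stopifnot(inherits(clotting, "clotting_result"))
  if (!is.null(stated_dialysis)) stopifnot(inherits(stated_dialysis, "dialysis_status"))
  if (length(specimens) == 0) stop("a processable request needs specimens", call. = FALSE)
  structure(
    list(order_id = as.character(order_id), patient_id = as.character(patient_id),
         birth_date = as.Date(birth_date), sex = match.arg(sex, c("f", "m")),
         request_time = parse_ts(request_time, "request_time"),
         specimens = specimens, panel = panel, clotting = clotting,
         stated_dialysis = stated_dialysis,
         stated_anticoagulation = stated_anticoagulation,
         anticoagulant_drug = anticoagulant_drug),
    class = "meld_request")
}

#' Prior validated results of one patient
#'
#' The verification rules compare a request against the patient's previously
#' *validated* results: the delta check, the anticoagulation baseline and the
#' last-determinable-INR policy all read from this history.
#'
#' @param patient_id patient id.
#' @param prior data frame with one row per prior validated request, columns
#'   `timestamp` (POSIXct or ISO string), `bilirubin`, `creatinine`, `inr`,
#'   optionally `albumin`, `fibrinogen`, `cholinesterase`,
#'   `anticoagulation`, `dialysis_mode`, `meld`. Rows must be in strictly
#'   increasing time order.
#' @return an object of class `patient_history`.
#' @export
patient_history <- function(patient_id, prior = NULL) {
  if (is.null(prior) || nrow(prior) == 0) {
    prior <- data.frame(timestamp = as.POSIXct(character(0), tz = "UTC"),
                        bilirubin = numeric(0), creatinine = numeric(0),
                        inr = numeric(0))
  }
  if (!inherits(prior$timestamp, "POSIXct")) {
    prior$timestamp <- as.POSIXct(prior$timestamp, tz = "UTC")
  }
  if (is.unsorted(as.numeric(prior$timestamp), strictly = TRUE)) {
    stop("history timestamps must be strictly increasing", call. = FALSE)
  }
  n <- nrow(prior)
  for (col in c("albumin", "fibrinogen", "cholinesterase")) {
    if (is.null(prior[[col]])) prior[[col]] <- rep(NA_real_, n)
  }
  if (is.null(prior$anticoagulation)) prior$anticoagulation <- rep("none", n)
  if (is.null(prior$dialysis_mode)) prior$dialysis_mode <- rep("none", n)
  if (is.null(prior$meld)) prior$meld <- rep(NA_integer_, n)
  structure(list(patient_id = as.character(patient_id), prior = prior),
            class = "patient_history")
}

# Rows of a history strictly before a time point (most recent last).
history_before <- function(history, time) {
  if (is.null(history)) return(NULL)
  pr <- history$prior
  pr[as.numeric(pr$timestamp) < as.numeric(time), , drop = FALSE]
}

# Age in completed years at a reference date, calendar arithmetic.
age_years <- function(birth_date, at) {
  birth <- as.POSIXlt(as.Date(birth_date))
  ref <- as.POSIXlt(as.Date(at))
  age <- ref$year - birth$year
  before_birthday <- ref$mon < birth$mon |
    (ref$mon == birth$mon & ref$mday < birth$mday)
  age - as.integer(before_birthday)
}
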