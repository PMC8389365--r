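request_csv_columns <- c(
  "order_id", "patient_id", "birth_date", "sex", "request_time",
  "serum_specimen_id", "serum_tube_type", "serum_labeled_patient_id",
  "serum_draw_time", "serum_arrival_time",
  "citrate_specimen_id", "citrate_tube_type", "citrate_labeled_patient_id",
  "citrate_draw_time", "citrate_arrival_time", "citrate_fill_ratio",
  "citrate_clotted",
  "bilirubin_umol_l", "creatinine_umol_l", "inr", "sodium_mmol_l",
  "albumin_g_l", "fibrinogen_g_l", "cholinesterase_ku_l",
  "clotting_status", "pt_seconds",
  "dialysis_mode", "dialysis_sessions_prior_week", "cvvhd_hours_prior_week",
  "anticoagulation", "anticoagulant_drug")

request_to_row <- function(rq) {
  slot <- function(tube) {
    for (sp in rq$specimens) {
      if ((tube == "serum" && sp$tube_type %in% c("serum", "lithium_heparin",
                                                  "ascites", "other")) ||
        (tube == "citrate" && sp$tube_type == "citrate")) return(sp)
    }
    NULL
  }
  serum <- slot("serum"); citrate <- slot("citrate")
  sfield <- function(sp, f, default = NA) if (is.null(sp)) default else sp[[f]]
  dial <- rq$stated_dialysis
  data.frame(
    order_id = rq$order_id, patient_id = rq$patient_id,
    birth_date = as.character(rq$birth_date), sex = rq$sex,
    request_time = format_ts(rq$request_time),
    serum_specimen_id = sfield(serum, "specimen_id", NA_character_),
    serum_tube_type = sfield(serum, "tube_type", NA_character_),
    serum_labeled_patient_id = sfield(serum, "labeled_patient_id", NA_character_),
    serum_draw_time = if (is.null(serum)) NA_character_ else format_ts(serum$draw_time),
    serum_arrival_time = if (is.null(serum)) NA_character_ else format_ts(serum$lab_arrival_time),
    citrate_specimen_id = sfield(citrate, "specimen_id", NA_character_),
    citrate_tube_type = sfield(citrate, "tube_type", NA_character_),
    citrate_labeled_patient_id = sfield(citrate, "labeled_patient_id", NA_character_),
    citrate_draw_time = if (is.null(citrate)) NA_character_ else format_ts(citrate$draw_time),
    citrate_arrival_time = if (is.null(citrate)) NA_character_ else format_ts(citrate$lab_arrival_time),
    citrate_fill_ratio = sfield(citrate, "fill_ratio", NA_real_),
    citrate_clotted = sfield(citrate, "clotted", NA),
    bilirubin_umol_l = rq$panel$bilirubin, creatinine_umol_l = rq$panel$creatinine,
    inr = rq$panel$inr, sodium_mmol_l = rq$panel$sodium,
    albumin_g_l = rq$panel$albumin, fibrinogen_g_l = rq$panel$fibrinogen,
    cholinesterase_ku_l = rq$panel$cholinesterase,
    clotting_status = rq$clotting$status, pt_seconds = rq$clotting$pt_seconds,
    dialysis_mode = if (is.null(dial)) NA_character_ else dial$mode,
    dialysis_sessions_prior_week = if (is.null(dial)) NA_real_ else dial$sessions_prior_week,
    cvvhd_hours_prior_week = if (is.null(dial)) NA_real_ else dial$cvvhd_hours_prior_week,
    anticoagulation = rq$stated_anticoagulation,
    anticoagulant_drug = rq$anticoagulant_drug,
    stringsAsFactors = FALSE)
}

row_to_request <- function(row) {
  specimens <- list()
  if (!is.na(row$serum_specimen_id)) {
    specimens <- c(specimens, list(specimen(
      row$serum_specimen_id, row$serum_tube_type, row$serum_labeled_patient_id,
      row$serum_draw_time, row$serum_arrival_time)))
  }
  if (!is.na(row$citrate_specimen_id)) {
    specimens <- c(specimens, list(specimen(
      row$citrate_specimen_id, row$citrate_tube_type,
      row$citrate_labeled_patient_id, row$citrate_draw_time,
      row$citrate_arrival_time, fill_ratio = row$citrate_fill_ratio,
      clotted = isTRUE(row$citrate_clotted))))
  }
  panel <- analyte_panel(row$bilirubin_umol_l, row$creatinine_umol_l,
                         inr = row$inr, sodium = row$sodium_mmol_l,
                         albumin = row$albumin_g_l, fibrinogen = row$fibrinogen_g_l,
                         cholinesterase = row$cholinesterase_ku_l)
  clotting <- clotting_result(row$clotting_status, pt_seconds = row$pt_seconds,
                              inr = row$inr)
  dial <- if (is.na(row$dialysis_mode)) {
    dialysis_status(NA)
  } else {
    dialysis_status(row$dialysis_mode,
                    sessions_prior_week = row$dialysis_sessions_prior_week,
                    cvvhd_hours_prior_week = row$cvvhd_hours_prior_week)
  }
  meld_request(row$order_id, row$patient_id, row$birth_date, row$sex,
               row$request_time, specimens, panel, clotting = clotting,
               stated_dialysis = dial,
               stated_anticoagulation = row$anticoagulation,
               anticoagulant_drug = row$anticoagulant_drug)
}

#' Write / read MELD requests as CSV
#'
#' One row per request; specimen columns are prefixed `serum_`/`citrate_`,
#' concentrations carry their unit in the header (`bilirubin_umol_l`, ...).
#'
#' @param requests list of [meld_request()] objects (or a `cohort_bundle`).
#' @param path output/input file.
#' @return `write_requests_csv` returns `path` invisibly; `read_requests_csv`
#'   returns a list of `meld_request` objects.
#' @export
write_requests_csv <- function(requests, path) {
  if (inherits(requests, "cohort_bundle")) requests <- requests$requests
  rows <- do.call(rbind, lapply(requests, request_to_row))
  utils::write.csv(rows[, request_csv_columns], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_requests_csv
#' @export
read_requests_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  missing <- setdiff(request_csv_columns, names(df))
  if (length(missing)) {
    stop("request CSV lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) row_to_request(df[i, , drop = FALSE]))
}

request_to_list <- function(rq) {
  specimens <- lapply(rq$specimens, function(sp) list(
    specimen_id = sp$specimen_id, tube_type = sp$tube_type,
    labeled_patient_id = sp$labeled_patient_id,
    draw_time = format_ts(sp$draw_time),
    lab_arrival_time = format_ts(sp$lab_arrival_time),
    fill_ratio = sp$fill_ratio, clotted = sp$clotted))
  list(order_id = rq$order_id, patient_id = rq$patient_id,
       birth_date = as.character(rq$birth_date), sex = rq$sex,
       request_time = format_ts(rq$request_time),
       specimens = specimens,
       panel = unclass(rq$panel),
       clotting = unclass(rq$clotting),
       stated_dialysis = if (is.null(rq$stated_dialysis)) NULL
                         else unclass(rq$stated_dialysis),
       stated_anticoagulation = rq$stated_anticoagulation,
       anticoagulant_drug = rq$anticoagulant_drug)
}

#' Write / read MELD requests as nested JSON
#'
#' @inheritParams write_requests_csv
#' @export
write_requests_json <- function(requests, path) {
  if (inherits(requests, "cohort_bundle")) requests <- requests$requests
  jsonlite::write_json(lapply(requests, request_to_list), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_requests_json
#' @export
read_requests_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(x) {
    num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
    specimens <- lapply(x$specimens, function(sp) specimen(
      sp$specimen_id, sp$tube_type, sp$labeled_patient_id,
      sp$draw_time, sp$lab_arrival_time,
      fill_ratio = num(sp$fill_ratio), clotted = isTRUE(sp$clotted)))
    panel <- analyte_panel(num(x$panel$bilirubin), num(x$panel$creatinine),
                           inr = num(x$panel$inr), sodium = num(x$panel$sodium),
                           albumin = num(x$panel$albumin),
                           fibrinogen = num(x$panel$fibrinogen),
                           cholinesterase = num(x$panel$cholinesterase))
    clotting <- clotting_result(x$clotting$status,
                                pt_seconds = num(x$clotting$pt_seconds),
                                inr = num(x$clotting$inr),
                                timeout_seconds = num(x$clotting$timeout_seconds))
    dial <- if (is.null(x$stated_dialysis) || is.null(x$stated_dialysis$mode)) {
      dialysis_status(NA)
    } else {
      dialysis_status(x$stated_dialysis$mode,
                      sessions_prior_week = num(x$stated_dialysis$sessions_prior_week),
                      cvvhd_hours_prior_week = num(x$stated_dialysis$cvvhd_hours_prior_week))
    }
    meld_request(x$order_id, x$patient_id, x$birth_date, x$sex, x$request_time,
                 specimens, panel, clotting = clotting, stated_dialysis = dial,
                 stated_anticoagulation = x$stated_anticoagulation,
                 anticoagulant_drug = if (is.null(x$anticoagulant_drug))
                   NA_character_ else x$anticoagulant_drug)
  })
}

#' Write verdict reports as JSON
#'
#' One [render_report()] document per request.
#'
#' @param verdicts list of `validation_verdict` objects.
#' @param requests matching list of [meld_request()] objects.
#' @param path output file.
#' @export
write_verdicts_json <- function(verdicts, requests, path) {
  stopifnot(length(verdicts) == length(requests))
  docs <- Map(render_report, verdicts, requests)
  jsonlite::write_json(docs, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}
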