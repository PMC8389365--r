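#' Summarise a validated cohort
#'
#' Counts dispositions and reason codes, derives the headline rates (flagged,
#' unreported, first-pass valid — percentages half-up to one decimal), the
#' median score before and after dialysis corrections, and the dialysis
#' prevalence among reportable scores overall and by sex. Unresolved
#' `NEEDS_CONSULTATION` verdicts count as unreported: without consultation no
#' score may leave the laboratory.
#'
#' @param verdicts list of `validation_verdict` objects (after any
#'   [apply_correction()] calls).
#' @param requests the matching list of [meld_request()] objects.
#' @return an object of class `cohort_summary`.
#' @export
summarize_cohort <- function(verdicts, requests) {
  n <- length(verdicts)
  if (n == 0) stop("cannot summarise an empty cohort", call. = FALSE)
  if (n != length(requests)) {
    stop("one verdict per request required: got ", n, " verdicts for ",
         length(requests), " requests", call. = FALSE)
  }
  disp <- vapply(verdicts, `[[`, "", "disposition")
  n_valid <- sum(disp == "VALID")
  n_corrected <- sum(disp == "CORRECTED_VALID")
  n_consult <- sum(disp == "NEEDS_CONSULTATION")
  n_invalid <- sum(disp == "INVALID") + n_consult

  all_reasons <- unlist(lapply(verdicts, `[[`, "reasons"))
  reason_counts <- integer(length(reason_codes))
  names(reason_counts) <- reason_codes
  if (length(all_reasons)) {
    tab <- table(all_reasons)
    reason_counts[names(tab)] <- as.integer(tab)
  }

  corrected <- which(disp == "CORRECTED_VALID")
  med <- function(x) if (length(x)) stats::median(x) else NA_real_
  score_before <- med(vapply(verdicts[corrected], function(v)
    if (!is.null(v$provisional)) as.numeric(v$provisional$score) else NA_real_,
    numeric(1)))
  score_after <- med(vapply(verdicts[corrected], function(v)
    as.numeric(v$result$score), numeric(1)))

  reported <- which(disp %in% c("VALID", "CORRECTED_VALID"))
  dial <- vapply(verdicts[reported], function(v)
    isTRUE(v$result$dialysis_override_applied), logical(1))
  sex <- vapply(requests[reported], `[[`, "", "sex")
  dial_pct <- function(keep) {
    if (!any(keep)) return(NA_real_)
    pct(sum(dial[keep]), sum(keep))
  }

  structure(
    list(n_requests = n, n_valid = n_valid, n_corrected = n_corrected,
         n_invalid = n_invalid, n_needs_consultation = n_consult,
         reason_counts = reason_counts,
         pct_valid = pct(n_valid, n),
         pct_flagged = pct(n - n_valid, n),
         pct_unreported = pct(n_invalid, n),
         pct_reported = pct(n_valid + n_corrected, n),
         median_score_before_correction = score_before,
         median_score_after_correction = score_after,
         dialysis_pct_overall = dial_pct(rep(TRUE, length(dial))),
         dialysis_pct_women = dial_pct(sex == "f"),
         dialysis_pct_men = dial_pct(sex == "m")),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("%d MELD requests: %d valid (%.1f%%), %d corrected, %d unreported (%.1f%%); flagged %.1f%%\n",
              x$n_requests, x$n_valid, x$pct_valid, x$n_corrected,
              x$n_invalid, x$pct_unreported, x$pct_flagged))
  nz <- x$reason_counts[x$reason_counts > 0]
  if (length(nz)) {
    cat("reason codes:\n")
    for (i in seq_along(nz)) cat(sprintf("  %-28s %d\n", names(nz)[i], nz[i]))
  }
  invisible(x)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Association helper for cohort tables such as dialysis by sex. Uncorrected
#' Pearson statistic by default (1 df); Yates continuity correction is
#' available via `continuity`.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @param continuity apply the Yates correction.
#' @return list with `statistic`, `df` and `p_value`.
#' @examples
#' chi_square_2x2(matrix(c(253, 2380, 305, 4332), nrow = 2))
#' @export
chi_square_2x2 <- function(table, continuity = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("a 2x2 table is required", call. = FALSE)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all margins must be positive", call. = FALSE)
  }
  ht <- stats::chisq.test(table, correct = continuity)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Render the reporting document for one request
#'
#' Builds the result document transferred onward to the transplant
#' organisation: identifiers, the MELD parameters in both unit systems, the
#' score (only when the verdict releases one), the dialysis status including
#' any correction, the disposition and the ordered reason codes. Field order
#' is stable.
#'
#' @param verdict a final `validation_verdict`.
#' @param request the matching [meld_request()].
#' @param format `"list"`, `"json"` or `"text"`.
#' @return named list, JSON string, or character vector of lines.
#' @export
render_report <- function(verdict, request, format = c("list", "json", "text")) {
  format <- match.arg(format)
  dial <- request$stated_dialysis
  doc <- list(
    order_id = request$order_id,
    patient_id = request$patient_id,
    birth_date = as.character(request$birth_date),
    sex = request$sex,
    request_time = format_ts(request$request_time),
    disposition = verdict$disposition,
    reasons = as.list(verdict$reasons),
    analytes = list(
      bilirubin_umol_l = request$panel$bilirubin,
      creatinine_umol_l = request$panel$creatinine,
      inr = request$panel$inr,
      sodium_mmol_l = request$panel$sodium),
    dialysis_status = list(
      stated = if (is.null(dial) || is.na(dial$mode)) "not stated" else dial$mode))
  if (length(verdict$corrections)) {
    doc$dialysis_status$corrected_to <- verdict$corrections$stated_dialysis$new
  }
  if (!is.null(verdict$result)) {
    r <- verdict$result
    doc$score <- r$score
    doc$score_components <- list(
      bilirubin_mgdl = r$bilirubin_mgdl, creatinine_mgdl = r$creatinine_mgdl,
      inr_used = r$inr_used,
      dialysis_override_applied = r$dialysis_override_applied,
      clamps_applied = as.list(r$clamps_applied))
    if (!is.na(r$meld_na)) doc$meld_na <- r$meld_na
  }
  doc$narrative <- verdict$narrative
  switch(format,
         list = doc,
         json = as.character(jsonlite::toJSON(doc, auto_unbox = TRUE,
                                              digits = NA, null = "null")),
         text = {
           lines <- c(
             sprintf("MELD report  order %s  patient %s (%s, *%s)",
                     doc$order_id, doc$patient_id, doc$sex, doc$birth_date),
             sprintf("disposition: %s%s", doc$disposition,
                     if (length(verdict$reasons))
                       paste0("  [", paste(verdict$reasons, collapse = ", "), "]")
                     else ""),
             sprintf("bilirubin %.1f umol/L, creatinine %.1f umol/L, INR %s",
                     doc$analytes$bilirubin_umol_l, doc$analytes$creatinine_umol_l,
                     if (is.na(doc$analytes$inr)) "undeterminable"
                     else sprintf("%.2f", doc$analytes$inr)),
             sprintf("dialysis: %s%s", doc$dialysis_status$stated,
                     if (!is.null(doc$dialysis_status$corrected_to))
                       paste0(" -> ", doc$dialysis_status$corrected_to) else ""))
           if (!is.null(doc$score)) {
             lines <- c(lines, sprintf("lab-MELD %d%s", doc$score,
                                       if (!is.null(doc$meld_na))
                                         sprintf(" (MELD-Na %d)", doc$meld_na)
                                       else ""))
           } else {
             lines <- c(lines, "no score reportable")
           }
           c(lines, doc$narrative)
         })
}
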