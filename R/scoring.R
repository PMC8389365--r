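#' Analyte panel for one MELD request
#'
#' Bundles the measured concentrations in laboratory (SI) units. Bilirubin and
#' creatinine are in umol/L, sodium in mmol/L, the INR is dimensionless. The
#' INR may be `NA` when the clotting test was undeterminable (no clot within
#' the instrument timeout); scoring then requires prior resolution via
#' [resolve_inr()]. Albumin (g/L), fibrinogen (g/L) and cholinesterase (kU/L)
#' are context parameters for the anticoagulation heuristic, never score
#' inputs.
#'
#' @param bilirubin,creatinine concentrations in umol/L, positive.
#' @param inr international normalized ratio, positive or `NA`.
#' @param sodium serum sodium in mmol/L, optional (`NA` if not measured).
#' @param albumin,fibrinogen,cholinesterase optional liver-synthesis markers.
#' @return an object of class `analyte_panel`.
#' @export
analyte_panel <- function(bilirubin, creatinine, inr = NA_real_,
                          sodium = NA_real_, albumin = NA_real_,
                          fibrinogen = NA_real_, cholinesterase = NA_real_) {
  chk <- function(x, nm) {
    if (!is.na(x) && (!is.numeric(x) || !is.finite(x) || x <= 0)) {
      stop(nm, " must be positive when present", call. = FALSE)
    }
    as.numeric(x)
  }
  if (is.na(bilirubin) || is.na(creatinine)) {
    stop("bilirubin and creatinine are mandatory MELD parameters", call. = FALSE)
  }
  structure(
    list(bilirubin = chk(bilirubin, "bilirubin"),
         creatinine = chk(creatinine, "creatinine"),
         inr = chk(inr, "inr"),
         sodium = chk(sodium, "sodium"),
         albumin = chk(albumin, "albumin"),
         fibrinogen = chk(fibrinogen, "fibrinogen"),
         cholinesterase = chk(cholinesterase, "cholinesterase")),
    class = "analyte_panel")
}

#' Stated dialysis status of a MELD request
#'
#' The creatinine override (set to 4.0 mg/dL) applies when renal replacement
#' criteria are met: at least two intermittent dialyses within the prior week,
#' or at least 24 hours of continuous veno-venous hemodialysis (CVVHD) within
#' the prior week. Albumin dialysis is not a kidney replacement method and
#' never qualifies. `mode = NA` encodes a request whose sender did not state
#' the status.
#'
#' @param mode one of `"none"`, `"intermittent"`, `"cvvhd"`,
#'   `"albumin_dialysis"`, or `NA` (not stated).
#' @param sessions_prior_week intermittent sessions in the prior 7 days.
#' @param cvvhd_hours_prior_week CVVHD hours in the prior 7 days.
#' @return an object of class `dialysis_status`.
#' @export
dialysis_status <- function(mode = "none", sessions_prior_week = 0,
                            cvvhd_hours_prior_week = 0) {
  if (!is.na(mode)) {
    mode <- match.arg(mode, c("none", "intermittent", "cvvhd", "albumin_dialysis"))
  } else {
    mode <- NA_character_
  }
  if (sessions_prior_week < 0 || cvvhd_hours_prior_week < 0) {
    stop("dialysis counts/hours must be non-negative", call. = FALSE)
  }
  if (identical(mode, "none") &&
      (sessions_prior_week > 0 || cvvhd_hours_prior_week > 0)) {
    stop("mode 'none' implies zero sessions and zero CVVHD hours", call. = FALSE)
  }
  structure(
    list(mode = mode,
         sessions_prior_week = as.numeric(sessions_prior_week),
         cvvhd_hours_prior_week = as.numeric(cvvhd_hours_prior_week)),
    class = "dialysis_status")
}

# Does the stated status qualify for the creatinine override?
dialysis_qualifies <- function(dialysis) {
  if (is.null(dialysis) || is.na(dialysis$mode)) return(FALSE)
  (dialysis$mode == "intermittent" && dialysis$sessions_prior_week >= 2) ||
    (dialysis$mode == "cvvhd" && dialysis$cvvhd_hours_prior_week >= 24)
}

#' MELD score coefficients and clamps
#'
#' The published UNOS/Eurotransplant weights: score = round(10 * (0.957 *
#' ln(creatinine) + 0.378 * ln(bilirubin) + 1.12 * ln(INR) + 0.643)) with
#' components in mg/dL floored at 1.0, creatinine capped at 4.0 mg/dL (also the
#' dialysis override value), the score clamped to 6..40, half-up rounding.
#' MELD-Na applies from an initial MELD of 11 with sodium clamped to
#' 125..137 mmol/L. Every constant is overridable so regulatory variants are a
#' configuration change, not a code change.
#'
#' @param w_creatinine,w_bilirubin,w_inr,intercept regression weights.
#' @param input_floor_mgdl lower clamp for each component (and the INR).
#' @param creatinine_cap_mgdl upper clamp for creatinine; also the override value.
#' @param score_min,score_max reportable score bounds.
#' @param meldna_threshold minimal initial MELD for the sodium adjustment.
#' @param na_clamp_low,na_clamp_high sodium clamp in mmol/L.
#' @param conversion_factors umol/L-per-mg/dL divisors, see [to_mg_dl()].
#' @return an object of class `meld_coefficients`.
#' @export
meld_coefficients <- function(w_creatinine = 0.957, w_bilirubin = 0.378,
                              w_inr = 1.12, intercept = 0.643,
                              input_floor_mgdl = 1.0, creatinine_cap_mgdl = 4.0,
                              score_min = 6L, score_max = 40L,
                              meldna_threshold = 11L,
                              na_clamp_low = 125, na_clamp_high = 137,
                              conversion_factors = c(bilirubin = 17.1,
                                                     creatinine = 88.4)) {
  stopifnot(creatinine_cap_mgdl > input_floor_mgdl, input_floor_mgdl > 0,
            score_max > score_min, na_clamp_high > na_clamp_low)
  structure(
    list(w_creatinine = w_creatinine, w_bilirubin = w_bilirubin, w_inr = w_inr,
         intercept = intercept, input_floor_mgdl = input_floor_mgdl,
         creatinine_cap_mgdl = creatinine_cap_mgdl,
         score_min = as.integer(score_min), score_max = as.integer(score_max),
         meldna_threshold = as.integer(meldna_threshold),
         na_clamp_low = na_clamp_low, na_clamp_high = na_clamp_high,
         conversion_factors = conversion_factors),
    class = "meld_coefficients")
}

#' Compute the laboratory MELD score
#'
#' Converts bilirubin and creatinine to mg/dL, applies the input floor
#' (1.0 mg/dL, INR 1.0), the creatinine cap (4.0 mg/dL) and, when the stated
#' dialysis qualifies (>= 2 intermittent sessions or >= 24 h CVVHD in the prior
#' week), overrides creatinine with the cap before evaluating the linear
#' predictor. The score is rounded half-up and clamped to the reportable range.
#'
#' @param panel an [analyte_panel()]; `inr` must be present (a measurable
#'   clotting test, or one already resolved via [resolve_inr()]).
#' @param dialysis a [dialysis_status()].
#' @param coeffs a [meld_coefficients()].
#' @return an object of class `meld_result` with elements `score`,
#'   `bilirubin_mgdl`, `creatinine_mgdl`, `inr_used`,
#'   `dialysis_override_applied`, `meld_na` (filled by [compute_meld_na()]),
#'   and `clamps_applied`.
#' @examples
#' compute_meld(analyte_panel(34.2, 132.6, inr = 1.3), dialysis_status("none"))
#' @export
compute_meld <- function(panel, dialysis = dialysis_status("none"),
                         coeffs = meld_coefficients()) {
  stopifnot(inherits(panel, "analyte_panel"), inherits(dialysis, "dialysis_status"),
            inherits(coeffs, "meld_coefficients"))
  if (is.na(panel$inr)) {
    stop("INR undeterminable: resolve the clotting result (see resolve_inr()) ",
         "before scoring", call. = FALSE)
  }
  clamps <- character(0)
  bili <- to_mg_dl("bilirubin", panel$bilirubin, coeffs$conversion_factors)
  crea <- to_mg_dl("creatinine", panel$creatinine, coeffs$conversion_factors)
  inr <- panel$inr

  override <- dialysis_qualifies(dialysis)
  if (override) {
    crea <- coeffs$creatinine_cap_mgdl
    clamps <- c(clamps, "creatinine_dialysis_override")
  }
  if (bili < coeffs$input_floor_mgdl) {
    bili <- coeffs$input_floor_mgdl; clamps <- c(clamps, "bilirubin_floor")
  }
  if (crea < coeffs$input_floor_mgdl) {
    crea <- coeffs$input_floor_mgdl; clamps <- c(clamps, "creatinine_floor")
  }
  if (crea > coeffs$creatinine_cap_mgdl) {
    crea <- coeffs$creatinine_cap_mgdl; clamps <- c(clamps, "creatinine_cap")
  }
  if (inr < 1.0) {
    inr <- 1.0; clamps <- c(clamps, "inr_floor")
  }

  raw <- 10 * (coeffs$w_creatinine * log(crea) + coeffs$w_bilirubin * log(bili) +
                 coeffs$w_inr * log(inr) + coeffs$intercept)
  score <- round_half_up(raw)
  if (score < coeffs$score_min) { score <- coeffs$score_min; clamps <- c(clamps, "score_min") }
  if (score > coeffs$score_max) { score <- coeffs$score_max; clamps <- c(clamps, "score_max") }

  structure(
    list(score = as.integer(score), bilirubin_mgdl = bili, creatinine_mgdl = crea,
         inr_used = inr, dialysis_override_applied = override,
         meld_na = NA_integer_, clamps_applied = clamps),
    class = "meld_result")
}

#' Add the sodium-adjusted MELD-Na score
#'
#' Sodium is clamped to the 125..137 mmol/L corridor. When the initial MELD is
#' at or above the applicability threshold (11), MELD-Na = round(MELD + 1.32 *
#' (137 - Na) - 0.033 * MELD * (137 - Na)), clamped to the score maximum;
#' otherwise MELD-Na equals the unadjusted score. Missing sodium leaves
#' `meld_na` as `NA` and the lab-MELD untouched.
#'
#' @param meld a [compute_meld()] result.
#' @param sodium serum sodium in mmol/L (possibly `NA`).
#' @param coeffs a [meld_coefficients()].
#' @return `meld` with `meld_na` filled in.
#' @export
compute_meld_na <- function(meld, sodium, coeffs = meld_coefficients()) {
  stopifnot(inherits(meld, "meld_result"))
  if (is.na(sodium)) {
    meld$meld_na <- NA_integer_
    return(meld)
  }
  na <- min(max(sodium, coeffs$na_clamp_low), coeffs$na_clamp_high)
  if (meld$score >= coeffs$meldna_threshold) {
    d <- coeffs$na_clamp_high - na
    adj <- round_half_up(meld$score + 1.32 * d - 0.033 * meld$score * d)
    meld$meld_na <- as.integer(min(adj, coeffs$score_max))
  } else {
    meld$meld_na <- meld$score
  }
  meld
}

#' @export
print.meld_result <- function(x, ...) {
  cat(sprintf("lab-MELD %d (bilirubin %.2f mg/dL, creatinine %.2f mg/dL%s, INR %.2f)\n",
              x$score, x$bilirubin_mgdl, x$creatinine_mgdl,
              if (x$dialysis_override_applied) " [dialysis override]" else "",
              x$inr_used))
  if (!is.na(x$meld_na)) cat(sprintf("MELD-Na %d\n", x$meld_na))
  invisible(x)
}
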