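#' Verification rule configuration
#'
#' Every threshold of the rule engine in one place. Defaults reflect routine
#' laboratory practice where no regulatory number exists; each is deliberately
#' a plain scalar so site policy can be expressed in a YAML/JSON file
#' ([read_config()]).
#'
#' @param codraw_tolerance_min maximal spread (minutes) between draw times of
#'   the serum and citrate tubes of one order before a split order is assumed.
#' @param preanalytic_max_h maximal draw-to-lab interval in hours.
#' @param late_entrance_max_h maximal order-to-lab interval in hours.
#' @param underfill_min_ratio minimal acceptable citrate fill ratio; below it
#'   the citrate-to-blood mixing ratio falsely raises the INR.
#' @param min_age_years minimal patient age for MELD; younger patients are
#'   routed to PELD (not computed here).
#' @param delta_lookback_days window for the delta check against the most
#'   recent prior validated result.
#' @param delta_thresholds named relative-change thresholds (fractions) for
#'   `creatinine`, `bilirubin`, `inr`.
#' @param anticoag_inr_abs absolute INR above which stated VKA/DOAC therapy is
#'   considered to influence the score.
#' @param anticoag_baseline_ratio INR-to-baseline ratio above which
#'   anticoagulation influence is assumed (the baseline is the most recent
#'   prior validated result without anticoagulation).
#' @param synthesis_tolerance relative band within which albumin, fibrinogen
#'   and cholinesterase count as "unchanged" when judging an INR rise.
#' @param dialysis_min_creatinine_umol stated renal replacement with a serum
#'   creatinine below this value is implausible.
#' @param dialysis_max_rise stated renal replacement with a relative
#'   creatinine rise above this fraction (vs the most recent prior within the
#'   lookback) is implausible.
#' @param inr_policy resolution policy for an undeterminable INR:
#'   `"last_determinable"` (accept the most recent prior measured INR, the
#'   advisory-committee practice), `"table_max"` (INR at the maximum of the
#'   instrument conversion table) or `"block"` (never report).
#' @param conversion_table_max_inr INR at the top of the prothrombin-time
#'   conversion table, used by the `"table_max"` policy.
#' @param clotting_timeout_s instrument waiting time for the clotting reaction.
#' @param chi_sq_continuity use Yates continuity correction in
#'   [chi_square_2x2()].
#' @param coefficients a [meld_coefficients()] object.
#' @return an object of class `verification_config`.
#' @export
verification_config <- function(codraw_tolerance_min = 30,
                                preanalytic_max_h = 4,
                                late_entrance_max_h = 24,
                                underfill_min_ratio = 0.90,
                                min_age_years = 12,
                                delta_lookback_days = 7,
                                delta_thresholds = c(creatinine = 1.00,
                                                     bilirubin = 1.50,
                                                     inr = 0.75),
                                anticoag_inr_abs = 1.5,
                                anticoag_baseline_ratio = 1.2,
                                synthesis_tolerance = 0.20,
                                dialysis_min_creatinine_umol = 100,
                                dialysis_max_rise = 0.50,
                                inr_policy = c("last_determinable", "table_max", "block"),
                                conversion_table_max_inr = 9.0,
                                clotting_timeout_s = 315,
                                chi_sq_continuity = FALSE,
                                coefficients = meld_coefficients()) {
  inr_policy <- match.arg(inr_policy)
  stopifnot(all(delta_thresholds > 0), underfill_min_ratio > 0,
            inherits(coefficients, "meld_coefficients"))
  structure(
    list(codraw_tolerance_min = codraw_tolerance_min,
         preanalytic_max_h = preanalytic_max_h,
         late_entrance_max_h = late_entrance_max_h,
         underfill_min_ratio = underfill_min_ratio,
         min_age_years = min_age_years,
         delta_lookback_days = delta_lookback_days,
         delta_thresholds = delta_thresholds,
         anticoag_inr_abs = anticoag_inr_abs,
         anticoag_baseline_ratio = anticoag_baseline_ratio,
         synthesis_tolerance = synthesis_tolerance,
         dialysis_min_creatinine_umol = dialysis_min_creatinine_umol,
         dialysis_max_rise = dialysis_max_rise,
         inr_policy = inr_policy,
         conversion_table_max_inr = conversion_table_max_inr,
         clotting_timeout_s = clotting_timeout_s,
         chi_sq_continuity = chi_sq_continuity,
         coefficients = coefficients),
    class = "verification_config")
}

#' Read a verification configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys keep their defaults. The
#' `coefficients` block, when present, is passed to [meld_coefficients()].
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return a [verification_config()].
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$coefficients)) {
    raw$coefficients <- do.call(meld_coefficients, raw$coefficients)
  }
  if (!is.null(raw$delta_thresholds)) {
    raw$delta_thresholds <- unlist(raw$delta_thresholds)
  }
  known <- names(formals(verification_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(verification_config, raw)
}
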