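#' Convert bilirubin or creatinine from umol/L to mg/dL
#'
#' MELD arithmetic is defined on conventional units (mg/dL) while German
#' laboratories report SI units (umol/L). The creatinine factor 88.4 is pinned
#' by the regulatory equivalence 353.6 umol/L = 4.0 mg/dL used for the dialysis
#' override; bilirubin uses the standard factor 17.1.
#'
#' @param analyte `"bilirubin"` or `"creatinine"`.
#' @param value concentration in umol/L; must be positive.
#' @param factors named numeric vector of umol/L-per-mg/dL divisors,
#'   overridable for non-standard assays.
#' @return concentration in mg/dL.
#' @examples
#' to_mg_dl("creatinine", 353.6) # 4.0
#' to_mg_dl("bilirubin", 34.2)   # 2.0
#' @export
to_mg_dl <- function(analyte, value,
                     factors = c(bilirubin = 17.1, creatinine = 88.4)) {
  analyte <- match.arg(analyte, c("bilirubin", "creatinine"))
  if (!is.numeric(value) || any(!is.finite(value)) || any(value <= 0)) {
    stop("'", analyte, "' must be a positive finite concentration in umol/L",
         call. = FALSE)
  }
  value / factors[[analyte]]
}

# Half-up rounding (commercial rounding, Eurotransplant practice). base R's
# round() rounds half to even; MELD scores of the form x.5 must go up.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# Percentage of a count, half-up to one decimal, as printed on lab reports.
pct <- function(count, total) {
  if (total <= 0) stop("total must be positive", call. = FALSE)
  round_half_up(100 * count / total, 1)
}
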