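#' Calibration constants of the default simulated workload
#'
#' Category counts and cohort totals of a published six-year university
#' -hospital MELD verification workload (7,270 requests from 1,494 patients,
#' 193 of them flagged) that anchor the simulator defaults: per-category
#' error-injection probabilities are count / n_requests.
#'
#' @return a list with elements `n_requests`, `n_patients`, `study_days`,
#'   `category_counts` (named integer vector over reason-code categories),
#'   `preanalytical_counts` (the seven preanalytical sub-categories),
#'   `anticoagulated_counts` (treated patients by drug class),
#'   `dialysis_by_sex` (2x2 matrix of dialysis yes/no by sex) and
#'   `undeterminable_inr` (patients with no clot within the timeout, and
#'   deaths within the observation window).
#' @export
calibration_counts <- function() {
  preanalytical <- c(MATERIAL_ERROR = 56L, UNDERFILLED_CITRATE = 7L,
                     PATIENT_MISIDENTIFICATION = 7L, PROLONGED_PREANALYTIC = 5L,
                     PELD_REQUIRED = 5L, CITRATE_CLOTTED = 3L,
                     LATE_LAB_ENTRANCE = 2L)
  list(
    n_requests = 7270L,
    n_patients = 1494L,
    study_days = as.integer(as.Date("2018-10-31") - as.Date("2012-11-01")) + 1L,
    preanalytical_counts = preanalytical,
    category_counts = c(
      preanalytical,
      MISSING_DIALYSIS_STATUS = 4L,
      ANTICOAGULATION_INR_IMPACT = 24L,
      INR_UNDETERMINABLE = 32L,
      DIALYSIS_CRITERIA_NOT_MET = 8L,
      DIALYSIS_IMPLAUSIBLE = 21L,
      ALBUMIN_DIALYSIS_NOT_RRT = 1L,
      DELTA_CHECK_FAIL = 18L),
    anticoagulated_counts = c(fondaparinux = 2L, heparin = 488L, vka = 33L,
                              doac = 1L),
    dialysis_by_sex = matrix(c(253L, 2633L - 253L, 305L, 4637L - 305L), nrow = 2,
                             dimnames = list(c("dialysis", "no_dialysis"),
                                             c("women", "men"))),
    dialysis_corrections = c(to_no = 30L, to_yes = 4L),
    undeterminable_inr = c(patients = 21L, died = 13L))
}

#' Default per-category error-injection probabilities
#'
#' Calibration category counts divided by the cohort size; one error category
#' at most is injected per request.
#'
#' @return named numeric vector of probabilities summing to 193/7,270.
#' @export
default_error_rates <- function() {
  cal <- calibration_counts()
  cal$category_counts / cal$n_requests
}

#' Simulation configuration
#'
#' Defines the synthetic cohort: size, seed, analyte marginals (log-normal for
#' bilirubin and creatinine, shifted log-normal for the INR, loosely calibrated
#' to the reference workload's medians and ranges), dialysis and
#' anticoagulation prevalences, the repeat-request structure that builds
#' patient histories, and the per-category error-injection probabilities.
#'
#' @param n_requests cohort size.
#' @param seed RNG seed; identical configs yield identical cohorts.
#' @param error_rates named per-category injection probabilities (names must
#'   be reason codes); must sum to at most 1.
#' @param bilirubin_meanlog,bilirubin_sdlog,creatinine_meanlog,creatinine_sdlog
#'   log-normal parameters of the analyte base levels (umol/L).
#' @param inr_shift,inr_meanlog,inr_sdlog shifted log-normal INR base level:
#'   `inr_shift + rlnorm(meanlog, sdlog)`.
#' @param dialysis_prevalence fraction of patients under qualifying renal
#'   replacement.
#' @param anticoag_mix named fractions of patients per drug class (remainder
#'   is untreated).
#' @param mean_requests_per_patient geometric repeat-request structure;
#'   the default reproduces roughly 1,500 patients per 7,270 requests.
#' @param sodium_missing_rate fraction of requests without a sodium result.
#' @param study_start first order date; request times spread over `study_days`.
#' @param study_days length of the simulated period in days.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_requests = 7270L, seed = 1L,
                              error_rates = default_error_rates(),
                              bilirubin_meanlog = log(31.7), bilirubin_sdlog = 1.05,
                              creatinine_meanlog = log(86), creatinine_sdlog = 0.55,
                              inr_shift = 0.8, inr_meanlog = log(0.5), inr_sdlog = 0.8,
                              dialysis_prevalence = 558 / 7270,
                              anticoag_mix = c(heparin = 488, vka = 33,
                                               fondaparinux = 2) / 7270,
                              mean_requests_per_patient = 7270 / 1494,
                              sodium_missing_rate = 0.05,
                              study_start = "2012-11-01", study_days = 2191L) {
  if (any(error_rates < 0) || any(error_rates > 1)) {
    stop("error rates must be probabilities", call. = FALSE)
  }
  if (sum(error_rates) > 1) {
    stop("error rates sum to more than 1; at most one category is injected ",
         "per request", call. = FALSE)
  }
  bad <- setdiff(names(error_rates), reason_codes)
  if (length(bad)) stop("unknown error categories: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  stopifnot(n_requests >= 1, mean_requests_per_patient >= 1,
            dialysis_prevalence >= 0, dialysis_prevalence <= 1,
            sum(anticoag_mix) <= 1)
  structure(
    list(n_requests = as.integer(n_requests), seed = as.integer(seed),
         error_rates = error_rates,
         bilirubin_meanlog = bilirubin_meanlog, bilirubin_sdlog = bilirubin_sdlog,
         creatinine_meanlog = creatinine_meanlog, creatinine_sdlog = creatinine_sdlog,
         inr_shift = inr_shift, inr_meanlog = inr_meanlog, inr_sdlog = inr_sdlog,
         dialysis_prevalence = dialysis_prevalence, anticoag_mix = anticoag_mix,
         mean_requests_per_patient = mean_requests_per_patient,
         sodium_missing_rate = sodium_missing_rate,
         study_start = as.Date(study_start), study_days = as.integer(study_days)),
    class = "simulation_config")
}

# Vectorised lab-MELD for history tables (no dialysis override bookkeeping).
meld_score_vec <- function(bili_umol, crea_umol, inr, override = FALSE,
                           coeffs = meld_coefficients()) {
  bili <- pmax(bili_umol / coeffs$conversion_factors[["bilirubin"]],
               coeffs$input_floor_mgdl)
  crea <- crea_umol / coeffs$conversion_factors[["creatinine"]]
  crea <- ifelse(override, coeffs$creatinine_cap_mgdl, crea)
  crea <- pmin(pmax(crea, coeffs$input_floor_mgdl), coeffs$creatinine_cap_mgdl)
  inr <- pmax(inr, 1)
  raw <- 10 * (coeffs$w_creatinine * log(crea) + coeffs$w_bilirubin * log(bili) +
                 coeffs$w_inr * log(inr) + coeffs$intercept)
  as.integer(pmin(pmax(round_half_up(raw), coeffs$score_min), coeffs$score_max))
}

#' Simulate a cohort of MELD requests
#'
#' Generates `n_requests` synthetic requests from a smaller pool of patients
#' (geometric repeat structure), with per-patient base analyte levels and
#' small per-request fluctuation, patient-level dialysis and anticoagulation
#' status, timestamps over the study window, and per-patient histories of the
#' clean (pre-injection) values — the delta check and the anticoagulation
#' baseline compare against previously *validated* results, so injected
#' corruptions never enter a history. At most one error category is injected
#' per request ([inject_error()]); clean requests pass every rule by
#' construction.
#'
#' @param config a [simulation_config()].
#' @return a `cohort_bundle`: `requests` (list of [meld_request()]),
#'   `histories` (named list of [patient_history()]), `truth` (per-request
#'   injected category, `"clean"` otherwise, named by order id) and `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_requests

  # --- patients -------------------------------------------------------------
  p_geo <- 1 / config$mean_requests_per_patient
  sizes <- integer(0)
  while (sum(sizes) < n) {
    sizes <- c(sizes, stats::rgeom(max(64L, ceiling(n * p_geo)), p_geo) + 1L)
  }
  n_pat <- which(cumsum(sizes) >= n)[1]
  sizes <- sizes[seq_len(n_pat)]
  sizes[n_pat] <- sizes[n_pat] - (sum(sizes) - n)
  pat_id <- sprintf("P%05d", seq_len(n_pat))
  sex <- ifelse(stats::runif(n_pat) < 941 / 1494, "m", "f")
  age0 <- pmin(pmax(stats::rnorm(n_pat, 55, 12), 12.5), 84)

  dialysis_pat <- stats::runif(n_pat) < config$dialysis_prevalence
  dial_mode <- ifelse(dialysis_pat,
                      ifelse(stats::runif(n_pat) < 0.8, "intermittent", "cvvhd"),
                      "none")
  dial_sessions <- ifelse(dial_mode == "intermittent",
                          sample(2:4, n_pat, replace = TRUE), 0)
  dial_hours <- ifelse(dial_mode == "cvvhd", stats::runif(n_pat, 24, 168), 0)

  ac_classes <- names(config$anticoag_mix)
  ac_prob <- c(config$anticoag_mix, none = 1 - sum(config$anticoag_mix))
  anticoag <- sample(c(ac_classes, "none"), n_pat, replace = TRUE, prob = ac_prob)

  bili0 <- pmin(pmax(stats::rlnorm(n_pat, config$bilirubin_meanlog,
                                   config$bilirubin_sdlog), 2.2), 1100)
  crea0 <- pmin(pmax(stats::rlnorm(n_pat, config$creatinine_meanlog,
                                   config$creatinine_sdlog), 25), 786)
  crea0 <- ifelse(dialysis_pat, stats::runif(n_pat, 150, 600), crea0)
  inr0 <- pmin(config$inr_shift + stats::rlnorm(n_pat, config$inr_meanlog,
                                                config$inr_sdlog), 11)
  # stated VKA therapy must not already exceed the impact threshold
  inr0 <- ifelse(anticoag %in% c("vka", "doac"), stats::runif(n_pat, 0.9, 1.35), inr0)
  alb0 <- stats::runif(n_pat, 20, 45)
  fib0 <- stats::runif(n_pat, 1, 5)
  che0 <- stats::runif(n_pat, 1.5, 8)
  na0 <- stats::rnorm(n_pat, 135, 4)

  # --- request times --------------------------------------------------------
  t0 <- as.POSIXct(paste(config$study_start, "00:00:00"), tz = "UTC")
  pat_of <- rep.int(seq_len(n_pat), sizes)
  gaps <- stats::runif(n, 1, 30)            # days between repeat requests
  first_day <- stats::runif(n_pat, 0, pmax(config$study_days - 30 * sizes, 1))
  day <- numeric(n)
  idx <- 1L
  for (p in seq_len(n_pat)) {
    k <- sizes[p]
    d <- first_day[p] + cumsum(c(0, gaps[idx + seq_len(k - 1) - 1]))[seq_len(k)]
    day[idx:(idx + k - 1)] <- d
    idx <- idx + k
  }
  req_time <- t0 + day * 86400 + stats::runif(n, 7 * 3600, 16 * 3600)
  draw_time <- req_time + stats::runif(n, 5, 90) * 60
  arr_time <- draw_time + stats::runif(n, 20, 180) * 60
  birth <- as.Date(t0) + floor(first_day) - round(age0 * 365.25)

  # --- per-request analytes (clean) ----------------------------------------
  bili <- bili0[pat_of] * stats::runif(n, 0.9, 1.1)
  crea <- crea0[pat_of] * stats::runif(n, 0.9, 1.1)
  inr <- pmax(inr0[pat_of] * stats::runif(n, 0.93, 1.07), 0.8)
  alb <- alb0[pat_of] * stats::runif(n, 0.92, 1.08)
  fib <- fib0[pat_of] * stats::runif(n, 0.92, 1.08)
  che <- che0[pat_of] * stats::runif(n, 0.92, 1.08)
  sodium <- na0[pat_of] + stats::rnorm(n, 0, 1.5)
  sodium[stats::runif(n) < config$sodium_missing_rate] <- NA_real_

  # --- truth labels ---------------------------------------------------------
  rates <- config$error_rates
  truth <- sample(c(names(rates), "clean"), n, replace = TRUE,
                  prob = c(rates, 1 - sum(rates)))
  order_id <- sprintf("O%06d", seq_len(n))
  names(truth) <- order_id

  # --- histories (clean values only) ---------------------------------------
  override <- dialysis_pat[pat_of]
  meld_hist <- meld_score_vec(bili, crea, inr, override)
  hist_df <- data.frame(
    timestamp = req_time, bilirubin = bili, creatinine = crea, inr = inr,
    albumin = alb, fibrinogen = fib, cholinesterase = che,
    anticoagulation = anticoag[pat_of], dialysis_mode = dial_mode[pat_of],
    meld = meld_hist, stringsAsFactors = FALSE)
  hist_split <- split(hist_df, pat_of)
  histories <- lapply(seq_len(n_pat), function(p) {
    structure(list(patient_id = pat_id[p],
                   prior = hist_split[[as.character(p)]]),
              class = "patient_history")
  })
  names(histories) <- pat_id

  # --- assemble requests ----------------------------------------------------
  requests <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pat_of[i]
    serum <- structure(
      list(specimen_id = paste0(order_id[i], "-S"), tube_type = "serum",
           labeled_patient_id = pat_id[p], draw_time = draw_time[i],
           lab_arrival_time = arr_time[i], fill_ratio = NA_real_,
           clotted = FALSE), class = "specimen")
    citrate <- structure(
      list(specimen_id = paste0(order_id[i], "-C"), tube_type = "citrate",
           labeled_patient_id = pat_id[p], draw_time = draw_time[i],
           lab_arrival_time = arr_time[i],
           fill_ratio = stats::runif(1, 0.95, 1.05), clotted = FALSE),
      class = "specimen")
    panel <- structure(
      list(bilirubin = bili[i], creatinine = crea[i], inr = inr[i],
           sodium = sodium[i], albumin = alb[i], fibrinogen = fib[i],
           cholinesterase = che[i]), class = "analyte_panel")
    clotting <- structure(
      list(status = "clot_detected", pt_seconds = 12 * inr[i], inr = inr[i],
           timeout_seconds = 315), class = "clotting_result")
    dial <- structure(
      list(mode = dial_mode[p], sessions_prior_week = dial_sessions[p],
           cvvhd_hours_prior_week = dial_hours[p]), class = "dialysis_status")
    requests[[i]] <- structure(
      list(order_id = order_id[i], patient_id = pat_id[p],
           birth_date = birth[p], sex = sex[p], request_time = req_time[i],
           specimens = list(serum, citrate), panel = panel, clotting = clotting,
           stated_dialysis = dial, stated_anticoagulation = anticoag[p],
           anticoagulant_drug = NA_character_), class = "meld_request")
  }

  # --- error injection ------------------------------------------------------
  for (i in which(truth != "clean")) {
    pid <- requests[[i]]$patient_id
    if (truth[i] == "DELTA_CHECK_FAIL") {
      histories[[pid]] <- ensure_recent_prior(histories[[pid]], requests[[i]],
                                              lookback_days = 7)
    }
    requests[[i]] <- inject_error(requests[[i]], truth[i],
                                  history = histories[[pid]])
  }

  structure(list(requests = requests, histories = histories, truth = truth,
                 config = config), class = "cohort_bundle")
}

# Guarantee a usable prior validated result within the delta-check lookback:
# fabricate one 2 days before the request if the patient has none.
ensure_recent_prior <- function(history, request, lookback_days = 7) {
  pr <- history_before(history, request$request_time)
  if (nrow(pr) > 0) {
    gap <- (as.numeric(request$request_time) -
              as.numeric(pr$timestamp[nrow(pr)])) / 86400
    if (gap <= lookback_days) return(history)
  }
  panel <- request$panel
  row <- data.frame(
    timestamp = request$request_time - 2 * 86400,
    bilirubin = panel$bilirubin, creatinine = panel$creatinine,
    inr = panel$inr, albumin = panel$albumin, fibrinogen = panel$fibrinogen,
    cholinesterase = panel$cholinesterase,
    anticoagulation = request$stated_anticoagulation,
    dialysis_mode = if (is.na(request$stated_dialysis$mode)) "none"
                    else request$stated_dialysis$mode,
    meld = meld_score_vec(panel$bilirubin, panel$creatinine, panel$inr,
                          dialysis_qualifies(request$stated_dialysis)),
    stringsAsFactors = FALSE)
  prior <- rbind(history$prior, row)
  prior <- prior[order(as.numeric(prior$timestamp)), , drop = FALSE]
  history$prior <- prior
  history
}

#' Inject one error category into a clean request
#'
#' Minimally mutates a request so that the targeted verification rule fires:
#' e.g. `UNDERFILLED_CITRATE` lowers the citrate fill ratio,
#' `PATIENT_MISIDENTIFICATION` mislabels a tube, `PELD_REQUIRED` moves the
#' birth date to age 5, `DIALYSIS_CRITERIA_NOT_MET` states a single
#' intermittent session, `INR_UNDETERMINABLE` turns the clotting test into a
#' no-clot-within-timeout result. `DELTA_CHECK_FAIL` quadruples bilirubin and
#' therefore needs a prior validated result within the lookback window (the
#' simulator guarantees one).
#'
#' @param request a clean [meld_request()].
#' @param category a reason-code category (see [reason_codes]).
#' @param history the patient's [patient_history()]; used by categories whose
#'   rule compares against prior results.
#' @return the mutated `meld_request`.
#' @export
inject_error <- function(request, category, history = NULL) {
  stopifnot(inherits(request, "meld_request"))
  is_citrate <- vapply(request$specimens, function(s) s$tube_type == "citrate",
                       logical(1))
  ci <- which(is_citrate)[1]
  switch(as.character(category),
    MATERIAL_ERROR = {
      request$specimens <- request$specimens[!is_citrate]
    },
    SPLIT_ORDER = {
      request$specimens[[ci]]$draw_time <-
        request$specimens[[ci]]$draw_time + 2 * 3600
      request$specimens[[ci]]$lab_arrival_time <-
        request$specimens[[ci]]$draw_time + 3600
    },
    UNDERFILLED_CITRATE = {
      request$specimens[[ci]]$fill_ratio <- 0.60
    },
    PATIENT_MISIDENTIFICATION = {
      request$specimens[[ci]]$labeled_patient_id <-
        paste0(request$patient_id, "X")
    },
    PROLONGED_PREANALYTIC = {
      for (j in seq_along(request$specimens)) {
        request$specimens[[j]]$lab_arrival_time <-
          request$specimens[[j]]$draw_time + 5.5 * 3600
      }
    },
    LATE_LAB_ENTRANCE = {
      for (j in seq_along(request$specimens)) {
        request$specimens[[j]]$draw_time <- request$request_time + 28 * 3600
        request$specimens[[j]]$lab_arrival_time <- request$request_time + 30 * 3600
      }
    },
    CITRATE_CLOTTED = {
      request$specimens[[ci]]$clotted <- TRUE
    },
    PELD_REQUIRED = {
      request$birth_date <- as.Date(request$request_time) - round(5 * 365.25)
    },
    MISSING_DIALYSIS_STATUS = {
      request$stated_dialysis <- dialysis_status(NA)
    },
    DIALYSIS_CRITERIA_NOT_MET = {
      request$stated_dialysis <- dialysis_status("intermittent",
                                                 sessions_prior_week = 1)
    },
    DIALYSIS_IMPLAUSIBLE = {
      request$stated_dialysis <- dialysis_status("intermittent",
                                                 sessions_prior_week = 3)
      request$panel$creatinine <- min(request$panel$creatinine, 70)
    },
    ALBUMIN_DIALYSIS_NOT_RRT = {
      request$stated_dialysis <- dialysis_status("albumin_dialysis")
    },
    ANTICOAGULATION_INR_IMPACT = {
      request$stated_anticoagulation <- "vka"
      request$anticoagulant_drug <- "phenprocoumon"
      pr <- history_before(history, request$request_time)
      prior_inr <- if (!is.null(pr) && nrow(pr) > 0) {
        v <- pr$inr[is.finite(pr$inr)]
        if (length(v)) v[length(v)] else NA_real_
      } else NA_real_
      # 1.4 x the previous INR trips the baseline heuristic without tripping
      # the delta check; the 1.6 floor covers patients whose prior results
      # were all under anticoagulation (no usable baseline).
      request$panel$inr <- if (is.finite(prior_inr)) max(1.4 * prior_inr, 1.6)
                           else max(request$panel$inr, 1.6)
      request$clotting$inr <- request$panel$inr
      request$clotting$pt_seconds <- 12 * request$panel$inr
    },
    INR_UNDETERMINABLE = {
      request$panel$inr <- NA_real_
      request$clotting <- clotting_result("no_clot_within_timeout",
                                          timeout_seconds = 315)
    },
    DELTA_CHECK_FAIL = {
      request$panel$bilirubin <- 4 * request$panel$bilirubin
    },
    stop("unknown error category: ", category, call. = FALSE)
  )
  request
}

#' @export
print.cohort_bundle <- function(x, ...) {
  tab <- table(x$truth)
  cat(sprintf("cohort of %d MELD requests from %d patients (seed %d)\n",
              length(x$requests), length(x$histories), x$config$seed))
  cat("injected:", sum(x$truth != "clean"), "requests\n")
  print(tab[order(-tab)])
  invisible(x)
}
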