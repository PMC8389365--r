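cfg <- verification_config()

test_that("a clean request is VALID with a score and no reasons", {
  v <- validate_request(clean_request())
  expect_equal(v$disposition, "VALID")
  expect_length(v$reasons, 0)
  expect_s3_class(v$result, "meld_result")
  expect_false(is.na(v$result$meld_na))
})

test_that("order-integrity rules fire on missing tubes, split orders and unstated dialysis", {
  expect_equal(check_order_integrity(clean_request(), cfg), character(0))
  expect_equal(check_order_integrity(clean_request(include_citrate = FALSE), cfg),
               "MATERIAL_ERROR")
  expect_equal(check_order_integrity(clean_request(serum_tube = "lithium_heparin"), cfg),
               "MATERIAL_ERROR")
  expect_equal(check_order_integrity(
    clean_request(citrate_draw_min = 30 + 121, citrate_arrival_min = 30 + 181), cfg),
    "SPLIT_ORDER")
  expect_equal(check_order_integrity(clean_request(dialysis = dialysis_status(NA)), cfg),
               "MISSING_DIALYSIS_STATUS")
})

test_that("preanalytical rules fire on timing, filling, identity and age problems", {
  expect_equal(check_preanalytics(clean_request(), cfg), character(0))
  # draw 10:00, arrival 14:30 -> longer than 4 h in transit
  expect_equal(check_preanalytics(
    clean_request(draw_min = 0, serum_arrival_min = 270,
                  citrate_draw_min = 0, citrate_arrival_min = 270), cfg),
    "PROLONGED_PREANALYTIC")
  expect_equal(check_preanalytics(
    clean_request(draw_min = 28 * 60, serum_arrival_min = 30 * 60,
                  citrate_draw_min = 28 * 60, citrate_arrival_min = 30 * 60), cfg),
    "LATE_LAB_ENTRANCE")
  expect_equal(check_preanalytics(clean_request(fill_ratio = 0.70), cfg),
               "UNDERFILLED_CITRATE")
  expect_equal(check_preanalytics(clean_request(fill_ratio = 0.90), cfg),
               character(0))
  expect_equal(check_preanalytics(clean_request(clotted = TRUE), cfg),
               "CITRATE_CLOTTED")
  expect_equal(check_preanalytics(clean_request(citrate_label = "P99999"), cfg),
               "PATIENT_MISIDENTIFICATION")
  expect_equal(check_preanalytics(clean_request(birth_date = "2009-01-15"), cfg),
               "PELD_REQUIRED")  # age 6 at draw
  expect_equal(check_preanalytics(clean_request(birth_date = "2003-03-01"), cfg),
               character(0))     # just turned 12
})

test_that("dialysis plausibility separates criteria, albumin dialysis and lab incongruence", {
  crit <- clean_request(dialysis = dialysis_status("intermittent",
                                                   sessions_prior_week = 1),
                        creatinine = 300)
  expect_equal(check_dialysis(crit, NULL, cfg), "DIALYSIS_CRITERIA_NOT_MET")
  cv <- clean_request(dialysis = dialysis_status("cvvhd", cvvhd_hours_prior_week = 20),
                      creatinine = 300)
  expect_equal(check_dialysis(cv, NULL, cfg), "DIALYSIS_CRITERIA_NOT_MET")
  alb <- clean_request(dialysis = dialysis_status("albumin_dialysis"))
  expect_equal(check_dialysis(alb, NULL, cfg), "ALBUMIN_DIALYSIS_NOT_RRT")
  low <- clean_request(dialysis = dialysis_status("intermittent",
                                                  sessions_prior_week = 2),
                       creatinine = 60)
  expect_equal(check_dialysis(low, NULL, cfg), "DIALYSIS_IMPLAUSIBLE")
  # falling creatinine on proper dialysis is plausible
  h <- make_history(timestamps = "2015-03-08 08:00:00", creatinine = 320)
  ok <- clean_request(dialysis = dialysis_status("intermittent",
                                                 sessions_prior_week = 2),
                      creatinine = 280)
  expect_equal(check_dialysis(ok, h, cfg), character(0))
  # steep rise despite renal replacement is not
  rise <- clean_request(dialysis = dialysis_status("intermittent",
                                                   sessions_prior_week = 2),
                        creatinine = 550)
  expect_equal(check_dialysis(rise, h, cfg), "DIALYSIS_IMPLAUSIBLE")
  expect_equal(check_dialysis(clean_request(), NULL, cfg), character(0))
})

test_that("anticoagulation influence on the INR is detected, stated or not", {
  vka <- clean_request(anticoagulation = "vka", inr = 2.65)
  expect_equal(check_anticoagulation(vka, NULL, cfg), "ANTICOAGULATION_INR_IMPACT")
  # stated VKA with an INR at the patient's usual level passes
  expect_equal(check_anticoagulation(
    clean_request(anticoagulation = "vka", inr = 1.3), NULL, cfg), character(0))
  # heparin with an INR equal to baseline passes
  h <- make_history(timestamps = "2015-03-05 08:00:00", inr = 1.2)
  expect_equal(check_anticoagulation(
    clean_request(anticoagulation = "heparin", inr = 1.2), h, cfg), character(0))
  # unstated anticoagulation unravelled: INR 1.1 -> 2.8, synthesis unchanged
  hb <- make_history(timestamps = "2015-03-05 08:00:00", inr = 1.1)
  expect_equal(check_anticoagulation(
    clean_request(anticoagulation = "none", inr = 2.8), hb, cfg),
    "ANTICOAGULATION_INR_IMPACT")
  # same INR jump with collapsing synthesis markers is liver failure, not a drug
  worse <- clean_request(anticoagulation = "none", inr = 2.8, albumin = 18,
                         fibrinogen = 0.9, cholinesterase = 1.5)
  expect_equal(check_anticoagulation(worse, hb, cfg), character(0))
})

test_that("delta check flags improbable changes within the lookback window", {
  at <- as.POSIXct("2015-03-10 08:00:00", tz = "UTC")
  expect_equal(delta_check(analyte_panel(34.2, 400, inr = 1.2), NULL, at, cfg),
               character(0))
  h <- make_history(timestamps = "2015-03-09 08:00:00", creatinine = 80)
  expect_equal(delta_check(analyte_panel(34.2, 400, inr = 1.2), h, at, cfg),
               "DELTA_CHECK_FAIL")  # 400% change in 24 h
  expect_equal(delta_check(analyte_panel(34.2, 88, inr = 1.2), h, at, cfg),
               character(0))        # 10% change
  # outside the 7-day lookback the prior result is not comparable
  h_old <- make_history(timestamps = "2015-02-01 08:00:00", creatinine = 80)
  expect_equal(delta_check(analyte_panel(34.2, 400, inr = 1.2), h_old, at, cfg),
               character(0))
  # INR and bilirubin thresholds
  h2 <- make_history(timestamps = "2015-03-09 08:00:00", inr = 1.1,
                     bilirubin = 40)
  expect_equal(delta_check(analyte_panel(40, 120, inr = 2.2), h2, at, cfg),
               "DELTA_CHECK_FAIL")
  expect_equal(delta_check(analyte_panel(110, 120, inr = 1.15), h2, at, cfg),
               "DELTA_CHECK_FAIL")
})

test_that("undeterminable INR resolution follows the configured policy", {
  ok <- resolve_inr(clotting_result("clot_detected", 16.8, 1.4), config = cfg)
  expect_equal(ok$inr, 1.4)
  expect_false(ok$blocked)
  expect_length(ok$codes, 0)

  manual <- resolve_inr(clotting_result("manual_curve_read", 300, 3.5), config = cfg)
  expect_equal(manual$inr, 3.5)
  expect_equal(manual$codes, "INR_UNDETERMINABLE")

  nc <- clotting_result("no_clot_within_timeout")
  h <- make_history(timestamps = "2015-03-01 08:00:00", inr = 3.3)
  last <- resolve_inr(nc, h, policy = "last_determinable", config = cfg)
  expect_equal(last$inr, 3.3)
  expect_equal(last$codes, "INR_UNDETERMINABLE")
  expect_false(last$blocked)

  tm <- resolve_inr(nc, h, policy = "table_max", config = cfg)
  expect_equal(tm$inr, 9.0)

  blocked <- resolve_inr(nc, h, policy = "block", config = cfg)
  expect_true(blocked$blocked)
  # last-determinable with no usable history blocks as well
  empty <- resolve_inr(nc, patient_history("P1"), policy = "last_determinable",
                       config = cfg)
  expect_true(empty$blocked)
})

test_that("each reason code is triggerable in isolation and maps to its disposition", {
  h_delta <- make_history(timestamps = "2015-03-09 08:00:00", creatinine = 80)
  fixtures <- list(
    MATERIAL_ERROR = list(rq = clean_request(include_citrate = FALSE),
                          disp = "INVALID"),
    SPLIT_ORDER = list(rq = clean_request(citrate_draw_min = 200,
                                          citrate_arrival_min = 260),
                       disp = "INVALID"),
    MISSING_DIALYSIS_STATUS = list(rq = clean_request(dialysis = dialysis_status(NA)),
                                   disp = "NEEDS_CONSULTATION"),
    PROLONGED_PREANALYTIC = list(rq = clean_request(serum_arrival_min = 330,
                                                    citrate_arrival_min = 330),
                                 disp = "INVALID"),
    LATE_LAB_ENTRANCE = list(rq = clean_request(draw_min = 28 * 60,
                                                serum_arrival_min = 30 * 60,
                                                citrate_draw_min = 28 * 60,
                                                citrate_arrival_min = 30 * 60),
                             disp = "INVALID"),
    UNDERFILLED_CITRATE = list(rq = clean_request(fill_ratio = 0.60),
                               disp = "INVALID"),
    CITRATE_CLOTTED = list(rq = clean_request(clotted = TRUE), disp = "INVALID"),
    PATIENT_MISIDENTIFICATION = list(rq = clean_request(citrate_label = "P9"),
                                     disp = "INVALID"),
    PELD_REQUIRED = list(rq = clean_request(birth_date = "2009-06-01"),
                         disp = "INVALID"),
    INR_UNDETERMINABLE = list(
      rq = clean_request(inr = NA,
                         clotting = clotting_result("no_clot_within_timeout")),
      disp = "INVALID"),  # no prior INR -> blocked
    DIALYSIS_CRITERIA_NOT_MET = list(
      rq = clean_request(creatinine = 300,
                         dialysis = dialysis_status("intermittent",
                                                    sessions_prior_week = 1)),
      disp = "NEEDS_CONSULTATION"),
    ALBUMIN_DIALYSIS_NOT_RRT = list(
      rq = clean_request(dialysis = dialysis_status("albumin_dialysis")),
      disp = "NEEDS_CONSULTATION"),
    DIALYSIS_IMPLAUSIBLE = list(
      rq = clean_request(creatinine = 60,
                         dialysis = dialysis_status("intermittent",
                                                    sessions_prior_week = 2)),
      disp = "NEEDS_CONSULTATION"),
    ANTICOAGULATION_INR_IMPACT = list(
      rq = clean_request(anticoagulation = "vka", inr = 2.65),
      disp = "INVALID"),
    DELTA_CHECK_FAIL = list(rq = clean_request(creatinine = 400),
                            history = h_delta, disp = "NEEDS_CONSULTATION"))
  for (code in names(fixtures)) {
    fx <- fixtures[[code]]
    v <- validate_request(fx$rq, fx$history, cfg)
    expect_identical(v$reasons, code, label = paste("reasons for", code))
    expect_identical(v$disposition, fx$disp, label = paste("disposition for", code))
    if (v$disposition == "INVALID") expect_null(v$result)
  }
})

test_that("verdicts are deterministic and reasons keep evaluation order", {
  rq <- clean_request(fill_ratio = 0.6, clotted = TRUE,
                      dialysis = dialysis_status("intermittent",
                                                 sessions_prior_week = 1),
                      creatinine = 300, anticoagulation = "vka", inr = 2.7)
  v1 <- validate_request(rq, NULL, cfg)
  v2 <- validate_request(rq, NULL, cfg)
  expect_identical(v1, v2)
  expect_identical(v1$reasons,
                   c("UNDERFILLED_CITRATE", "CITRATE_CLOTTED",
                     "DIALYSIS_CRITERIA_NOT_MET", "ANTICOAGULATION_INR_IMPACT"))
  expect_identical(v1$disposition, "INVALID")
})

test_that("a resolved undeterminable INR routes to consultation, not release", {
  h <- make_history(timestamps = "2015-03-01 08:00:00", inr = 3.3)
  rq <- clean_request(inr = NA, bilirubin = 250, creatinine = 150,
                      clotting = clotting_result("no_clot_within_timeout"))
  v <- validate_request(rq, h, cfg)
  expect_identical(v$disposition, "NEEDS_CONSULTATION")
  expect_identical(v$reasons, "INR_UNDETERMINABLE")
  expect_null(v$result)
  expect_equal(v$provisional$inr_used, 3.3)
})

test_that("dialysis corrections re-score and record the change", {
  # stated qualifying dialysis, lab picture incompatible; confirmed: none
  rq <- clean_request(creatinine = 88.4, bilirubin = 171, inr = 1.8,
                      dialysis = dialysis_status("intermittent",
                                                 sessions_prior_week = 2))
  v <- validate_request(rq, NULL, cfg)
  expect_identical(v$disposition, "NEEDS_CONSULTATION")
  corr <- apply_correction(rq, v, dialysis_status("none"), config = cfg)
  expect_identical(corr$disposition, "CORRECTED_VALID")
  expect_lt(corr$result$score, v$provisional$score)
  expect_identical(corr$corrections$stated_dialysis,
                   list(old = "intermittent", new = "none"))
  expect_true("DIALYSIS_STATUS_CORRECTED" %in% corr$reasons)

  # unstated dialysis confirmed as performed: score can only go up
  rq2 <- clean_request(creatinine = 150, dialysis = dialysis_status(NA))
  v2 <- validate_request(rq2, NULL, cfg)
  corr2 <- apply_correction(rq2, v2,
                            dialysis_status("intermittent", sessions_prior_week = 2),
                            config = cfg)
  expect_identical(corr2$disposition, "CORRECTED_VALID")
  expect_gte(corr2$result$score, v2$provisional$score)

  # confirmed status identical to stated: verdict unchanged
  same <- apply_correction(rq, v, dialysis_status("intermittent",
                                                  sessions_prior_week = 2),
                           config = cfg)
  expect_identical(same, v)

  # confirmed status that still fails the criteria stays in consultation
  bad <- apply_correction(rq, v, dialysis_status("intermittent",
                                                 sessions_prior_week = 1),
                          config = cfg)
  expect_identical(bad$disposition, "NEEDS_CONSULTATION")

  # a VALID verdict is not correctable
  expect_error(apply_correction(clean_request(), validate_request(clean_request()),
                                dialysis_status("none")), "NEEDS_CONSULTATION")
})

test_that("correction monotonicity holds below the creatinine cap", {
  set.seed(11)
  qualifying <- dialysis_status("intermittent", sessions_prior_week = 2)
  for (rep in 1:50) {
    bili <- runif(1, 20, 400); inr <- runif(1, 1, 4)
    # none -> qualifying never decreases the score
    rq <- clean_request(creatinine = runif(1, 100, 350), bilirubin = bili,
                        inr = inr,
                        dialysis = dialysis_status("intermittent",
                                                   sessions_prior_week = 1))
    v <- validate_request(rq, NULL, cfg)
    c_no <- apply_correction(rq, v, dialysis_status("none"), config = cfg)
    c_yes <- apply_correction(rq, v, qualifying, config = cfg)
    expect_gte(c_yes$result$score, c_no$result$score)
    expect_equal(c_no$result$score, v$provisional$score)  # 1 session never overrode
    # qualifying -> none never increases the score (creatinine below the cap)
    rq2 <- clean_request(creatinine = runif(1, 30, 95), bilirubin = bili,
                         inr = inr, dialysis = qualifying)
    v2 <- validate_request(rq2, NULL, cfg)  # implausible: consultation
    expect_identical(v2$disposition, "NEEDS_CONSULTATION")
    c2 <- apply_correction(rq2, v2, dialysis_status("none"), config = cfg)
    expect_lte(c2$result$score, v2$provisional$score)
  }
})

test_that("configuration round-trips through YAML and rejects unknown keys", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("preanalytic_max_h: 6", "underfill_min_ratio: 0.85",
               "inr_policy: table_max"), path)
  c2 <- read_config(path)
  expect_equal(c2$preanalytic_max_h, 6)
  expect_equal(c2$underfill_min_ratio, 0.85)
  expect_equal(c2$inr_policy, "table_max")
  expect_equal(c2$delta_lookback_days, cfg$delta_lookback_days)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("no_such_threshold: 1", bad)
  expect_error(read_config(bad), "unknown config keys")
})
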