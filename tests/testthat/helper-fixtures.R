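# A request that passes every verification rule; individual fields are
# overridable to build minimal failing fixtures.
clean_request <- function(order_id = "O000001", patient_id = "P00001",
                          bilirubin = 34.2, creatinine = 120, inr = 1.2,
                          sodium = 136, albumin = 30, fibrinogen = 2.5,
                          cholinesterase = 4,
                          request_time = "2015-03-10T08:00:00",
                          draw_min = 30, serum_arrival_min = 120,
                          citrate_draw_min = draw_min,
                          citrate_arrival_min = serum_arrival_min,
                          fill_ratio = 1.0, clotted = FALSE,
                          birth_date = "1960-01-15", sex = "m",
                          serum_label = patient_id, citrate_label = patient_id,
                          include_citrate = TRUE, serum_tube = "serum",
                          dialysis = dialysis_status("none"),
                          anticoagulation = "none", clotting = NULL) {
  rt <- as.POSIXct(request_time, tz = "UTC",
                   format = "%Y-%m-%dT%H:%M:%S")
  specimens <- list(specimen(paste0(order_id, "-S"), serum_tube, serum_label,
                             rt + draw_min * 60, rt + serum_arrival_min * 60))
  if (include_citrate) {
    specimens <- c(specimens, list(
      specimen(paste0(order_id, "-C"), "citrate", citrate_label,
               rt + citrate_draw_min * 60, rt + citrate_arrival_min * 60,
               fill_ratio = fill_ratio, clotted = clotted)))
  }
  panel <- analyte_panel(bilirubin, creatinine, inr = inr, sodium = sodium,
                         albumin = albumin, fibrinogen = fibrinogen,
                         cholinesterase = cholinesterase)
  meld_request(order_id, patient_id, birth_date, sex, rt, specimens, panel,
               clotting = clotting, stated_dialysis = dialysis,
               stated_anticoagulation = anticoagulation)
}

# Shorthand history: one row per prior validated result.
make_history <- function(patient_id = "P00001", timestamps, bilirubin = 34.2,
                         creatinine = 120, inr = 1.2, albumin = 30,
                         fibrinogen = 2.5, cholinesterase = 4,
                         anticoagulation = "none", dialysis_mode = "none") {
  k <- length(timestamps)
  patient_history(patient_id, data.frame(
    timestamp = as.POSIXct(timestamps, tz = "UTC"),
    bilirubin = rep_len(bilirubin, k), creatinine = rep_len(creatinine, k),
    inr = rep_len(inr, k), albumin = rep_len(albumin, k),
    fibrinogen = rep_len(fibrinogen, k),
    cholinesterase = rep_len(cholinesterase, k),
    anticoagulation = rep_len(anticoagulation, k),
    dialysis_mode = rep_len(dialysis_mode, k)))
}

random_panel <- function(n) {
  data.frame(bilirubin = exp(runif(n, log(2.5), log(1000))),
             creatinine = exp(runif(n, log(20), log(780))),
             inr = exp(runif(n, log(0.85), log(12))),
             dialysis = runif(n) < 0.1)
}
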