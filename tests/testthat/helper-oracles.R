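# Independent brute-force oracles and fixture builders.

# Reference-chart scorer: a literal linear search over the published
# inclusive bands, written independently of the package's band tables.
oracle_score <- function(rr, spo2, oxy, sbp, hr, cons, temp) {
  s_rr <- if (rr <= 8) 3 else if (rr <= 11) 1 else if (rr <= 20) 0 else
    if (rr <= 24) 2 else 3
  s_spo2 <- if (spo2 <= 91) 3 else if (spo2 <= 93) 2 else if (spo2 <= 95) 1
    else 0
  s_oxy <- if (oxy) 2 else 0
  s_sbp <- if (sbp <= 90) 3 else if (sbp <= 100) 2 else if (sbp <= 110) 1
    else if (sbp <= 219) 0 else 3
  s_hr <- if (hr <= 40) 3 else if (hr <= 50) 1 else if (hr <= 90) 0 else
    if (hr <= 110) 1 else if (hr <= 130) 2 else 3
  s_cons <- if (cons == "alert") 0 else 3
  # temperatures recorded at one decimal
  t10 <- round(temp * 10)
  s_temp <- if (t10 <= 350) 3 else if (t10 <= 360) 1 else if (t10 <= 380) 0
    else if (t10 <= 390) 1 else 2
  s_rr + s_spo2 + s_oxy + s_sbp + s_hr + s_cons + s_temp
}

random_observations <- function(n) {
  data.frame(
    respiratory_rate = sample(0:45, n, replace = TRUE),
    spo2 = sample(60:100, n, replace = TRUE),
    on_oxygen = sample(c(TRUE, FALSE), n, replace = TRUE),
    systolic_bp = sample(40:240, n, replace = TRUE),
    heart_rate = sample(20:185, n, replace = TRUE),
    consciousness = sample(c("alert", "new_confusion", "voice", "pain",
                             "unresponsive"), n, replace = TRUE),
    temperature = round(runif(n, 33, 41.5), 1))
}

# O(n^2) brute-force sustained-trigger scan: try every candidate index.
oracle_trigger_index <- function(scores, high = 7, floor = 5) {
  n <- length(scores)
  for (i in seq_len(n)) {
    if (scores[i] >= high &&
        (i == n || all(scores[(i + 1):n] >= floor)))
      return(i)
  }
  NULL
}

# Exact two-sided Fisher p by hypergeometric point-probability enumeration.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pre-scored timeline fixture for derive_cohort tests: observations carry
# news_total directly (hours are offsets from the hospital admission).
make_patient <- function(pid, score_hours, scores,
                         door_hour, pathway = c("ward", "ed", "theatre"),
                         t0 = as.POSIXct("2019-05-06 09:00", tz = "UTC")) {
  pathway <- match.arg(pathway)
  door <- t0 + door_hour * 3600
  obs <- if (length(scores))
    data.frame(patient_id = pid, timestamp = t0 + score_hours * 3600,
               news_total = as.integer(scores))
  else data.frame(patient_id = character(), timestamp = as.POSIXct(character()),
                  news_total = integer())
  ward_start <- t0 + 3600
  ev <- data.frame(
    patient_id = pid,
    event_type = c("hospital_admission", "ed_stay",
                   if (pathway != "ed") "ward_stay",
                   if (pathway == "theatre") "theatre_visit",
                   "critical_care_admission"),
    start = c(t0, t0,
              if (pathway != "ed") ward_start,
              if (pathway == "theatre") door - 2 * 3600,
              door),
    end = c(t0, if (pathway == "ed") door else ward_start,
            if (pathway == "theatre") c(door - 2 * 3600, door)
            else if (pathway == "ward") door,
            door + 2 * 86400),
    first_heart_rate_time = as.POSIXct(NA))
  ev$first_heart_rate_time[ev$event_type == "critical_care_admission"] <- door
  list(observations = obs, events = ev)
}

complete_covariates <- function(pids) {
  n <- length(pids)
  if (n == 0) return(complete_covariates("placeholder")[0, ])
  data.frame(patient_id = pids, age = 60, male = TRUE, charlson = 5,
             frailty = 1, sofa_day1 = 4, niv_or_imv = FALSE, sepsis = FALSE,
             elective_admission = FALSE, peri_arrest_call = FALSE,
             cc_death = FALSE, hospital_death = FALSE, cc_los_days = 3,
             hospital_los_days = rep(10, n))
}

bind_patients <- function(patients) {
  list(observations = do.call(rbind, lapply(patients, `[[`, "observations")),
       events = do.call(rbind, lapply(patients, `[[`, "events")))
}
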