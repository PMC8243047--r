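#' Configuration for the synthetic ward-EHR generator
#'
#' Defaults emulate the study conditions of a large UK academic centre with a
#' fully deployed NEWS protocol: roughly half of screened critical-care
#' admissions arrive directly from the emergency department, ~39 percent
#' never sustain a high score, admission latency after the trigger is
#' lognormal with median 6.3 h (IQR ~3.8--10.3), critical-care mortality is
#' ~16 percent at baseline, and the per-hour exposure effect on the odds of
#' critical-care death is 1.02.
#'
#' @param n_patients Number of screened critical-care admissions to simulate.
#' @param seed Integer seed (mandatory; every draw flows from it).
#' @param fraction_ed_direct,fraction_theatre,fraction_not_sustained,fraction_over_cap
#'   Fractions of patients constructed to violate, respectively, the
#'   ward-pathway rule (ED-direct or intervening theatre visit), the
#'   sustained-trigger rule, and the 7-day exposure cap.
#' @param fraction_missing Fraction of otherwise-includable patients given one
#'   missing analysis covariate (complete-case exclusion).
#' @param latency_dist \code{"lognormal"} (default) or \code{"gamma"} shape
#'   for the trigger-to-door latency.
#' @param latency_meanlog,latency_sdlog Lognormal latency parameters in hours
#'   (defaults reproduce median 6.3, IQR 3.8--10.3).
#' @param onset_meanlog_days,onset_sdlog_days Lognormal days from hospital
#'   admission to deterioration onset (defaults give median 3.3, IQR
#'   ~1.1--10.3).
#' @param trigger_news_probs Named probability vector over triggering NEWS
#'   values 7..14 (default median 8, IQR 7--9).
#' @param beta_cc_death Named generating coefficients (log-odds scale) of the
#'   critical-care mortality model; must contain \code{intercept} and may
#'   contain \code{std_hours}, \code{age}, \code{sofa_day1},
#'   \code{niv_or_imv}, \code{charlson}, \code{frailty},
#'   \code{time_to_trigger_days}.
#' @param p_death_post_cc Additional hospital-death probability for
#'   critical-care survivors.
#' @param gamma_cc_los Named generating coefficients (log-days scale) of the
#'   critical-care length-of-stay model (\code{intercept}, \code{std_hours},
#'   \code{sepsis}, \code{niv_or_imv}).
#' @param sigma_cc_los Residual SD of log length of stay.
#' @param study_start,study_end Window over which hospital admissions are
#'   scattered.
#' @return A list of class \code{std_generator_config}.
#' @export
generator_config <- function(
    n_patients = 1000L,
    seed,
    fraction_ed_direct = 0.4995,
    fraction_theatre = 0,
    fraction_not_sustained = 0.3913,
    fraction_over_cap = 0.005,
    fraction_missing = 0.0127,
    latency_dist = c("lognormal", "gamma"),
    latency_meanlog = 1.8406,
    latency_sdlog = 0.7320,
    onset_meanlog_days = log(3.3),
    onset_sdlog_days = 1.658,
    trigger_news_probs = c("7" = 0.35, "8" = 0.30, "9" = 0.15, "10" = 0.10,
                           "11" = 0.05, "12" = 0.03, "13" = 0.01,
                           "14" = 0.01),
    beta_cc_death = c(intercept = -4.415, std_hours = log(1.02),
                      age = log(1.02), sofa_day1 = log(1.2),
                      niv_or_imv = log(1.73), charlson = log(0.98),
                      frailty = log(0.9), time_to_trigger_days = log(1.02)),
    p_death_post_cc = 0.132,
    gamma_cc_los = c(intercept = 0.36, std_hours = 0.012, sepsis = 0.32,
                     niv_or_imv = 0.67),
    sigma_cc_los = 0.8,
    study_start = as.POSIXct("2017-01-01 00:00", tz = "UTC"),
    study_end = as.POSIXct("2021-03-01 00:00", tz = "UTC")) {
  if (missing(seed)) stop("generator_config() requires a seed", call. = FALSE)
  latency_dist <- match.arg(latency_dist)
  fr <- c(fraction_ed_direct, fraction_theatre, fraction_not_sustained,
          fraction_over_cap, fraction_missing)
  if (any(fr < 0 | fr > 1) ||
      fraction_ed_direct + fraction_theatre + fraction_not_sustained +
        fraction_over_cap > 1)
    stop("violation fractions must lie in [0,1] and sum to at most 1",
         call. = FALSE)
  if (abs(sum(trigger_news_probs) - 1) > 1e-8 ||
      any(as.integer(names(trigger_news_probs)) < 7))
    stop("trigger_news_probs must sum to 1 over values >= 7", call. = FALSE)
  n_patients <- as.integer(n_patients)
  seed <- as.integer(seed)
  structure(as.list(environment()), class = "std_generator_config")
}

# Draw per-patient static covariates; marginals match the descriptive table
# of the emulated study population.
draw_covariates <- function(n) {
  age <- round(pmin(pmax(stats::rnorm(n, 65, 14), 18), 100))
  frailty0 <- stats::runif(n) < 0.52
  frailty <- ifelse(frailty0, 0,
                    round(stats::rgamma(n, 1.3, scale = 2.8), 1))
  data.frame(
    age = age,
    male = stats::runif(n) < 0.608,
    charlson = round(stats::rgamma(n, 1.9, scale = 6.5)),
    frailty = frailty,
    sofa_day1 = round(stats::rgamma(n, 3, scale = 1.9)),
    niv_or_imv = stats::runif(n) < 0.427,
    sepsis = stats::runif(n) < 0.356,
    elective_admission = stats::runif(n) < 0.229,
    peri_arrest_call = stats::runif(n) < 0.109)
}

# Allocate total NEWS values across the seven components (vectorised over a
# vector of totals). The binary-valued components (oxygen weight 0/2,
# consciousness 0/3) are placed first; the remaining total, by then at most
# 15, is always realisable by the five numeric components (each attains
# 0..3). Oxygen and non-alert consciousness become more likely at higher
# totals, mimicking escalating support.
allocate_components <- function(totals) {
  m <- length(totals)
  rem <- as.integer(totals)
  # supplemental oxygen: forced on when the rest cannot absorb the total
  can_off <- rem <= 18L
  can_on <- rem >= 2L
  p_oxy <- pmin(0.95, 0.10 + rem * 0.06)
  oxy <- ifelse(can_on & (!can_off | stats::runif(m) < p_oxy), 2L, 0L)
  rem <- rem - oxy
  can_alert <- rem <= 15L
  can_cvpu <- rem >= 3L
  p_cvpu <- pmin(0.9, 0.03 + rem * 0.02)
  cons <- ifelse(can_cvpu & (!can_alert | stats::runif(m) < p_cvpu), 3L, 0L)
  rem <- rem - cons
  comp <- list(on_oxygen = oxy, consciousness = cons)
  left <- 12L  # max attainable by the numeric components not yet assigned
  for (nm in c("respiratory_rate", "spo2", "systolic_bp", "heart_rate",
               "temperature")) {
    lo <- pmax(0L, rem - left)
    hi <- pmin(3L, rem)
    v <- lo + as.integer(floor(stats::runif(m) * (hi - lo + 1L)))
    v <- pmin(v, hi)
    comp[[nm]] <- v
    rem <- rem - v
    left <- left - 3L
  }
  comp
}

# Physiologic sampling window for each parameter: top bands are capped and
# bottom bands floored so generated vitals stay plausible.
vital_caps <- list(respiratory_rate = 50, spo2 = 100, systolic_bp = 250,
                   heart_rate = 190, temperature = 41.9)
vital_floors <- list(respiratory_rate = 4, spo2 = 70, systolic_bp = 50,
                     heart_rate = 25, temperature = 33)

# Vectorised: sample, for each element of `scores`, a value of `param`
# uniformly within a band realising that component score.
components_to_vitals <- function(param, scores, bands) {
  b <- bands$parameters[[param]]
  step <- if (param == "temperature") 0.1 else 1
  out <- numeric(length(scores))
  for (s in unique(scores)) {
    rows <- which(b$score == s)
    idx <- which(scores == s)
    pick <- rows[sample.int(length(rows), length(idx), replace = TRUE)]
    lo <- pmax(b$lo[pick], vital_floors[[param]])
    hi <- pmin(ifelse(is.infinite(b$hi[pick]),
                      vital_caps[[param]] + step, b$hi[pick]),
               vital_caps[[param]] + step)
    k <- round((hi - lo) / step)  # values lo, lo+step, ..., hi-step
    out[idx] <- lo + floor(stats::runif(length(idx)) * k) * step
  }
  if (step == 1) out <- as.integer(out) else out <- round(out, 1)
  out
}

scores_to_observations <- function(patient_id, times, totals, bands) {
  n <- length(times)
  comp <- allocate_components(totals)
  cons_levels <- c("new_confusion", "voice", "pain", "unresponsive")
  cons <- rep("alert", n)
  ncv <- sum(comp$consciousness > 0L)
  if (ncv) cons[comp$consciousness > 0L] <-
      cons_levels[sample.int(4L, ncv, replace = TRUE)]
  data.frame(
    patient_id = rep(patient_id, length.out = n), timestamp = times,
    respiratory_rate = components_to_vitals("respiratory_rate",
                                            comp$respiratory_rate, bands),
    spo2 = components_to_vitals("spo2", comp$spo2, bands),
    on_oxygen = comp$on_oxygen > 0L,
    systolic_bp = components_to_vitals("systolic_bp", comp$systolic_bp,
                                       bands),
    heart_rate = components_to_vitals("heart_rate", comp$heart_rate, bands),
    consciousness = cons,
    temperature = components_to_vitals("temperature", comp$temperature,
                                       bands))
}

minutes <- function(t) as.POSIXct(round(as.numeric(t) / 60) * 60,
                                  origin = "1970-01-01", tz = "UTC")

#' Simulate ward observation and admission-event tables
#'
#' Generates one screened critical-care admission per patient. Each patient is
#' assigned a pathway category (included, ED-direct, theatre-intervened,
#' never-sustained, over the 7-day cap); vitals are produced by drawing a
#' target NEWS for every observation slot (baseline 0--4, a short ramp, then
#' a sustained >= 5 plateau after the trigger for compliant categories) and
#' sampling each vital uniformly inside the band realising its component
#' score, so the scored trajectory reproduces the intended category exactly.
#' Observation frequency follows the escalation protocol: ~6-hourly at low
#' scores, hourly once the score is high.
#'
#' @param cfg A [generator_config()].
#' @return List with \code{observations}, \code{events} and \code{truth} (the
#'   per-patient generating record: category, trigger time and score, true
#'   Score-to-Door hours, covariates).
#' @export
simulate_trajectories <- function(cfg) {
  stopifnot(inherits(cfg, "std_generator_config"))
  set.seed(cfg$seed)
  n <- cfg$n_patients
  bands <- news_bands()
  if (n == 0L)
    return(list(observations = empty_observations(),
                events = empty_events(),
                truth = cbind(data.frame(patient_id = character(),
                                         category = character(),
                                         missing_flag = logical(),
                                         trigger_news = integer(),
                                         std_hours = numeric(),
                                         time_to_trigger_days = numeric(),
                                         trigger_time = as.POSIXct(character()),
                                         out_of_hours = logical()),
                              draw_covariates(0))))
  ids <- sprintf("P%05d", seq_len(n))
  category <- sample(c("ed_direct", "theatre", "not_sustained", "over_cap",
                       "included"), n, replace = TRUE,
                     prob = c(cfg$fraction_ed_direct, cfg$fraction_theatre,
                              cfg$fraction_not_sustained,
                              cfg$fraction_over_cap,
                              1 - cfg$fraction_ed_direct -
                                cfg$fraction_theatre -
                                cfg$fraction_not_sustained -
                                cfg$fraction_over_cap))
  missing_flag <- category == "included" &
    stats::runif(n) < cfg$fraction_missing
  cov <- draw_covariates(n)
  t0 <- minutes(cfg$study_start +
                  stats::runif(n) * as.numeric(difftime(cfg$study_end,
                                                        cfg$study_start,
                                                        units = "secs")))
  onset_h <- pmax(stats::rlnorm(n, cfg$onset_meanlog_days,
                                cfg$onset_sdlog_days) * 24, 8)
  latency_h <- if (cfg$latency_dist == "lognormal")
    stats::rlnorm(n, cfg$latency_meanlog, cfg$latency_sdlog)
  else {
    shape <- 1 / (exp(cfg$latency_sdlog^2) - 1)
    stats::rgamma(n, shape,
                  scale = exp(cfg$latency_meanlog + cfg$latency_sdlog^2 / 2) /
                    shape)
  }
  latency_h <- pmax(latency_h, 0.5)
  latency_h[category == "over_cap"] <-
    168 + stats::rexp(sum(category == "over_cap"), 1 / 48)
  latency_h[category == "over_cap"] <- pmax(
    latency_h[category == "over_cap"], 168.1)
  latency_h[category != "over_cap"] <- pmin(
    latency_h[category != "over_cap"], 167)
  trigger_news <- sample(as.integer(names(cfg$trigger_news_probs)), n,
                         replace = TRUE, prob = cfg$trigger_news_probs)

  obs_times <- vector("list", n)
  obs_totals <- vector("list", n)
  ev_acc <- list(pid = vector("list", n), type = vector("list", n),
                 start = vector("list", n), end = vector("list", n),
                 fhr = vector("list", n))
  trigger_time <- rep(t0[1], n)
  for (i in seq_len(n)) {
    cat_i <- category[i]
    trig <- minutes(t0[i] + onset_h[i] * 3600)
    door <- minutes(trig + latency_h[i] * 3600)
    trigger_time[i] <- trig
    ev_type <- "hospital_admission"
    ev_start <- as.numeric(t0[i])
    ev_end <- as.numeric(t0[i])
    ev_fhr <- NA_real_
    if (cat_i == "ed_direct") {
      ev_type <- c(ev_type, "ed_stay", "critical_care_admission")
      ev_start <- c(ev_start, as.numeric(t0[i]), as.numeric(door))
      ev_end <- c(ev_end, as.numeric(door), as.numeric(door) + 3 * 86400)
      ev_fhr <- c(ev_fhr, NA_real_, as.numeric(door) + 120)
      times <- numeric(0); totals <- integer(0)
    } else {
      ward_start <- minutes(t0[i] + 4 * 3600)
      pre_end <- trig - 90 * 60
      pre_times <- if (pre_end > ward_start)
        seq(ward_start, pre_end, by = 6 * 3600) else ward_start
      pre_scores <- sample(0:4, length(pre_times), replace = TRUE,
                           prob = c(0.4, 0.3, 0.15, 0.1, 0.05))
      ramp_time <- trig - 45 * 60
      post_times <- seq(trig, door - 61, by = 3600)
      n_post <- length(post_times) - 1L
      plateau <- if (n_post > 0) {
        if (cat_i == "not_sustained")
          sample(5:6, n_post, replace = TRUE)
        else
          pmax(5L, pmin(16L, trigger_news[i] +
                          sample(-2:2, n_post, replace = TRUE)))
      } else integer(0)
      first_score <- if (cat_i == "not_sustained" &&
                         stats::runif(1) < 0.5) 6L else trigger_news[i]
      times <- c(pre_times, ramp_time, post_times)
      totals <- c(pre_scores, sample(5:6, 1),
                  first_score, plateau)
      if (cat_i == "not_sustained" && first_score >= 7L) {
        # a reached trigger must be disqualified by a later sub-floor score;
        # clear the grid around the dip so deduplication cannot remove it
        dip_time <- minutes(door - 600)
        apart <- abs(as.numeric(times) - as.numeric(dip_time)) > 300
        times <- c(times[apart], dip_time)
        totals <- c(totals[apart], sample(0:4, 1))
      }
      keep <- !duplicated(as.numeric(times)) & times < door
      times <- as.numeric(times[keep]); totals <- totals[keep]
      o <- order(times)
      times <- times[o]; totals <- totals[o]
      ev_type <- c(ev_type, "ed_stay")
      ev_start <- c(ev_start, as.numeric(t0[i]))
      ev_end <- c(ev_end, as.numeric(ward_start))
      ev_fhr <- c(ev_fhr, NA_real_)
      if (cat_i == "theatre") {
        theatre_start <- minutes(door - 3 * 3600)
        ev_type <- c(ev_type, "ward_stay", "theatre_visit")
        ev_start <- c(ev_start, as.numeric(ward_start),
                      as.numeric(theatre_start))
        ev_end <- c(ev_end, as.numeric(theatre_start), as.numeric(door))
        ev_fhr <- c(ev_fhr, NA_real_, NA_real_)
      } else {
        ev_type <- c(ev_type, "ward_stay")
        ev_start <- c(ev_start, as.numeric(ward_start))
        ev_end <- c(ev_end, as.numeric(door))
        ev_fhr <- c(ev_fhr, NA_real_)
      }
      ev_type <- c(ev_type, "critical_care_admission")
      ev_start <- c(ev_start, as.numeric(door))
      ev_end <- c(ev_end, as.numeric(door) + 3 * 86400)
      ev_fhr <- c(ev_fhr, as.numeric(door) + 300)
    }
    obs_times[[i]] <- times
    obs_totals[[i]] <- totals
    ev_acc$pid[[i]] <- rep(ids[i], length(ev_type))
    ev_acc$type[[i]] <- ev_type
    ev_acc$start[[i]] <- ev_start
    ev_acc$end[[i]] <- ev_end
    ev_acc$fhr[[i]] <- ev_fhr
  }
  n_obs <- lengths(obs_times)
  observations <- if (sum(n_obs) == 0L) empty_observations() else
    scores_to_observations(
      rep(ids, n_obs),
      as.POSIXct(unlist(obs_times), origin = "1970-01-01", tz = "UTC"),
      unlist(obs_totals), bands)
  as_time <- function(x) as.POSIXct(x, origin = "1970-01-01", tz = "UTC")
  events <- data.frame(
    patient_id = unlist(ev_acc$pid),
    event_type = unlist(ev_acc$type),
    start = as_time(unlist(ev_acc$start)),
    end = as_time(unlist(ev_acc$end)),
    first_heart_rate_time = as_time(unlist(ev_acc$fhr)))
  fhr <- events$first_heart_rate_time[
    events$event_type == "critical_care_admission"]
  truth <- cbind(
    data.frame(patient_id = ids, category = category,
               missing_flag = missing_flag, trigger_news = trigger_news,
               std_hours = as.numeric(difftime(fhr, trigger_time,
                                               units = "hours")),
               time_to_trigger_days = as.numeric(difftime(trigger_time, t0,
                                                          units = "days")),
               trigger_time = trigger_time,
               out_of_hours = is_out_of_hours(trigger_time)),
    cov)
  list(observations = observations, events = events, truth = truth)
}

empty_observations <- function() {
  data.frame(patient_id = character(), timestamp = as.POSIXct(character()),
             respiratory_rate = integer(), spo2 = integer(),
             on_oxygen = logical(), systolic_bp = integer(),
             heart_rate = integer(), consciousness = character(),
             temperature = numeric())
}

empty_events <- function() {
  data.frame(patient_id = character(), event_type = character(),
             start = as.POSIXct(character()), end = as.POSIXct(character()),
             first_heart_rate_time = as.POSIXct(character()))
}

#' Assign outcomes from the generating regression models
#'
#' Critical-care death follows a logistic model in the true exposure and
#' covariates; hospital death comprises critical-care deaths plus an
#' independent post-critical-care hazard among survivors; critical-care
#' length of stay follows a log-linear model with Gaussian residuals on the
#' log scale (the generating model applies to survivors, per the analysis it
#' feeds; decedents' stays are drawn from the same model, representing time
#' to death).
#'
#' @param truth Per-patient truth table from [simulate_trajectories()] (needs
#'   \code{std_hours}, \code{time_to_trigger_days} and the covariates).
#' @param cfg A [generator_config()].
#' @return \code{truth} with added columns \code{cc_death},
#'   \code{hospital_death}, \code{cc_los_days}, \code{hospital_los_days}.
#' @export
assign_outcomes <- function(truth, cfg) {
  stopifnot(inherits(cfg, "std_generator_config"))
  n <- nrow(truth)
  b <- cfg$beta_cc_death
  lp <- rep(b[["intercept"]], n)
  for (nm in setdiff(names(b), "intercept")) {
    if (!nm %in% names(truth))
      stop("generating coefficient '", nm, "' has no matching column",
           call. = FALSE)
    lp <- lp + b[[nm]] * as.numeric(truth[[nm]])
  }
  if (any(!is.finite(lp))) stop("non-finite linear predictor", call. = FALSE)
  truth$cc_death <- stats::runif(n) < stats::plogis(lp)
  truth$hospital_death <- truth$cc_death |
    stats::runif(n) < cfg$p_death_post_cc
  g <- cfg$gamma_cc_los
  lp_los <- rep(g[["intercept"]], n)
  for (nm in setdiff(names(g), "intercept")) {
    if (!nm %in% names(truth))
      stop("generating coefficient '", nm, "' has no matching column",
           call. = FALSE)
    lp_los <- lp_los + g[[nm]] * as.numeric(truth[[nm]])
  }
  truth$cc_los_days <- exp(lp_los + stats::rnorm(n, 0, cfg$sigma_cc_los))
  truth$hospital_los_days <- truth$cc_los_days +
    stats::rlnorm(n, log(10), 0.9)
  truth
}

#' Simulate a complete synthetic study
#'
#' Runs [simulate_trajectories()] and [assign_outcomes()] and shapes the
#' result into the three tables the derivation stage consumes, plus the
#' generating truth. Missingness is injected completely at random: each
#' flagged patient loses one randomly chosen analysis covariate.
#'
#' @param cfg A [generator_config()].
#' @return List with \code{observations}, \code{events}, \code{covariates}
#'   (including outcomes) and \code{truth}.
#' @export
simulate_study <- function(cfg) {
  sim <- simulate_trajectories(cfg)
  truth <- assign_outcomes(sim$truth, cfg)
  covariates <- truth[, c("patient_id", "age", "male", "charlson", "frailty",
                          "sofa_day1", "niv_or_imv", "sepsis",
                          "elective_admission", "peri_arrest_call",
                          "cc_death", "hospital_death", "cc_los_days",
                          "hospital_los_days")]
  maskable <- c("age", "charlson", "frailty", "sofa_day1")
  for (i in which(truth$missing_flag))
    covariates[i, sample(maskable, 1)] <- NA
  list(observations = sim$observations, events = sim$events,
       covariates = covariates, truth = truth)
}
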