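#' Detect the sustained high-NEWS trigger in a scored timeline
#'
#' The inclusion rule for the analysis cohort: the trigger is the EARLIEST
#' pre-admission observation scoring at or above \code{high_threshold}
#' (default 7) such that every subsequent observation strictly before
#' \code{admission_time} scores at or above \code{floor} (default 5). A score
#' of exactly \code{floor} is tolerated ("did not decrease below 5" read
#' literally); an observation timestamped exactly at \code{admission_time} is
#' outside the pre-admission interval and ignored.
#'
#' @param scores Integer vector of NEWS totals, ordered by time.
#' @param times \code{POSIXct} timestamps, strictly increasing, same length as
#'   \code{scores}.
#' @param admission_time \code{POSIXct} time of critical-care admission; only
#'   observations strictly before it are considered.
#' @param high_threshold Trigger threshold (default 7).
#' @param floor Sustain floor (default 5).
#' @return \code{NULL} if no observation qualifies, otherwise a list with
#'   \code{time}, \code{score} and \code{index} (position in the input).
#' @examples
#' t0 <- as.POSIXct("2020-01-01 08:00", tz = "UTC")
#' tt <- t0 + 3600 * (0:3)
#' detect_sustained_trigger(c(8, 4, 9, 7), tt, t0 + 3600 * 10)$score  # 9
#' @export
detect_sustained_trigger <- function(scores, times, admission_time,
                                     high_threshold = 7L, floor = 5L) {
  if (length(scores) != length(times))
    stop("scores and times must have equal length", call. = FALSE)
  if (length(scores) == 0L) return(NULL)
  if (is.unsorted(times, strictly = TRUE))
    stop("observation times must be strictly increasing", call. = FALSE)
  keep <- times < admission_time
  scores <- scores[keep]
  times <- times[keep]
  if (length(scores) == 0L) return(NULL)
  # suffix minimum: sustained iff min over the tail >= floor
  suffix_min <- rev(cummin(rev(scores)))
  ok <- scores >= high_threshold & suffix_min >= floor
  if (!any(ok)) return(NULL)
  i <- which(ok)[1L]
  list(time = times[i], score = scores[i], index = which(keep)[i])
}

#' Score-to-Door time in decimal hours
#'
#' The exposure of interest: hours from the sustained trigger to critical-care
#' admission, with admission timed by the first recorded heart rate in
#' critical care (an observation-based surrogate that avoids administrative
#' timestamp error).
#'
#' @param trigger_time \code{POSIXct} trigger time.
#' @param first_heart_rate_time \code{POSIXct} first recorded heart rate in
#'   the critical-care episode.
#' @return Decimal hours (positive).
#' @examples
#' compute_score_to_door(as.POSIXct("2020-03-02 10:00", tz = "UTC"),
#'                       as.POSIXct("2020-03-02 16:18", tz = "UTC"))  # 6.3
#' @export
compute_score_to_door <- function(trigger_time, first_heart_rate_time) {
  if (anyNA(first_heart_rate_time))
    stop("first_heart_rate_time is missing", call. = FALSE)
  hours <- as.numeric(difftime(first_heart_rate_time, trigger_time,
                               units = "hours"))
  if (any(hours < 0))
    stop("critical-care door time precedes the trigger", call. = FALSE)
  if (any(hours == 0))
    stop("non-positive Score-to-Door exposure (door equals trigger)",
         call. = FALSE)
  hours
}

#' Out-of-hours indicator
#'
#' Out-of-hours is the whole weekend, \code{[Saturday 00:00, Monday 00:00)},
#' plus weekday nights \code{[20:00, 24:00)} and \code{[00:00, 08:00)}. The
#' windows are half-open, so Monday 08:00 itself is in hours and the
#' indicator integrates to exactly 48 + 5 x 12 = 108 hours over a week.
#'
#' @param t \code{POSIXct} vector (timezone-naive timestamps should be parsed
#'   in a fixed zone, e.g. UTC).
#' @return Logical vector.
#' @examples
#' is_out_of_hours(as.POSIXct("2021-02-02 19:59", tz = "UTC"))  # Tue, FALSE
#' is_out_of_hours(as.POSIXct("2021-02-02 20:00", tz = "UTC"))  # Tue, TRUE
#' @export
is_out_of_hours <- function(t) {
  wday <- as.integer(format(t, "%u"))  # 1 = Monday ... 7 = Sunday
  lt <- as.POSIXlt(t)
  hour_frac <- lt$hour + lt$min / 60 + lt$sec / 3600
  weekend <- wday >= 6L
  night <- hour_frac >= 20 | hour_frac < 8
  weekend | (!weekend & night)
}

#' Derive the sustained-derangement analysis cohort
#'
#' Applies the inclusion/exclusion algorithm to scored ward observations and
#' admission events, producing one cohort row per included patient (for the
#' first qualifying critical-care admission) and a step-ordered exclusion
#' ledger. Steps, in order, each patient counted once at the first failing
#' step:
#' \enumerate{
#'   \item \emph{pathway}: the admission must come from a level-1 ward -- not
#'     directly from the emergency department and with no intervening theatre
#'     visit (both counted under \code{excluded_direct_ed}, the dominant
#'     cause);
#'   \item \emph{sustained trigger}: a NEWS >= \code{high_threshold} never
#'     followed by a pre-admission score below \code{floor};
#'   \item \emph{exposure cap}: Score-to-Door time at most \code{cap_hours};
#'   \item \emph{complete case}: all analysis covariates and outcomes present.
#' }
#'
#' @param observations Data frame of raw observations (columns
#'   \code{patient_id}, \code{timestamp}, and the seven scoring inputs of
#'   [score_news()]); or an already-scored table containing
#'   \code{news_total}.
#' @param events Data frame of admission events: \code{patient_id},
#'   \code{event_type} (\code{hospital_admission}, \code{ed_stay},
#'   \code{ward_stay}, \code{theatre_visit}, \code{critical_care_admission},
#'   \code{discharge}, \code{death}), \code{start}, \code{end},
#'   \code{first_heart_rate_time} (critical-care rows only).
#' @param covariates Data frame keyed by \code{patient_id} with the analysis
#'   covariates and outcomes (\code{age}, \code{male}, \code{charlson},
#'   \code{frailty}, \code{sofa_day1}, \code{niv_or_imv}, \code{sepsis},
#'   \code{elective_admission}, \code{peri_arrest_call}, \code{cc_death},
#'   \code{hospital_death}, \code{cc_los_days}, \code{hospital_los_days}).
#' @param bands Band table used if \code{observations} still need scoring.
#' @param high_threshold,floor Trigger thresholds (defaults 7 and 5).
#' @param cap_hours Exposure cap in hours (default 168, i.e. 7 days,
#'   inclusive).
#' @return A list of class \code{std_cohort_result}: \code{cohort} (data
#'   frame of included complete-case patients), \code{cohort_imputable} (the
#'   same rows plus the patients excluded only for missing data, flagged by
#'   \code{complete_case} -- the input to the median-imputation sensitivity
#'   analysis) and \code{ledger} (see [exclusion_ledger()]).
#' @export
derive_cohort <- function(observations, events, covariates,
                          bands = news_bands(),
                          high_threshold = 7L, floor = 5L, cap_hours = 168) {
  stopifnot(is.data.frame(events), is.data.frame(covariates))
  if (nrow(events) > 0 && !"news_total" %in% names(observations) &&
      nrow(observations) > 0)
    observations <- score_news(observations, bands)

  cc <- events[events$event_type == "critical_care_admission", , drop = FALSE]
  if (anyDuplicated(cc$patient_id)) {
    # index episode: the FIRST critical-care admission per hospital stay
    cc <- cc[order(cc$patient_id, cc$start), , drop = FALSE]
    cc <- cc[!duplicated(cc$patient_id), , drop = FALSE]
  }
  n_total <- nrow(cc)
  counts <- c(direct_ed = 0L, not_sustained = 0L, over_cap = 0L,
              missing_data = 0L)
  analysis_vars <- c("age", "male", "charlson", "frailty", "sofa_day1",
                     "niv_or_imv", "sepsis", "elective_admission",
                     "peri_arrest_call", "cc_death", "hospital_death",
                     "cc_los_days", "hospital_los_days")
  if (anyDuplicated(covariates$patient_id))
    stop("duplicate covariate rows for patient(s) ",
         paste(unique(covariates$patient_id[
           duplicated(covariates$patient_id)]), collapse = ", "),
         call. = FALSE)
  if (anyNA(cc$first_heart_rate_time) && n_total > 0)
    stop("critical-care episode for patient ",
         cc$patient_id[which(is.na(cc$first_heart_rate_time))[1]],
         " lacks first_heart_rate_time", call. = FALSE)
  ids <- cc$patient_id

  # step 1 (vectorised): the event immediately preceding critical care must
  # be a ward stay -- not an ED stay and not a theatre visit
  prior <- events[events$event_type %in%
                    c("ed_stay", "ward_stay", "theatre_visit"), , drop = FALSE]
  prior_cc_start <- cc$start[match(prior$patient_id, ids)]
  prior <- prior[!is.na(prior_cc_start) & prior$start < prior_cc_start, ,
                 drop = FALSE]
  prior <- prior[order(prior$patient_id, -as.numeric(prior$start)), ,
                 drop = FALSE]
  first_of <- !duplicated(prior$patient_id)
  last_type <- stats::setNames(prior$event_type[first_of],
                               prior$patient_id[first_of])
  from_ward <- !is.na(last_type[as.character(ids)]) &
    last_type[as.character(ids)] == "ward_stay"
  from_ward[is.na(from_ward)] <- FALSE
  counts["direct_ed"] <- sum(!from_ward)

  adm <- events[events$event_type == "hospital_admission", , drop = FALSE]
  adm_time <- tapply(as.numeric(adm$start), adm$patient_id, min)

  # per-patient sorted observation index lists over plain vectors
  ts_all <- as.numeric(observations$timestamp)
  sc_all <- observations$news_total
  o <- order(observations$patient_id, ts_all)
  dup <- o[which(diff(ts_all[o]) == 0 &
                   observations$patient_id[o][-length(o)] ==
                   observations$patient_id[o][-1])]
  if (length(dup))
    stop("duplicate observation timestamps for patient ",
         observations$patient_id[dup[1]], call. = FALSE)
  obs_split <- if (nrow(observations))
    split(o, observations$patient_id[o]) else list()
  door_num <- as.numeric(cc$first_heart_rate_time)

  trig_time <- trig_score <- std_hours <- rep(NA_real_, n_total)
  for (i in which(from_ward)) {
    ii <- obs_split[[as.character(ids[i])]]
    trig <- detect_sustained_trigger(sc_all[ii], ts_all[ii], door_num[i],
                                     high_threshold, floor)
    if (is.null(trig)) {
      counts["not_sustained"] <- counts["not_sustained"] + 1L
      next
    }
    h <- (door_num[i] - trig$time) / 3600
    if (h <= 0)
      stop("non-positive Score-to-Door exposure for patient ", ids[i],
           call. = FALSE)
    if (h > cap_hours) {
      counts["over_cap"] <- counts["over_cap"] + 1L
      next
    }
    trig_time[i] <- trig$time
    trig_score[i] <- trig$score
    std_hours[i] <- h
  }

  sel <- which(!is.na(std_hours))
  covrows <- covariates[match(ids[sel], covariates$patient_id),
                        intersect(analysis_vars, names(covariates)),
                        drop = FALSE]
  for (v in setdiff(analysis_vars, names(covrows))) covrows[[v]] <- NA
  covrows <- covrows[, analysis_vars, drop = FALSE]
  complete <- stats::complete.cases(covrows)
  counts["missing_data"] <- sum(!complete)

  all_rows <- if (length(sel)) {
    tt <- as.POSIXct(trig_time[sel], origin = "1970-01-01", tz = "UTC")
    data.frame(
      patient_id = ids[sel],
      trigger_time = tt,
      trigger_news = as.integer(trig_score[sel]),
      door_time = cc$first_heart_rate_time[sel],
      std_hours = std_hours[sel],
      time_to_trigger_days =
        (trig_time[sel] - as.numeric(adm_time[as.character(ids[sel])])) /
          86400,
      out_of_hours = is_out_of_hours(tt),
      covrows,
      complete_case = complete,
      row.names = NULL)
  } else empty_cohort()
  cohort <- all_rows[all_rows$complete_case %in% TRUE, , drop = FALSE]
  structure(list(cohort = cohort,
                 cohort_imputable = all_rows,
                 ledger = exclusion_ledger(n_total, counts)),
            class = "std_cohort_result")
}

empty_cohort <- function() {
  data.frame(patient_id = character(), trigger_time = as.POSIXct(character()),
             trigger_news = integer(), door_time = as.POSIXct(character()),
             std_hours = numeric(), time_to_trigger_days = numeric(),
             out_of_hours = logical(), complete_case = logical())
}

#' Exclusion ledger
#'
#' Step-ordered accounting of the cohort derivation: every screened
#' critical-care admission is counted exactly once, either at the first
#' exclusion step it fails or as included, so the counts always sum to the
#' input total.
#'
#' @param n_total Number of unplanned critical-care admissions screened.
#' @param counts Named integer vector with elements \code{direct_ed},
#'   \code{not_sustained}, \code{over_cap}, \code{missing_data}.
#' @return Data frame of class \code{std_ledger} with columns \code{step} and
#'   \code{n}.
#' @export
exclusion_ledger <- function(n_total, counts) {
  included <- n_total - sum(counts)
  stopifnot(included >= 0)
  structure(
    data.frame(step = c("total_screened", "excluded_direct_ed",
                        "excluded_not_sustained", "excluded_over_7_days",
                        "excluded_missing_data", "included"),
               n = as.integer(c(n_total, counts["direct_ed"],
                                counts["not_sustained"], counts["over_cap"],
                                counts["missing_data"], included))),
    class = c("std_ledger", "data.frame"))
}

#' @export
print.std_cohort_result <- function(x, ...) {
  cat("Score-to-Door cohort derivation\n")
  print.data.frame(x$ledger)
  if (nrow(x$cohort)) {
    med <- stats::median(x$cohort$std_hours)
    iqr <- stats::quantile(x$cohort$std_hours, c(0.25, 0.75))
    cat(sprintf("median Score-to-Door %.1f h [IQR %.1f-%.1f]\n",
                med, iqr[1], iqr[2]))
  }
  invisible(x)
}
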