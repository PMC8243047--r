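#' Score a single vital-sign observation
#'
#' Computes the NEWS total and the per-parameter component breakdown for one
#' observation set. All seven inputs must be present and in range; out-of-range
#' values (e.g. an SpO2 above 100) are rejected rather than clamped, because a
#' silently corrected typo would propagate into cohort derivation.
#'
#' @param obs A list or one-row data frame with elements
#'   \code{respiratory_rate} (breaths/min), \code{spo2} (percent, 0--100),
#'   \code{on_oxygen} (logical), \code{systolic_bp} (mmHg), \code{heart_rate}
#'   (beats/min), \code{consciousness} (one of \code{"alert"},
#'   \code{"new_confusion"}, \code{"voice"}, \code{"pain"},
#'   \code{"unresponsive"}) and \code{temperature} (degrees C, one decimal).
#' @param bands A \code{news_bands} object; defaults to NEWS2 Scale 1.
#' @return An object of class \code{news_result}: list with \code{total}
#'   (integer), \code{components} (named integer vector, including the
#'   \code{on_oxygen} weight) and \code{band_version}.
#' @examples
#' score_observation(list(respiratory_rate = 22, spo2 = 93, on_oxygen = FALSE,
#'                        systolic_bp = 105, heart_rate = 95,
#'                        consciousness = "alert", temperature = 38.5))
#' @export
score_observation <- function(obs, bands = news_bands()) {
  df <- as.data.frame(obs[c("respiratory_rate", "spo2", "on_oxygen",
                            "systolic_bp", "heart_rate", "consciousness",
                            "temperature")], stringsAsFactors = FALSE)
  sc <- score_news(df, bands)
  comp_cols <- paste0("news_", c("respiratory_rate", "spo2", "on_oxygen",
                                 "systolic_bp", "heart_rate", "consciousness",
                                 "temperature"))
  components <- as.integer(sc[1, comp_cols])
  names(components) <- sub("^news_", "", comp_cols)
  structure(list(total = as.integer(sc$news_total[1]),
                 components = components,
                 band_version = bands$version),
            class = "news_result")
}

#' @export
print.news_result <- function(x, ...) {
  cat("NEWS total ", x$total, " (", x$band_version, ")\n", sep = "")
  print(x$components)
  invisible(x)
}

#' Score a table of observations
#'
#' Vectorised NEWS scoring over a data frame of observation sets. This is the
#' workhorse used by cohort derivation; [score_observation()] is the
#' convenience wrapper for a single set.
#'
#' @param observations Data frame with the seven input columns named as in
#'   [score_observation()] (additional columns such as \code{patient_id} and
#'   \code{timestamp} pass through untouched).
#' @param bands A \code{news_bands} object.
#' @return The input with added integer columns \code{news_<parameter>} (one
#'   per parameter plus \code{news_on_oxygen}) and \code{news_total}.
#' @export
score_news <- function(observations, bands = news_bands()) {
  stopifnot(inherits(bands, "news_bands"))
  needed <- c("respiratory_rate", "spo2", "on_oxygen", "systolic_bp",
              "heart_rate", "consciousness", "temperature")
  miss_col <- setdiff(needed, names(observations))
  if (length(miss_col))
    stop("observations lack column(s): ", paste(miss_col, collapse = ", "),
         call. = FALSE)
  n <- nrow(observations)
  for (nm in needed) {
    bad <- is.na(observations[[nm]])
    if (any(bad))
      stop("missing value for parameter '", nm, "' in observation row(s) ",
           paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  check_range <- function(x, nm, lo, hi = Inf) {
    bad <- x < lo | x > hi
    if (any(bad))
      stop("out-of-range ", nm, " (allowed [", lo, ", ",
           if (is.finite(hi)) hi else "Inf", "]): ",
           paste(utils::head(x[bad], 5), collapse = ", "), call. = FALSE)
  }
  check_range(observations$respiratory_rate, "respiratory_rate", 0)
  check_range(observations$spo2, "spo2", 0, 100)
  check_range(observations$systolic_bp, "systolic_bp", 0)
  check_range(observations$heart_rate, "heart_rate", 0)
  check_range(observations$temperature, "temperature", 0)
  if (!is.logical(observations$on_oxygen))
    stop("on_oxygen must be logical", call. = FALSE)
  cons <- as.character(observations$consciousness)
  bad_cons <- !cons %in% names(bands$consciousness)
  if (any(bad_cons))
    stop("unknown consciousness level(s): ",
         paste(unique(cons[bad_cons]), collapse = ", "), call. = FALSE)

  out <- observations
  band_component <- function(x, tab) {
    # intervals are half-open [lo, hi) and contiguous, so findInterval on the
    # lower bounds is an exact lookup
    tab$score[findInterval(x, tab$lo)]
  }
  numeric_params <- c("respiratory_rate", "spo2", "systolic_bp", "heart_rate",
                      "temperature")
  for (nm in numeric_params)
    out[[paste0("news_", nm)]] <-
      as.integer(band_component(observations[[nm]], bands$parameters[[nm]]))
  out$news_consciousness <- as.integer(bands$consciousness[cons])
  out$news_on_oxygen <- as.integer(ifelse(observations$on_oxygen,
                                          bands$oxygen_weight, 0L))
  out$news_total <- out$news_respiratory_rate + out$news_spo2 +
    out$news_systolic_bp + out$news_heart_rate + out$news_temperature +
    out$news_consciousness + out$news_on_oxygen
  out
}
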