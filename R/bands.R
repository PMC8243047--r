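#' NEWS band tables
#'
#' A band table maps each of the six physiological parameters (respiratory
#' rate, oxygen saturation, systolic blood pressure, heart rate, level of
#' consciousness, temperature) to ordinal component scores in 0--3, plus a
#' fixed weighting added when the patient is on supplemental oxygen.
#' Numeric parameters are banded by ordered half-open intervals
#' \code{[lo, hi)}; consciousness is a categorical map. Two charts ship with
#' the package: \code{"news2_scale1"} (the 2017 revision, SpO2 Scale 1 --
#' the default) and \code{"news_2012"} (the original chart). Both have a
#' maximum attainable total of 20.
#'
#' @param version Either the name of a built-in table (\code{"news2_scale1"}
#'   or \code{"news_2012"}) or a path to a YAML band-table file with the same
#'   structure as the built-in ones (see
#'   \code{system.file("extdata", "news2_scale1.yaml", package = "scoretodoor")}).
#' @param validate Check the table invariants on load (default \code{TRUE}).
#' @return An object of class \code{news_bands}: a list with elements
#'   \code{version}, \code{oxygen_weight}, \code{consciousness} (named map to
#'   scores) and \code{parameters} (per parameter, a data frame with columns
#'   \code{lo}, \code{hi}, \code{score}).
#' @examples
#' bands <- news_bands()
#' max_attainable_score(bands)
#' @export
news_bands <- function(version = "news2_scale1", validate = TRUE) {
  builtin <- c("news2_scale1", "news_2012")
  path <- if (version %in% builtin) {
    system.file("extdata", paste0(version, ".yaml"), package = "scoretodoor",
                mustWork = TRUE)
  } else {
    if (!file.exists(version))
      stop("band table '", version, "' is neither a built-in version (",
           paste(builtin, collapse = ", "), ") nor an existing file",
           call. = FALSE)
    version
  }
  raw <- yaml::read_yaml(path)
  params <- lapply(raw$parameters, function(p) {
    b <- do.call(rbind, lapply(p$bands, function(bd)
      data.frame(lo = as.numeric(bd$lo), hi = as.numeric(bd$hi),
                 score = as.integer(bd$score))))
    b[order(b$lo), , drop = FALSE]
  })
  bands <- structure(
    list(version = raw$version,
         oxygen_weight = as.integer(raw$oxygen_weight),
         consciousness = vapply(raw$consciousness, as.integer, integer(1)),
         parameters = params),
    class = "news_bands")
  if (validate) {
    rep <- validate_band_table(bands)
    if (!rep$valid)
      stop("invalid band table '", raw$version, "':\n",
           paste(rep$problems$message, collapse = "\n"), call. = FALSE)
  }
  bands
}

#' @export
print.news_bands <- function(x, ...) {
  cat("NEWS band table '", x$version, "'\n", sep = "")
  cat("  parameters: ", paste(names(x$parameters), collapse = ", "), "\n",
      sep = "")
  cat("  oxygen weight: ", x$oxygen_weight,
      "; max attainable total: ", max_attainable_score(x), "\n", sep = "")
  invisible(x)
}

#' Validate a NEWS band table
#'
#' Checks the structural invariants a usable chart must satisfy: for every
#' numeric parameter the intervals are ordered, start at the parameter range
#' minimum, are contiguous (each interval's \code{hi} equals the next
#' interval's \code{lo} -- no gaps, no overlaps) and end open at infinity;
#' every component score lies in 0--3; the oxygen weight is non-negative; and
#' the consciousness map contains all five levels.
#'
#' @param bands A \code{news_bands} object (see [news_bands()]).
#' @return A list with \code{valid} (logical), \code{problems} (data frame
#'   with columns \code{parameter}, \code{message}; zero rows when valid) and
#'   \code{max_total} (the maximum attainable total, \code{NA} if invalid).
#' @examples
#' validate_band_table(news_bands())$valid
#' @export
validate_band_table <- function(bands) {
  stopifnot(inherits(bands, "news_bands"))
  probs <- list()
  note <- function(parameter, message)
    probs[[length(probs) + 1L]] <<- data.frame(parameter = parameter,
                                               message = message)
  levels_needed <- c("alert", "new_confusion", "voice", "pain", "unresponsive")
  missing_lv <- setdiff(levels_needed, names(bands$consciousness))
  if (length(missing_lv))
    note("consciousness", paste0("missing levels: ",
                                 paste(missing_lv, collapse = ", ")))
  if (any(!bands$consciousness %in% 0:3))
    note("consciousness", "component scores must lie in 0..3")
  if (length(bands$oxygen_weight) != 1L || is.na(bands$oxygen_weight) ||
      bands$oxygen_weight < 0L)
    note("on_oxygen", "oxygen weight must be a single non-negative integer")
  for (nm in names(bands$parameters)) {
    b <- bands$parameters[[nm]]
    if (any(!b$score %in% 0:3))
      note(nm, paste0("component score out of range 0..3: ",
                      paste(b$score[!b$score %in% 0:3], collapse = ", ")))
    if (any(b$hi <= b$lo))
      note(nm, "empty or inverted interval (hi <= lo)")
    if (nrow(b) > 1L) {
      gap <- which(abs(b$hi[-nrow(b)] - b$lo[-1L]) > 1e-9)
      for (g in gap) {
        kind <- if (b$hi[g] < b$lo[g + 1L]) "gap" else "overlap"
        note(nm, sprintf("%s between intervals at %g (bands %d and %d)",
                         kind, b$hi[g], g, g + 1L))
      }
    }
    if (!is.infinite(b$hi[nrow(b)]))
      note(nm, "last interval must be open at infinity")
  }
  problems <- if (length(probs)) do.call(rbind, probs) else
    data.frame(parameter = character(), message = character())
  valid <- nrow(problems) == 0L
  list(valid = valid,
       problems = problems,
       max_total = if (valid) max_attainable_score(bands) else NA_integer_)
}

#' Maximum attainable NEWS total for a band table
#'
#' The sum over the six parameters of each parameter's maximal component
#' score, plus the supplemental-oxygen weight. Both shipped charts yield 20,
#' the top of the published ordinal scale.
#'
#' @inheritParams validate_band_table
#' @return Integer maximum total.
#' @examples
#' max_attainable_score(news_bands("news2_scale1"))  # 20
#' @export
max_attainable_score <- function(bands) {
  stopifnot(inherits(bands, "news_bands"))
  rep <- validate_band_table_quick(bands)
  if (!rep) stop("invalid band table; run validate_band_table() for details",
                 call. = FALSE)
  sum(vapply(bands$parameters, function(b) max(b$score), integer(1))) +
    max(bands$consciousness) + bands$oxygen_weight
}

# structural check without recursing through max_attainable_score
validate_band_table_quick <- function(bands) {
  ok_scores <- all(vapply(bands$parameters,
                          function(b) all(b$score %in% 0:3), logical(1))) &&
    all(bands$consciousness %in% 0:3) && bands$oxygen_weight >= 0L
  ok_cover <- all(vapply(bands$parameters, function(b) {
    nrow(b) >= 1L && all(b$hi > b$lo) &&
      (nrow(b) == 1L || all(abs(b$hi[-nrow(b)] - b$lo[-1L]) < 1e-9)) &&
      is.infinite(b$hi[nrow(b)])
  }, logical(1)))
  ok_scores && ok_cover
}
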