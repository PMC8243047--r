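#' Describe the cohort by outcome group
#'
#' One row per variable with per-group summaries and a two-sided comparison
#' p-value: continuous variables as median [IQR] compared by Mann-Whitney U;
#' binary variables as count (percent of the group denominator) compared by
#' Fisher's exact test.
#'
#' @param cohort Data frame of cohort rows.
#' @param group_by Name of a binary (logical or 0/1) grouping column, e.g.
#'   \code{"cc_death"}.
#' @param variables Character vector of columns to summarise; defaults to all
#'   columns other than the grouping flag, \code{patient_id} and timestamps.
#' @return Data frame with columns \code{variable}, \code{type},
#'   \code{summary_all}, \code{summary_group0}, \code{summary_group1},
#'   \code{p_value}, \code{test}, \code{note}.
#' @export
describe_cohort <- function(cohort, group_by, variables = NULL) {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0,
            group_by %in% names(cohort))
  g <- cohort[[group_by]]
  if (is.numeric(g)) {
    if (!all(g %in% c(0, 1), na.rm = TRUE))
      stop("group_by must be a binary (logical or 0/1) column",
           call. = FALSE)
    g <- g == 1
  }
  if (!is.logical(g) || anyNA(g))
    stop("group_by must be a complete binary column", call. = FALSE)
  if (!any(g) || all(g))
    stop("both outcome groups must be non-empty", call. = FALSE)
  if (is.null(variables)) {
    drop <- c(group_by, "patient_id", "trigger_time", "door_time")
    variables <- setdiff(names(cohort), drop)
    variables <- variables[vapply(cohort[variables], function(x)
      is.numeric(x) || is.logical(x), logical(1))]
  }
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    binary <- is.logical(x) || all(x %in% c(0, 1, NA))
    note <- ""
    if (binary) {
      xb <- as.logical(x)
      tab <- table(factor(xb, c(FALSE, TRUE)), factor(g, c(FALSE, TRUE)))
      if (length(unique(xb[!is.na(xb)])) < 2) {
        p <- 1; note <- "constant variable"
      } else p <- stats::fisher.test(tab)$p.value
      summ <- function(sel) {
        n <- sum(xb[sel], na.rm = TRUE); d <- sum(sel & !is.na(xb))
        sprintf("%d (%.1f%%)", n, 100 * n / d)
      }
      data.frame(variable = v, type = "binary",
                 summary_all = summ(rep(TRUE, length(xb))),
                 summary_group0 = summ(!g), summary_group1 = summ(g),
                 p_value = p, test = "fisher_exact", note = note)
    } else {
      if (length(unique(x[!is.na(x)])) < 2) {
        p <- 1; note <- "constant variable"
      } else p <- mann_whitney_p(x[!g & !is.na(x)], x[g & !is.na(x)])
      summ <- function(sel) {
        q <- stats::quantile(x[sel], c(0.5, 0.25, 0.75), na.rm = TRUE)
        sprintf("%.1f [%.1f-%.1f]", q[1], q[2], q[3])
      }
      data.frame(variable = v, type = "continuous",
                 summary_all = summ(rep(TRUE, length(x))),
                 summary_group0 = summ(!g), summary_group1 = summ(g),
                 p_value = p, test = "mann_whitney", note = note)
    }
  })
  do.call(rbind, rows)
}

#' Two-sided Mann-Whitney U p-value
#'
#' For groups of at most 8 observations each the null distribution of U is
#' enumerated exactly over all group assignments (mid-ranks for ties; the
#' two-sided p doubles the smaller tail including the point, capped at 1).
#' For larger groups the tie-corrected normal approximation is used (no
#' continuity correction, matching the large-sample U test).
#'
#' @param x,y Numeric samples for the two groups.
#' @param exact_max Largest per-group size for the exact path (default 8).
#' @return Two-sided p-value.
#' @export
mann_whitney_p <- function(x, y, exact_max = 8L) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 > 0, n2 > 0)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (max(n1, n2) <= exact_max) {
    idx <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    lo <- mean(u_all <= u_obs + eps)
    hi <- mean(u_all >= u_obs - eps)
    min(1, 2 * min(lo, hi))
  } else {
    n <- n1 + n2
    ties <- table(r)
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- (u_obs - mu) / sqrt(sigma2)
    2 * stats::pnorm(-abs(z))
  }
}
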