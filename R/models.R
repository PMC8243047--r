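#' Specify a stepwise regression model
#'
#' Bundles the outcome, the candidate predictors entering the univariable
#' screen, the forced predictors (the Score-to-Door exposure is always kept in
#' the final model regardless of its screen p-value), the two alpha levels and
#' the family.
#'
#' @param outcome Outcome column name. For \code{family = "log_linear"} the
#'   outcome must be strictly positive; it is natural-log transformed before
#'   fitting.
#' @param candidates Character vector of candidate predictor names screened at
#'   \code{screen_alpha}.
#' @param forced Character vector of predictors always retained (default
#'   \code{"std_hours"}).
#' @param family \code{"logistic"} or \code{"log_linear"}.
#' @param screen_alpha Univariable retention threshold (default 0.2).
#' @param final_alpha Significance threshold reported for the final model
#'   (default 0.05).
#' @return An object of class \code{std_model_spec}.
#' @export
model_spec <- function(outcome, candidates, forced = "std_hours",
                       family = c("logistic", "log_linear"),
                       screen_alpha = 0.2, final_alpha = 0.05) {
  family <- match.arg(family)
  stopifnot(screen_alpha > final_alpha)
  structure(list(outcome = outcome, candidates = candidates, forced = forced,
                 family = family, screen_alpha = screen_alpha,
                 final_alpha = final_alpha),
            class = "std_model_spec")
}

fit_family <- function(formula, data, family) {
  if (family == "logistic")
    stats::glm(formula, data = data, family = stats::binomial())
  else
    stats::lm(formula, data = data)
}

prepare_outcome <- function(cohort, spec) {
  y <- cohort[[spec$outcome]]
  if (is.null(y)) stop("outcome '", spec$outcome, "' not found", call. = FALSE)
  if (spec$family == "log_linear") {
    if (any(y <= 0, na.rm = TRUE))
      stop("log-linear outcome '", spec$outcome,
           "' must be strictly positive", call. = FALSE)
    cohort[[".y"]] <- log(y)
  } else {
    cohort[[".y"]] <- as.numeric(as.logical(y))
  }
  cohort
}

#' Univariable screening of candidate predictors
#'
#' Fits one single-predictor model per candidate (same family as the final
#' model) and retains those with p below \code{screen_alpha}. Forced
#' predictors are retained unconditionally. Candidates whose fit does not
#' converge or shows complete separation are dropped with a warning rather
#' than aborting the run.
#'
#' @param cohort Cohort data frame.
#' @param spec A [model_spec()].
#' @return List with \code{retained} (candidate names passing the screen),
#'   \code{table} (per-candidate estimate and p) and \code{dropped}
#'   (candidates excluded for numerical reasons).
#' @export
univariable_screen <- function(cohort, spec) {
  stopifnot(inherits(spec, "std_model_spec"))
  cohort <- prepare_outcome(cohort, spec)
  res <- lapply(spec$candidates, function(v) {
    x <- cohort[[v]]
    if (is.null(x)) stop("candidate '", v, "' not found", call. = FALSE)
    if (length(unique(x[!is.na(x)])) < 2)
      return(data.frame(term = v, estimate = NA_real_, p_value = NA_real_,
                        status = "constant"))
    fit <- tryCatch(
      withCallingHandlers(
        fit_family(stats::reformulate(v, ".y"), cohort, spec$family),
        warning = function(w) {
          if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                    conditionMessage(w)))
            invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    bad <- is.null(fit) ||
      (spec$family == "logistic" &&
         (!fit$converged ||
            any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE) ||
            any(fit$fitted.values > 1 - 1e-10) ||
            any(fit$fitted.values < 1e-10)))
    if (bad) {
      warning("candidate '", v,
              "' dropped from screen (separation or non-convergence)",
              call. = FALSE)
      return(data.frame(term = v, estimate = NA_real_, p_value = NA_real_,
                        status = "separation"))
    }
    sm <- stats::coef(summary(fit))
    data.frame(term = v, estimate = sm[2, 1], p_value = sm[2, 4],
               status = "ok")
  })
  tab <- do.call(rbind, res)
  retained <- tab$term[tab$status == "ok" & tab$p_value < spec$screen_alpha]
  list(retained = retained, table = tab,
       dropped = tab$term[tab$status != "ok"])
}

#' Fit the multivariable model with BCa bootstrap confidence intervals
#'
#' Fits the final model (forced predictors plus the screen-retained
#' candidates) by maximum likelihood (logistic) or least squares on the
#' log-transformed outcome (log-linear), then computes per-term 95 percent
#' bias-corrected accelerated (BCa) bootstrap confidence intervals from
#' \code{B} case resamples of patient rows. With \code{B = 0} analytic Wald
#' intervals are reported instead and labelled as such.
#'
#' @param cohort Cohort data frame.
#' @param spec A [model_spec()].
#' @param retained Character vector of screen-retained predictors (e.g. from
#'   [univariable_screen()]); forced predictors are added automatically.
#' @param B Bootstrap replicates (default 2000).
#' @param seed Integer seed for the resampling (required when \code{B > 0}).
#' @return An object of class \code{std_fit}: data frame \code{terms} with
#'   columns \code{term}, \code{estimate}, \code{effect} (odds ratio
#'   \eqn{e^\beta} for logistic, percent change \eqn{100(e^\beta-1)} for
#'   log-linear), \code{ci_lower}, \code{ci_upper} (on the effect scale),
#'   \code{p_value}, \code{significant}; plus metadata (\code{n},
#'   \code{family}, \code{converged}, \code{ci_method}, \code{B},
#'   \code{seed}).
#' @export
fit_multivariable <- function(cohort, spec, retained = character(),
                              B = 2000L, seed = NULL) {
  stopifnot(inherits(spec, "std_model_spec"))
  predictors <- unique(c(spec$forced, retained))
  cohort <- prepare_outcome(cohort, spec)
  data <- cohort[, c(".y", predictors), drop = FALSE]
  data <- data[stats::complete.cases(data), , drop = FALSE]
  for (v in predictors)
    if (is.logical(data[[v]])) data[[v]] <- as.numeric(data[[v]])
  form <- stats::reformulate(predictors, ".y")
  # near-boundary fitted probabilities are common at large n with continuous
  # covariates; true separation is caught below via convergence and rank
  fit <- withCallingHandlers(
    fit_family(form, data, spec$family),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (spec$family == "logistic" && !fit$converged)
    stop("multivariable logistic model failed to converge", call. = FALSE)
  qr_rank <- fit$qr$rank
  if (qr_rank < length(predictors) + 1L)
    stop("collinear predictors: design matrix is rank deficient",
         call. = FALSE)
  sm <- stats::coef(summary(fit))
  beta <- sm[, 1]
  pvals <- sm[, 4]
  k <- length(beta)

  transform <- function(b) if (spec$family == "logistic") exp(b)
                           else percent_effect(b)
  ci <- matrix(NA_real_, k, 2)
  if (B > 0L) {
    if (is.null(seed)) stop("seed is required for the bootstrap",
                            call. = FALSE)
    set.seed(seed)
    # case resampling on the design matrix directly: identical estimator to
    # the formula interface, without re-parsing the model frame per replicate
    X <- stats::model.matrix(form, data)
    yv <- data$.y
    nr <- nrow(X)
    tboot <- matrix(NA_real_, B, k)
    for (r in seq_len(B)) {
      idx <- sample.int(nr, nr, replace = TRUE)
      co <- tryCatch(suppressWarnings(
        if (spec$family == "logistic")
          stats::glm.fit(X[idx, , drop = FALSE], yv[idx],
                         family = stats::binomial())$coefficients
        else
          stats::lm.fit(X[idx, , drop = FALSE], yv[idx])$coefficients),
        error = function(e) rep(NA_real_, k))
      if (length(co) == k && !anyNA(co)) tboot[r, ] <- co
    }
    # acceleration from case-deletion influence (jackknife approximation)
    infl <- stats::dfbeta(fit)
    for (j in seq_len(k))
      ci[j, ] <- bca_interval(tboot[, j], beta[j], infl[, j])
    ci_method <- "bca_bootstrap"
  } else {
    se <- sm[, 2]
    ci <- cbind(beta - stats::qnorm(0.975) * se,
                beta + stats::qnorm(0.975) * se)
    ci_method <- "wald"
  }

  terms <- data.frame(
    term = sub("^\\(Intercept\\)$", "constant", rownames(sm)),
    estimate = beta,
    effect = transform(beta),
    ci_lower = transform(ci[, 1]),
    ci_upper = transform(ci[, 2]),
    p_value = pvals,
    significant = pvals < spec$final_alpha,
    row.names = NULL)
  structure(list(terms = terms, outcome = spec$outcome, family = spec$family,
                 n = nrow(data), converged = TRUE, ci_method = ci_method,
                 B = if (B > 0L) B else 0L, seed = seed,
                 effect_label = if (spec$family == "logistic") "odds_ratio"
                                else "percent_change"),
            class = "std_fit")
}

#' @export
print.std_fit <- function(x, digits = 3, ...) {
  cat(sprintf("%s model for '%s' (n = %d, CI: %s%s)\n",
              x$family, x$outcome, x$n, x$ci_method,
              if (x$B > 0) sprintf(", B = %d", x$B) else ""))
  tab <- x$terms
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = digits)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' Bias-corrected accelerated bootstrap interval
#'
#' Computes the BCa interval for one statistic from its bootstrap replicates.
#' The bias-correction constant comes from the proportion of replicates below
#' the point estimate; the acceleration constant from the skewness of the
#' supplied empirical influence values (jackknife approximation -- for
#' regression coefficients the case-deletion influence from
#' \code{\link[stats]{dfbeta}}, for a mean the centred observations).
#' Adjusted percentiles are read off the replicate distribution with
#' normal-quantile interpolation.
#'
#' @param t Bootstrap replicates of the statistic (non-finite entries are
#'   dropped).
#' @param t0 Point estimate on the full sample.
#' @param influence Per-observation empirical influence values (any scaling;
#'   only their standardised skewness enters).
#' @param conf Confidence level (default 0.95).
#' @return Length-2 numeric vector (lower, upper); \code{NA} when fewer than
#'   20 usable replicates remain.
#' @export
bca_interval <- function(t, t0, influence, conf = 0.95) {
  t <- t[is.finite(t)]
  B <- length(t)
  if (B < 20L) return(c(NA_real_, NA_real_))
  prop <- (sum(t < t0) + 0.5 * sum(t == t0)) / B
  prop <- min(max(prop, 1 / (B + 1)), B / (B + 1))
  z0 <- stats::qnorm(prop)
  u <- influence - mean(influence)
  denom <- sum(u^2)^1.5
  a <- if (denom > 0) sum(u^3) / (6 * denom) else 0
  zal <- stats::qnorm(c((1 - conf) / 2, 1 - (1 - conf) / 2))
  adj <- stats::pnorm(z0 + (z0 + zal) / (1 - a * (z0 + zal)))
  st <- sort(t)
  vapply(adj, function(p) {
    kk <- (B + 1) * p
    k1 <- floor(kk)
    if (k1 < 1) return(st[1])
    if (k1 >= B) return(st[B])
    # interpolate on the normal-quantile scale between order statistics
    w <- (stats::qnorm(p) - stats::qnorm(k1 / (B + 1))) /
      (stats::qnorm((k1 + 1) / (B + 1)) - stats::qnorm(k1 / (B + 1)))
    st[k1] + w * (st[k1 + 1] - st[k1])
  }, numeric(1))
}

#' Percent change per unit from a log-scale coefficient
#'
#' For a model fitted on a natural-log-transformed outcome, a coefficient
#' \eqn{\beta} corresponds to a multiplicative effect \eqn{e^\beta} per unit
#' of the predictor, i.e. a \eqn{100(e^\beta - 1)} percent change. The
#' small-coefficient shorthand \eqn{100\beta} is also available via
#' \code{method = "abs"}; the two agree to first order but diverge for
#' \eqn{|\beta|} beyond a few hundredths.
#'
#' @param beta Coefficient(s) on the natural-log scale.
#' @param method \code{"exp"} (default, exact) or \code{"abs"}
#'   (\eqn{100\beta}).
#' @return Percent change per unit.
#' @examples
#' percent_effect(0.012)   # +1.21 percent per hour
#' percent_effect(-0.079)  # -7.60 percent per point
#' @export
percent_effect <- function(beta, method = c("exp", "abs")) {
  method <- match.arg(method)
  stopifnot(all(is.finite(beta)))
  if (method == "exp") 100 * (exp(beta) - 1) else 100 * beta
}

#' Median imputation of missing covariates
#'
#' Replaces every missing value by the median of the non-missing values of
#' its column (for logical columns, the majority value). Used by the
#' sensitivity analysis contrasting complete-case and imputed fits.
#'
#' @param data Data frame.
#' @param variables Columns to impute; defaults to all numeric/logical
#'   columns.
#' @return The data frame with missing cells filled in.
#' @export
impute_median <- function(data, variables = NULL) {
  if (is.null(variables))
    variables <- names(data)[vapply(data, function(x)
      is.numeric(x) || is.logical(x), logical(1))]
  for (v in variables) {
    x <- data[[v]]
    if (!anyNA(x)) next
    if (all(is.na(x)))
      stop("variable '", v, "' has no observed values to impute from",
           call. = FALSE)
    med <- stats::median(x[!is.na(x)])
    if (is.logical(x)) med <- as.logical(round(as.numeric(med)))
    x[is.na(x)] <- med
    data[[v]] <- x
  }
  data
}

#' Two-hourly block summary of an outcome along the exposure axis
#'
#' Assigns each patient to a half-open exposure block
#' \code{[0,2), [2,4), ...} hours, clipping exposures at \code{max_hours}
#' into the final block, and returns the per-block mean of the chosen
#' variable with a normal-approximation 95 percent confidence interval.
#' Blocks with a single patient are reported without an interval.
#'
#' @param cohort Cohort data frame with \code{std_hours}.
#' @param variable Column to average (e.g. \code{"cc_death"} or
#'   \code{"sofa_day1"}).
#' @param block_hours Block width in hours (default 2).
#' @param max_hours Clipping bound (default 48); exposures at or beyond it
#'   fall in the final block.
#' @return Data frame with \code{block_start}, \code{block_end}, \code{n},
#'   \code{mean}, \code{ci_lower}, \code{ci_upper}.
#' @export
block_summary <- function(cohort, variable, block_hours = 2,
                          max_hours = 48) {
  stopifnot(nrow(cohort) > 0, variable %in% names(cohort))
  h <- pmin(cohort$std_hours, max_hours - 1e-9)
  blk <- floor(h / block_hours)
  y <- as.numeric(cohort[[variable]])
  out <- lapply(sort(unique(blk)), function(b) {
    yi <- y[blk == b]
    n <- length(yi)
    m <- mean(yi)
    if (n > 1) {
      se <- stats::sd(yi) / sqrt(n)
      lo <- m - stats::qnorm(0.975) * se
      hi <- m + stats::qnorm(0.975) * se
    } else lo <- hi <- NA_real_
    data.frame(block_start = b * block_hours,
               block_end = (b + 1) * block_hours,
               n = n, mean = m, ci_lower = lo, ci_upper = hi)
  })
  do.call(rbind, out)
}
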