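#' Default predictor sets for the fitted models
#'
#' \code{default_mortality_candidates} are the candidate variables entering
#' the univariable screen of both mortality models (demographics,
#' comorbidity, frailty, admission characteristics, sickness severity,
#' ventilation, and the timing covariates). The log-linear models are not
#' screened: \code{default_cc_los_predictors} accompany the forced exposure
#' in the length-of-stay model, and \code{default_std_predictors} form the
#' exposure-determinants model. All are plain character vectors of cohort
#' column names and can be overridden per call or via the run config.
#'
#' @format Character vectors of cohort column names.
#' @name default_predictors
NULL

#' @rdname default_predictors
#' @export
default_mortality_candidates <- c(
  "age", "male", "charlson", "frailty", "sofa_day1", "niv_or_imv", "sepsis",
  "elective_admission", "trigger_news", "time_to_trigger_days",
  "out_of_hours", "peri_arrest_call")

#' @rdname default_predictors
#' @export
default_cc_los_predictors <- c("age", "frailty", "charlson", "sofa_day1",
                               "sepsis", "niv_or_imv")

#' @rdname default_predictors
#' @export
default_std_predictors <- c("age", "frailty", "charlson", "trigger_news",
                            "time_to_trigger_days", "out_of_hours",
                            "peri_arrest_call")

#' Run the full statistical analysis on a derived cohort
#'
#' Reproduces the analysis pipeline end to end: descriptive comparison by
#' critical-care survival; stepwise logistic models (univariable screen at
#' p < 0.2, multivariable with the Score-to-Door exposure forced in) for
#' critical-care and hospital mortality; log-linear models for critical-care
#' length of stay (survivors only, exposure forced) and for the determinants
#' of Score-to-Door time; two-hourly block summaries of mortality and day-1
#' SOFA; histogram and per-trigger-NEWS box statistics for plotting; and,
#' when incomplete rows are supplied, the median-imputation sensitivity
#' refit comparing significance flags.
#'
#' @param cohort Complete-case cohort data frame from [derive_cohort()].
#' @param B Bootstrap replicates for BCa intervals (default 2000; 0 gives
#'   Wald intervals).
#' @param seed Integer seed for the bootstrap resampling.
#' @param cohort_imputable Optional data frame including the
#'   missing-data-excluded rows (\code{cohort_imputable} from
#'   [derive_cohort()]); triggers the sensitivity analysis.
#' @param mortality_candidates,cc_los_predictors,std_predictors Predictor
#'   lists; defaults mirror the starred descriptive-table variables and the
#'   published model structures.
#' @return List of class \code{std_analysis} with elements
#'   \code{descriptives}, \code{screens}, \code{models} (named list of
#'   [fit_multivariable()] results), \code{blocks}, \code{std_histogram},
#'   \code{std_by_trigger_news}, \code{sensitivity} (or \code{NULL}).
#' @export
analyse_cohort <- function(cohort, B = 2000L, seed = 1L,
                           cohort_imputable = NULL,
                           mortality_candidates = default_mortality_candidates,
                           cc_los_predictors = default_cc_los_predictors,
                           std_predictors = default_std_predictors) {
  if (nrow(cohort) < 50L)
    stop("cohort too small to fit the multivariable models (n = ",
         nrow(cohort), ")", call. = FALSE)
  descriptives <- describe_cohort(cohort, "cc_death")

  specs <- list(
    cc_mortality = model_spec("cc_death", mortality_candidates,
                              forced = "std_hours", family = "logistic"),
    hospital_mortality = model_spec("hospital_death", mortality_candidates,
                                    forced = "std_hours",
                                    family = "logistic"),
    # log-linear models: predictors chosen for plausibility, no screen
    cc_los = model_spec("cc_los_days", character(),
                        forced = c("std_hours", cc_los_predictors),
                        family = "log_linear"),
    std_determinants = model_spec("std_hours", character(),
                                  forced = std_predictors,
                                  family = "log_linear"))

  screens <- list()
  models <- list()
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    data <- if (nm == "cc_los") cohort[!cohort$cc_death, , drop = FALSE]
            else cohort
    retained <- character()
    if (length(spec$candidates)) {
      sc <- univariable_screen(data, spec)
      screens[[nm]] <- sc$table
      retained <- sc$retained
    }
    models[[nm]] <- fit_multivariable(data, spec, retained, B = B,
                                      seed = seed + match(nm, names(specs)))
  }

  blocks <- list(cc_mortality = block_summary(cohort, "cc_death"),
                 sofa_day1 = block_summary(cohort, "sofa_day1"))
  std_histogram <- std_histogram_bins(cohort$std_hours)
  std_by_trigger_news <- box_stats_by(cohort, "std_hours", "trigger_news")

  sensitivity <- NULL
  if (!is.null(cohort_imputable) &&
      any(!cohort_imputable$complete_case)) {
    imputed <- impute_median(cohort_imputable)
    sens_models <- list()
    for (nm in names(specs)) {
      spec <- specs[[nm]]
      data <- if (nm == "cc_los") imputed[!imputed$cc_death, , drop = FALSE]
              else imputed
      retained <- if (length(spec$candidates))
        univariable_screen(data, spec)$retained else character()
      sens_models[[nm]] <- fit_multivariable(data, spec, retained, B = B,
                                             seed = seed + 100L +
                                               match(nm, names(specs)))
    }
    sensitivity <- list(
      models = sens_models,
      comparison = do.call(rbind, lapply(names(models), function(nm) {
        a <- models[[nm]]$terms; b <- sens_models[[nm]]$terms
        shared <- intersect(a$term, b$term)
        data.frame(model = nm, term = shared,
                   significant_complete_case =
                     a$significant[match(shared, a$term)],
                   significant_imputed =
                     b$significant[match(shared, b$term)])
      })))
  }
  structure(list(descriptives = descriptives, screens = screens,
                 models = models, blocks = blocks,
                 std_histogram = std_histogram,
                 std_by_trigger_news = std_by_trigger_news,
                 sensitivity = sensitivity, n = nrow(cohort),
                 B = B, seed = seed),
            class = "std_analysis")
}

# log-spaced histogram bins for the right-skewed exposure distribution
std_histogram_bins <- function(std_hours, n_bins = 20L) {
  breaks <- exp(seq(log(max(min(std_hours) * 0.999, 1e-3)),
                    log(max(std_hours) * 1.001), length.out = n_bins + 1L))
  h <- hist(std_hours, breaks = breaks, plot = FALSE)
  data.frame(bin_lower = h$breaks[-length(h$breaks)],
             bin_upper = h$breaks[-1], count = h$counts)
}

box_stats_by <- function(data, value, group) {
  g <- data[[group]]
  out <- lapply(sort(unique(g)), function(gv) {
    x <- data[[value]][g == gv]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75))
    iqr <- q[3] - q[1]
    data.frame(group = gv, n = length(x), q1 = q[1], median = q[2],
               q3 = q[3],
               whisker_low = min(x[x >= q[1] - 1.5 * iqr]),
               whisker_high = max(x[x <= q[3] + 1.5 * iqr]))
  })
  out <- do.call(rbind, out)
  names(out)[1] <- group
  out
}

#' @export
print.std_analysis <- function(x, ...) {
  cat("Score-to-Door analysis (n = ", x$n, ", B = ", x$B, ")\n", sep = "")
  for (nm in names(x$models)) {
    cat("\n== ", nm, " ==\n", sep = "")
    print(x$models[[nm]])
  }
  invisible(x)
}

## ---- config-driven entry points -------------------------------------------

#' Read a run configuration
#'
#' A single YAML file drives the pipeline: input CSV paths, optional column
#' mappings, band-table version, thresholds, model variable lists, bootstrap
#' settings and the output directory. Missing fields fall back to the
#' defaults shown in the shipped demo config
#' (\code{system.file("extdata", "demo_config.yaml", package = "scoretodoor")}).
#'
#' @param path Path to the YAML config.
#' @return Named list of settings with defaults filled in.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    seed = 1L, band_version = "news2_scale1",
    thresholds = list(high = 7L, floor = 5L, cap_hours = 168),
    bootstrap_B = 2000L,
    simulate = list(n_patients = 1000L),
    paths = list(output_dir = "std_output"),
    columns = list(),
    mortality_candidates = default_mortality_candidates,
    cc_los_predictors = default_cc_los_predictors,
    std_predictors = default_std_predictors)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (nm in names(defaults$thresholds))
    if (is.null(cfg$thresholds[[nm]]))
      cfg$thresholds[[nm]] <- defaults$thresholds[[nm]]
  if (cfg$thresholds$high <= cfg$thresholds$floor)
    stop("config thresholds must satisfy high > floor", call. = FALSE)
  cfg
}

apply_column_mapping <- function(df, mapping) {
  if (is.null(mapping) || !length(mapping)) return(df)
  for (canonical in names(mapping)) {
    supplied <- mapping[[canonical]]
    if (!supplied %in% names(df))
      stop("mapped column '", supplied, "' not found in input", call. = FALSE)
    names(df)[names(df) == supplied] <- canonical
  }
  df
}

parse_time <- function(x) {
  as.POSIXct(x, tz = "UTC", tryFormats = c("%Y-%m-%d %H:%M:%OS",
                                           "%Y-%m-%dT%H:%M:%OS",
                                           "%Y-%m-%d %H:%M", "%Y-%m-%d"))
}

#' Read the three study input tables
#'
#' @param cfg Config list from [read_config()] with \code{paths$observations},
#'   \code{paths$events}, \code{paths$covariates} and optional per-table
#'   \code{columns} mappings (canonical name -> supplied name).
#' @return List with parsed \code{observations}, \code{events},
#'   \code{covariates}.
#' @export
read_study <- function(cfg) {
  rd <- function(p) utils::read.csv(p, stringsAsFactors = FALSE)
  obs <- apply_column_mapping(rd(cfg$paths$observations),
                              cfg$columns$observations)
  ev <- apply_column_mapping(rd(cfg$paths$events), cfg$columns$events)
  cov <- apply_column_mapping(rd(cfg$paths$covariates),
                              cfg$columns$covariates)
  need_obs <- c("patient_id", "timestamp", "respiratory_rate", "spo2",
                "on_oxygen", "systolic_bp", "heart_rate", "consciousness",
                "temperature")
  miss <- setdiff(need_obs, names(obs))
  if (length(miss))
    stop("observations file lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  obs$timestamp <- parse_time(obs$timestamp)
  obs$on_oxygen <- as.logical(obs$on_oxygen)
  ev$start <- parse_time(ev$start)
  ev$end <- parse_time(ev$end)
  ev$first_heart_rate_time <- parse_time(ev$first_heart_rate_time)
  for (v in intersect(c("male", "niv_or_imv", "sepsis", "elective_admission",
                        "peri_arrest_call", "cc_death", "hospital_death"),
                      names(cov)))
    cov[[v]] <- as.logical(cov[[v]])
  list(observations = obs, events = ev, covariates = cov)
}

write_csv <- function(df, dir, name) {
  utils::write.csv(df, file.path(dir, name), row.names = FALSE)
}

#' Simulate a synthetic study to disk
#'
#' Writes the observation, event and covariate CSVs (plus the generating
#' truth) a derivation run consumes.
#'
#' @param config Path to a YAML config, or a config list; the \code{simulate}
#'   block holds [generator_config()] overrides, \code{seed} the master seed.
#' @param output_dir Destination directory (default from the config).
#' @return Invisibly, the list of written file paths.
#' @export
run_simulate <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) read_config(config) else config
  dir <- output_dir %||% cfg$paths$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen_args <- cfg$simulate
  gen_args$seed <- gen_args$seed %||% cfg$seed
  gen <- do.call(generator_config, gen_args)
  study <- simulate_study(gen)
  fmt <- function(df) {
    for (v in names(df))
      if (inherits(df[[v]], "POSIXct"))
        df[[v]] <- format(df[[v]], "%Y-%m-%d %H:%M:%S", tz = "UTC")
    df
  }
  write_csv(fmt(study$observations), dir, "observations.csv")
  write_csv(fmt(study$events), dir, "events.csv")
  write_csv(fmt(study$covariates), dir, "covariates.csv")
  write_csv(fmt(study$truth), dir, "truth.csv")
  message("simulated ", gen$n_patients, " patients into ", dir)
  invisible(file.path(dir, c("observations.csv", "events.csv",
                             "covariates.csv", "truth.csv")))
}

#' Derive the cohort from CSV inputs
#'
#' Scores the observations, applies the inclusion/exclusion algorithm and
#' writes \code{cohort.csv} plus the exclusion ledger (CSV and log lines).
#'
#' @param config Path to a YAML config, or a config list.
#' @return The [derive_cohort()] result, invisibly.
#' @export
run_derive <- function(config) {
  cfg <- if (is.character(config)) read_config(config) else config
  study <- read_study(cfg)
  bands <- news_bands(cfg$band_version)
  res <- derive_cohort(study$observations, study$events, study$covariates,
                       bands = bands,
                       high_threshold = cfg$thresholds$high,
                       floor = cfg$thresholds$floor,
                       cap_hours = cfg$thresholds$cap_hours)
  dir <- cfg$paths$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_csv(res$cohort, dir, "cohort.csv")
  write_csv(res$cohort_imputable, dir, "cohort_imputable.csv")
  write_csv(res$ledger, dir, "exclusion_ledger.csv")
  for (i in seq_len(nrow(res$ledger)))
    message(sprintf("%-24s %6d", res$ledger$step[i], res$ledger$n[i]))
  invisible(res)
}

#' Analyse a derived cohort from CSV inputs
#'
#' Runs [analyse_cohort()] on \code{cohort.csv} (and
#' \code{cohort_imputable.csv} for the sensitivity analysis) in the output
#' directory and writes the descriptive table, the four model tables, the
#' block summaries and the plotting data as tidy CSVs, plus a run log
#' recording seed, B and the model sample sizes.
#'
#' @param config Path to a YAML config, or a config list.
#' @return The [analyse_cohort()] result, invisibly.
#' @export
run_analyse <- function(config) {
  cfg <- if (is.character(config)) read_config(config) else config
  dir <- cfg$paths$output_dir
  cohort <- utils::read.csv(file.path(dir, "cohort.csv"))
  imp_path <- file.path(dir, "cohort_imputable.csv")
  cohort_imputable <- if (file.exists(imp_path)) utils::read.csv(imp_path)
                      else NULL
  res <- analyse_cohort(cohort, B = cfg$bootstrap_B, seed = cfg$seed,
                        cohort_imputable = cohort_imputable,
                        mortality_candidates = cfg$mortality_candidates,
                        cc_los_predictors = cfg$cc_los_predictors,
                        std_predictors = cfg$std_predictors)
  write_csv(res$descriptives, dir, "descriptives.csv")
  for (nm in names(res$models))
    write_csv(res$models[[nm]]$terms, dir, paste0("model_", nm, ".csv"))
  write_csv(res$blocks$cc_mortality, dir, "blocks_cc_mortality.csv")
  write_csv(res$blocks$sofa_day1, dir, "blocks_sofa_day1.csv")
  write_csv(res$std_histogram, dir, "std_histogram.csv")
  write_csv(res$std_by_trigger_news, dir, "std_by_trigger_news.csv")
  if (!is.null(res$sensitivity))
    write_csv(res$sensitivity$comparison, dir, "sensitivity_comparison.csv")
  log_lines <- c(
    sprintf("seed: %d", cfg$seed),
    sprintf("bootstrap_B: %d", cfg$bootstrap_B),
    sprintf("cohort_n: %d", res$n),
    vapply(names(res$models), function(nm)
      sprintf("model %s: n = %d, ci = %s", nm, res$models[[nm]]$n,
              res$models[[nm]]$ci_method), character(1)))
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  message(paste(log_lines, collapse = "\n"))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
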