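#' Write a fluorescence trace to a tab-delimited file
#'
#' Columns are `time_s`, the channel columns (`f_main`, or `f_sapphire`
#' and `f_sirius`), `setpoint_c` and `event` (empty except at samples
#' carrying an event label). Metadata are written as a commented header
#' line `# metadata: {json}`. Numbers are written with 17 significant
#' digits so a write/load round trip preserves the trace to full double
#' precision.
#'
#' @param trace A [fluorescence_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (!inherits(trace, "fluorescence_trace")) {
    abort_validation("trace must be a fluorescence_trace")
  }
  ev_col <- rep("", length(trace$times))
  if (nrow(trace$events)) {
    for (i in seq_len(nrow(trace$events))) {
      j <- which.min(abs(trace$times - trace$events$time[i]))
      ev_col[j] <- trace$events$label[i]
    }
  }
  num <- function(x) sprintf("%.17g", x)
  tab <- data.frame(time_s = num(trace$times))
  for (ch in colnames(trace$channels)) tab[[ch]] <- num(trace$channels[, ch])
  tab$setpoint_c <- num(trace$setpoint)
  tab$event <- ev_col

  con <- file(path, "w")
  on.exit(close(con))
  meta <- trace$metadata
  meta <- meta[!vapply(meta, is.null, logical(1))]
  writeLines(paste0("# metadata: ",
                    jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                                     null = "null", na = "null")), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a fluorescence trace from a tab-delimited file
#'
#' Reads the format written by [write_trace()]: a `# metadata: {json}`
#' header line, then a tab-delimited table with columns `time_s`,
#' `f_main` (or `f_sapphire` + `f_sirius`), `setpoint_c` and optionally
#' `event`. Validates the schema (naming any missing column), monotone
#' time and non-negative intensities.
#'
#' @param path File path.
#' @return A [fluorescence_trace()].
#' @export
load_trace_table <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  lines <- readLines(path, n = 50L)
  meta <- list()
  meta_line <- grep("^#\\s*metadata:", lines, value = TRUE)
  if (length(meta_line)) {
    meta <- jsonlite::fromJSON(sub("^#\\s*metadata:\\s*", "", meta_line[1L]),
                               simplifyVector = TRUE)
  }
  tab <- utils::read.delim(path, comment.char = "#", sep = "\t",
                           stringsAsFactors = FALSE)
  if (!"time_s" %in% names(tab)) abort_validation("missing required column: time_s")
  if (!"setpoint_c" %in% names(tab)) abort_validation("missing required column: setpoint_c")
  has_main <- "f_main" %in% names(tab)
  has_pair <- all(c("f_sapphire", "f_sirius") %in% names(tab))
  if (!has_main && !has_pair) {
    abort_validation("missing required column: f_main (or f_sapphire and f_sirius)")
  }
  if (any(diff(tab$time_s) <= 0)) abort_validation("time_s is not strictly increasing")
  channels <- if (has_main) {
    matrix(tab$f_main, ncol = 1, dimnames = list(NULL, "f_main"))
  } else {
    cbind(f_sapphire = tab$f_sapphire, f_sirius = tab$f_sirius)
  }
  events <- data.frame(time = numeric(0), label = character(0))
  if ("event" %in% names(tab)) {
    hit <- !is.na(tab$event) & tab$event != ""
    if (any(hit)) events <- data.frame(time = tab$time_s[hit], label = tab$event[hit])
  }
  fluorescence_trace(tab$time_s, channels, tab$setpoint_c,
                     events = events, metadata = as.list(meta))
}

#' Load and validate a pipeline run configuration
#'
#' Reads a YAML configuration (or accepts a named list) and validates the
#' invariants shared by all commands: a `seed` must be present for
#' reproducibility, and any entries whose names end in `_tol` must be
#' positive.
#'
#' @param config Path to a YAML file, or a named list.
#' @return The validated configuration list.
#' @export
load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort_validation(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort_validation("config must be a list or a YAML file path")
  if (is.null(config[["seed"]])) abort_validation("config must contain a seed")
  tol <- config[grepl("_tol$", names(config))]
  if (length(tol) && any(unlist(tol) <= 0)) {
    abort_validation("all tolerances must be > 0")
  }
  config
}

write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", null = "null")
  invisible(path)
}

#' Run a pipeline command
#'
#' Orchestrates the module functions into the reproducible commands a
#' complete analysis uses. Every report embeds the seed and the resolved
#' configuration, so re-running the same command with the same config
#' yields byte-identical output.
#'
#' Commands:
#' * `simulate` — render a trace from the configured `scenario`, `params`,
#'   `probe_type` (`"mty"`/`"gtemp"`) and `noise_sd`, and write it to
#'   `trace_out`.
#' * `analyze-mty` — estimate the temperature shift on the `trace` file
#'   (internal calibration from its own staircase).
#' * `analyze-gtemp` — ratio, inversion via the configured `calibration`
#'   (`c0`/`c1`/`range`) and interval summaries (`intervals`, minutes).
#' * `calibrate-gtemp` — fit the ratio calibration on a staircase trace.
#' * `fractions` — recovery proportions from the `table` file.
#' * `stats` — group comparison on the tidy `table` file
#'   (columns `replicate`, `group`, `value`).
#'
#' @param command One of the command strings above.
#' @param config A named list or YAML path; see [load_run_config()].
#' @param out Optional path for the JSON report.
#' @return The report, invisibly (also written to `out` when given).
#' @export
run_pipeline <- function(command, config, out = NULL) {
  commands <- c("simulate", "analyze-mty", "analyze-gtemp",
                "calibrate-gtemp", "fractions", "stats")
  if (!is.character(command) || length(command) != 1L || !(command %in% commands)) {
    abort_validation(sprintf("invalid command; must be one of: %s",
                             paste(commands, collapse = ", ")))
  }
  config <- load_run_config(config)
  report <- list(command = command, seed = config[["seed"]], config = config)

  if (command == "simulate") {
    probe_type <- config[["probe_type"]] %||% "mty"
    sc <- build_scenario(config[["scenario"]] %||% "inhibitor", config[["params"]] %||% list())
    trace <- if (probe_type == "mty") {
      probe <- do.call(mty_probe, config[["probe"]] %||% list())
      render_mty_trace(sc, probe, noise_sd = config[["noise_sd"]] %||% 0,
                       seed = config[["seed"]])
    } else {
      probe <- do.call(gtemp_probe, config[["probe"]] %||% list())
      render_gtemp_trace(sc, probe, noise_sd = config[["noise_sd"]] %||% 0,
                         seed = config[["seed"]])
    }
    if (!is.null(config[["trace_out"]])) write_trace(trace, config[["trace_out"]])
    report$trace_out <- config[["trace_out"]]
    report$n_samples <- length(trace$times)
    report$truth_drop <- sc$truth_drop

  } else if (command == "analyze-mty") {
    trace <- load_trace_table(config[["trace"]])
    if (n_channels(trace) != 1L) abort_validation("analyze-mty needs a single-channel trace")
    withCallingHandlers({
      est <- estimate_temperature_shift(trace)
    }, warning = function(w) {
      report$qc_warnings <<- c(report$qc_warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    report$delta_t <- est$delta_t
    report$magnitude <- est$magnitude
    report$stable <- est$stable
    report$fit <- est$fit[c("slope", "intercept", "r_squared", "n_points", "suspicious")]
    report$windows <- est$windows

  } else if (command == "analyze-gtemp") {
    trace <- load_trace_table(config[["trace"]])
    if (n_channels(trace) != 2L) {
      abort_validation("analyze-gtemp needs a two-channel trace (f_sapphire, f_sirius)")
    }
    cal <- config[["calibration"]]
    if (is.null(cal)) abort_validation("analyze-gtemp needs a calibration (c0, c1) in the config")
    calibration <- ratio_calibration(cal$c0, cal$c1,
                                     calibrated_range = cal$range %||% c(30, 42))
    temps <- infer_temperature_trace(compute_ratio(trace), calibration)
    report$calibration <- calibration[c("c0", "c1", "calibrated_range")]
    report$frac_extrapolated <- mean(temps$extrapolated)
    if (!is.null(config[["intervals"]])) {
      report$intervals <- summarize_interval(temps, config[["intervals"]])
    }

  } else if (command == "calibrate-gtemp") {
    trace <- load_trace_table(config[["trace"]])
    calibration <- fit_ratio_calibration(trace)
    report$calibration <- calibration[c("c0", "c1", "calibrated_range", "r_squared")]

  } else if (command == "fractions") {
    expt <- read_fractionation_table(config[["table"]])
    rec <- recovery_proportions(expt)
    report$recovery <- rec
    report$per_trial <- attr(rec, "per_trial")

  } else if (command == "stats") {
    tab <- utils::read.delim(config[["table"]], comment.char = "#", sep = "",
                             stringsAsFactors = FALSE)
    need <- c("group", "value")
    missing_cols <- setdiff(need, names(tab))
    if (length(missing_cols)) {
      abort_validation(sprintf("missing required column(s): %s",
                               paste(missing_cols, collapse = ", ")))
    }
    groups <- split(tab$value, tab$group)
    cmp <- compare_groups(groups, alpha = config[["alpha"]] %||% 0.05)
    report$summary <- cmp$summary
    report$anova <- cmp$anova
    report$tukey_pairs <- cmp$tukey_pairs
    report$ttest <- cmp$ttest
  }

  if (!is.null(out)) write_report(report, out)
  invisible(report)
}
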