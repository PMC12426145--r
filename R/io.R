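trial_csv_columns <- c("participant", "site", "experiment", "list_type",
                       "list_id", "repetition", "trial_index", "input_list",
                       "output_position", "response", "rt_ms")

#' Read trial-level recall data from CSV
#'
#' The dialect is long format, one row per response: `participant`, `site`,
#' `experiment`, `list_type` (same/spun/scrambled), `list_id`, `repetition`,
#' `trial_index`, `input_list` (six unique characters in presentation
#' order), `output_position` (1..6, unique and increasing within a trial),
#' `response` (single character; empty for an omission), `rt_ms` (positive;
#' empty for an omission). Trailing unattempted positions may be absent.
#' Malformed rows are reported with their line numbers; duplicated
#' response keys and unknown list types are hard errors.
#'
#' @param path CSV file path.
#' @return A validated tibble of trials (empty responses become `NA`).
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(
    participant = readr::col_character(),
    site = readr::col_character(),
    experiment = readr::col_character(),
    list_type = readr::col_character(),
    list_id = readr::col_character(),
    repetition = readr::col_integer(),
    trial_index = readr::col_integer(),
    input_list = readr::col_character(),
    output_position = readr::col_integer(),
    response = readr::col_character(),
    rt_ms = readr::col_double()
  ), na = c("", "NA"))
  missing <- setdiff(trial_csv_columns, names(df))
  if (length(missing) > 0L) {
    stop("trial file is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  line <- seq_len(nrow(df)) + 1L  # header is line 1

  bad_list <- nchar(df$input_list) != 6L |
    vapply(strsplit(df$input_list, ""), anyDuplicated, integer(1)) > 0L
  bad_pos <- is.na(df$output_position) | df$output_position < 1L |
    df$output_position > 6L
  bad_resp <- !is.na(df$response) & nchar(df$response) != 1L
  bad_rt <- !is.na(df$rt_ms) & df$rt_ms <= 0
  problems <- c(
    report_lines(line[bad_list], "input_list must be 6 unique characters"),
    report_lines(line[bad_pos], "output_position must be in 1..6"),
    report_lines(line[bad_resp], "response must be a single character or empty"),
    report_lines(line[bad_rt], "rt_ms must be positive")
  )
  if (length(problems) > 0L) {
    stop("malformed trial rows:\n", paste(problems, collapse = "\n"),
         call. = FALSE)
  }
  if (!all(df$list_type %in% c("same", "spun", "scrambled"))) {
    stop("unknown list_type: ",
         paste(setdiff(unique(df$list_type), c("same", "spun", "scrambled")),
               collapse = ", "), call. = FALSE)
  }
  key <- paste(df$participant, df$trial_index, df$output_position, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (participant, trial_index, output_position) at line(s): ",
         paste(line[duplicated(key)], collapse = ", "), call. = FALSE)
  }
  inc <- df |>
    dplyr::arrange(.data$participant, .data$trial_index,
                   .data$output_position) |>
    dplyr::group_by(.data$participant, .data$trial_index) |>
    dplyr::summarise(ok = all(diff(.data$output_position) > 0) &&
                       .data$output_position[1L] >= 1L, .groups = "drop")
  if (!all(inc$ok)) {
    stop("output_position must be strictly increasing within each trial.",
         call. = FALSE)
  }
  df
}

report_lines <- function(lines, what) {
  if (length(lines) == 0L) return(character(0))
  sprintf("  line %d: %s", utils::head(lines, 10L), what)
}

#' @rdname read_trials
#' @param trials A tibble of trials.
#' @export
write_trials <- function(trials, path) {
  out <- trials[, intersect(trial_csv_columns, names(trials))]
  readr::write_csv(out, path, na = "")
  invisible(trials)
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> score -> false-start screen -> lag-CRPs -> error
#' ratios, position counts, group curves, and the contrast suite, writing
#' every table as CSV plus a plain-text log of all parameter choices, the
#' seed, and a hash of the configuration.
#'
#' @param config A named list, or the path of a YAML file holding one.
#'   Required keys: `out_dir`, `seed`, and either `input` (a trial CSV) or
#'   `simulate` (a list with `n_participants` and optionally `list_types`,
#'   `n_reps`, and [sim_params()] overrides under `params`). Optional keys:
#'   `repeat_policy` (`"scored"`, the default, or `"excluded"`),
#'   `aggregation` (`"group"` default), `cross_lags` (default `+1, -1, -5`),
#'   `plot` (default `FALSE`).
#' @return Invisibly, a list with the computed tibbles and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  required <- c("out_dir", "seed")
  missing <- setdiff(required, names(config))
  if (is.null(config$input) && is.null(config$simulate)) {
    missing <- c(missing, "input or simulate")
  }
  if (length(missing) > 0L) {
    stop("config is missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  repeat_policy <- config$repeat_policy %||% "scored"
  aggregation <- config$aggregation %||% "group"
  cross_lags <- as.integer(config$cross_lags %||% c(1L, -1L, -5L))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  simulated <- FALSE
  if (!is.null(config$input)) {
    trials <- read_trials(config$input)
  } else {
    sim <- config$simulate
    params <- do.call(sim_params, c(sim$params %||% list(),
                                    list(seed = as.integer(config$seed))))
    trials <- simulate_experiment(
      n_participants = sim$n_participants,
      list_types = sim$list_types %||% c("same", "spun", "scrambled"),
      params = params,
      n_reps = sim$n_reps %||% params$n_reps,
      seed = as.integer(config$seed)
    )
    simulated <- TRUE
  }

  scored <- detect_false_starts(score_trials(trials))
  overall <- overall_lag_crp(scored, repeat_policy)
  pa <- postanticipation_lag_crp(scored, repeat_policy)
  curves <- aggregate_crp(dplyr::bind_rows(overall, pa))
  ratios <- withCallingHandlers(
    error_ratio(pa, aggregation = aggregation),
    warning = function(w) invokeRestart("muffleWarning")
  )
  positions <- position_counts(scored, average = TRUE)
  errors <- summarize_errors(scored)
  contrasts <- suppressWarnings(run_contrast_suite(pa, cross_lags = cross_lags))

  paths <- list(
    scored = file.path(out_dir, "scored_trials.csv"),
    crp_overall = file.path(out_dir, "crp_overall.csv"),
    crp_postanticipation = file.path(out_dir, "crp_postanticipation.csv"),
    group_curves = file.path(out_dir, "crp_group_curves.csv"),
    error_ratios = file.path(out_dir, "error_ratios.csv"),
    position_counts = file.path(out_dir, "position_counts.csv"),
    error_summary = file.path(out_dir, "error_summary.csv"),
    contrasts = file.path(out_dir, "contrasts.csv"),
    log = file.path(out_dir, "pipeline_log.txt")
  )
  if (simulated) {
    paths$trials <- file.path(out_dir, "trials.csv")
    write_trials(trials, paths$trials)
  }
  readr::write_csv(scored, paths$scored, na = "")
  readr::write_csv(overall, paths$crp_overall)
  readr::write_csv(pa, paths$crp_postanticipation)
  readr::write_csv(curves, paths$group_curves)
  readr::write_csv(ratios, paths$error_ratios)
  readr::write_csv(positions, paths$position_counts)
  readr::write_csv(errors, paths$error_summary)
  readr::write_csv(contrasts, paths$contrasts)

  if (isTRUE(config$plot)) {
    paths$plot <- file.path(out_dir, "crp_curves.png")
    p <- plot_lag_crp(dplyr::filter(curves, .data$mode == "postanticipation"))
    ggplot2::ggsave(paths$plot, p, width = 7, height = 4, dpi = 150)
  }

  log_lines <- c(
    sprintf("spinfill %s", as.character(utils::packageVersion("spinfill"))),
    sprintf("config_hash: %s", rlang::hash(config)),
    sprintf("seed: %s", config$seed),
    sprintf("repeat_policy: %s", repeat_policy),
    sprintf("aggregation: %s", aggregation),
    sprintf("cross_lags: %s", paste(cross_lags, collapse = ", ")),
    sprintf("input: %s", if (simulated) "simulated" else config$input),
    sprintf("n_participants: %d", dplyr::n_distinct(trials$participant)),
    sprintf("n_trials: %d",
            nrow(dplyr::distinct(trials, .data$participant, .data$trial_index)))
  )
  writeLines(log_lines, paths$log)

  invisible(list(trials = trials, scored = scored, overall = overall,
                 postanticipation = pa, curves = curves, ratios = ratios,
                 position_counts = positions, error_summary = errors,
                 contrasts = contrasts, paths = paths))
}
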