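#' Transition lags of one recall sequence
#'
#' The lag of a recall transition is the signed difference between the input
#' positions of the current and the previous recalled item, computed on the
#' current trial's input list: correct forward recall gives +1, skipping one
#' item gives +2, going back to the immediately preceding item gives -1, and
#' a transition from the final item of a six-item list to the first gives -5.
#' Transitions are defined only between consecutively emitted list items; an
#' intervening intrusion or omission voids both adjacent transitions.
#'
#' @inheritParams score_trial
#' @return An integer vector of lags (possibly empty).
#' @export
#' @examples
#' transition_lags("ABCDEF", c("A", "B", "D", "C"))  # +1 +2 -1
transition_lags <- function(input_list, output) {
  sc <- score_trial(input_list, output)
  is_item <- !sc$label %in% c("omission", "intrusion")
  ok <- is_item & dplyr::lag(is_item, default = FALSE)
  (sc$inpos - dplyr::lag(sc$inpos))[ok]
}

#' Overall lag-conditional response probability
#'
#' For each participant and list type, counts every transition between
#' consecutively emitted list items and divides occurrences by
#' opportunities: for a transition following an item at input position p,
#' every lag L with 1 <= p + L <= n was possible, so each such L gains one
#' opportunity, and the observed lag gains one occurrence. Under
#' `repeat_policy = "excluded"`, re-recalling an already-recalled item earns
#' no occurrence, and opportunities skip lags whose target item had already
#' been recalled (so a repeat's own lag is never an opportunity either).
#'
#' @param scored A scored tibble ([score_trials()]).
#' @param repeat_policy `"scored"` (repeats count like any response) or
#'   `"excluded"`.
#' @return A lag-CRP tibble: `participant`, `experiment`, `site`,
#'   `list_type`, `mode`, `repeat_policy`, `lag` (-(n-1)..(n-1)),
#'   `numerator`, `denominator`, `crp` (`NA` where the denominator is 0).
#' @export
overall_lag_crp <- function(scored, repeat_policy = c("scored", "excluded")) {
  repeat_policy <- match.arg(repeat_policy)
  scored <- ensure_meta(scored)
  n_items <- max(nchar(scored$input_list))
  lag_range <- seq.int(-(n_items - 1L), n_items - 1L)

  scored <- dplyr::arrange(scored, .data$participant, .data$trial_index,
                           .data$output_position)
  uid <- cumsum(!duplicated(paste(scored$participant, scored$trial_index,
                                  sep = "\r")))
  j <- stats::ave(uid, uid, FUN = seq_along)
  first_seen <- first_emission_index(uid, j, scored$inpos, n_items)

  is_item <- !scored$label %in% c("omission", "intrusion")
  prev_same <- dplyr::lag(uid) == uid & dplyr::lag(j) == j - 1L
  trans <- which(is_item & dplyr::lag(is_item, default = FALSE) &
                   dplyr::coalesce(prev_same, FALSE))
  prev_inpos <- scored$inpos[trans - 1L]
  obs_lag <- scored$inpos[trans] - prev_inpos
  if (repeat_policy == "excluded") {
    # a repeat response earns no occurrence; its lag is also absent from
    # the opportunity set, which skips already-recalled targets
    obs_lag[scored$rerecall[trans]] <- NA_integer_
  }
  counts <- count_lags(
    uid = uid[trans], j = j[trans], prev_inpos = prev_inpos,
    obs_lag = obs_lag,
    lag_range = lag_range, n_items = n_items,
    first_seen = first_seen, exclude_recalled = repeat_policy == "excluded",
    keys = scored[trans, c("participant", "experiment", "site", "list_type")]
  )
  finish_crp_table(counts, scored, lag_range, "overall", repeat_policy)
}

#' Postanticipation lag-conditional response probability
#'
#' Restricts lag-CRP scoring to the first response after an anticipation
#' error, on trials where every response before the anticipation was correct
#' and the anticipation was not flagged as a false start (see
#' [detect_false_starts()]). Each eligible trial contributes exactly one
#' scored transition, taken relative to the anticipated item's input
#' position; at -1 lag the scored response is a *fill-in* (the skipped item),
#' at +1 lag an *infill* (the next item). Lags run from -(n-1) to n-2.
#' Under `repeat_policy = "excluded"`, opportunities additionally skip lags
#' landing on already-recalled items; because the pre-anticipation prefix is
#' correct, the -1 and +1 probabilities are identical under both policies.
#'
#' @inheritParams overall_lag_crp
#' @return A lag-CRP tibble (see [overall_lag_crp()]) with
#'   `mode = "postanticipation"`.
#' @export
postanticipation_lag_crp <- function(scored,
                                     repeat_policy = c("scored", "excluded")) {
  repeat_policy <- match.arg(repeat_policy)
  scored <- ensure_meta(scored)
  n_items <- max(nchar(scored$input_list))
  lag_range <- seq.int(-(n_items - 1L), n_items - 2L)

  scored <- dplyr::arrange(scored, .data$participant, .data$trial_index,
                           .data$output_position)
  uid <- cumsum(!duplicated(paste(scored$participant, scored$trial_index,
                                  sep = "\r")))
  j <- stats::ave(uid, uid, FUN = seq_along)
  first_seen <- first_emission_index(uid, j, scored$inpos, n_items)

  # the scored row: the emitted response right after the first anticipation
  is_item <- !scored$label %in% c("omission", "intrusion")
  sc_rows <- which(scored$pa_eligible &
                     scored$output_position == scored$pa_response_index &
                     is_item)
  prev_inpos <- scored$pa_anticip_inpos[sc_rows]
  obs_lag <- scored$inpos[sc_rows] - prev_inpos
  if (repeat_policy == "excluded") {
    obs_lag[scored$rerecall[sc_rows]] <- NA_integer_
  }
  counts <- count_lags(
    uid = uid[sc_rows], j = j[sc_rows], prev_inpos = prev_inpos,
    obs_lag = obs_lag,
    lag_range = lag_range, n_items = n_items,
    first_seen = first_seen, exclude_recalled = repeat_policy == "excluded",
    keys = scored[sc_rows, c("participant", "experiment", "site", "list_type")]
  )
  finish_crp_table(counts, scored, lag_range, "postanticipation", repeat_policy)
}

# Shared opportunity/occurrence counter.
# For each transition r: denominator[L] += 1 for lags L with the target
# position in range (and, optionally, its item not yet recalled before row
# j[r]); numerator[obs_lag[r]] += 1 (NA obs_lag increments nothing).
count_lags <- function(uid, j, prev_inpos, obs_lag, lag_range, n_items,
                       first_seen, exclude_recalled, keys) {
  m <- length(uid)
  nl <- length(lag_range)
  if (m == 0L) {
    return(tibble::tibble(participant = character(), experiment = character(),
                          site = character(), list_type = character(),
                          lag = integer(), numerator = integer(),
                          denominator = integer()))
  }
  L <- rep(lag_range, times = m)
  r <- rep(seq_len(m), each = nl)
  target <- prev_inpos[r] + L
  valid <- target >= 1L & target <= n_items
  if (exclude_recalled) {
    tv <- ifelse(valid, target, 1L)
    recalled_before <- first_seen[cbind(uid[r], tv)] < j[r]
    valid <- valid & !recalled_before
  }
  df <- tibble::tibble(
    keys[r[valid], ],
    lag = L[valid],
    hit = as.integer(!is.na(obs_lag[r[valid]]) & obs_lag[r[valid]] == L[valid])
  )
  dplyr::summarise(
    dplyr::group_by(df, .data$participant, .data$experiment, .data$site,
                    .data$list_type, .data$lag),
    numerator = sum(.data$hit), denominator = dplyr::n(), .groups = "drop"
  )
}

# Fill in default experiment/site metadata columns when absent.
ensure_meta <- function(scored) {
  if (!"experiment" %in% names(scored)) scored$experiment <- "exp1"
  if (!"site" %in% names(scored)) scored$site <- "site1"
  scored
}

# uid x input-position matrix of the within-trial row index at which each
# item was first emitted (Inf if never emitted).
first_emission_index <- function(uid, j, inpos, n_items) {
  seen <- matrix(Inf, nrow = max(uid), ncol = n_items)
  ok <- which(!is.na(inpos))
  first <- ok[!duplicated(cbind(uid[ok], inpos[ok]))]
  seen[cbind(uid[first], inpos[first])] <- j[first]
  seen
}

# Expand to the full participant x list_type x lag grid and add crp.
finish_crp_table <- function(counts, scored, lag_range, mode, repeat_policy) {
  units <- dplyr::distinct(scored, .data$participant, .data$experiment,
                           .data$site, .data$list_type)
  grid <- tidyr::crossing(units, lag = lag_range)
  out <- dplyr::left_join(
    grid, counts,
    by = c("participant", "experiment", "site", "list_type", "lag")
  )
  out$numerator[is.na(out$numerator)] <- 0L
  out$denominator[is.na(out$denominator)] <- 0L
  dplyr::mutate(
    out,
    mode = mode, repeat_policy = repeat_policy,
    crp = ifelse(.data$denominator > 0, .data$numerator / .data$denominator,
                 NA_real_),
    .after = "list_type"
  ) |>
    dplyr::relocate("lag", "numerator", "denominator", "crp",
                    .after = "repeat_policy") |>
    dplyr::arrange(.data$participant, .data$list_type, .data$lag)
}

#' Fill-in and infill probabilities and the error ratio
#'
#' The fill-in probability is the postanticipation lag-CRP at -1, the infill
#' probability the postanticipation lag-CRP at +1, and the error ratio their
#' quotient P(fill-in) / P(infill); a ratio above 1 indicates a fill-in
#' tendency. Probabilities can be aggregated per participant (each
#' participant's own crp values), per experiment (means over each
#' experiment's participants), or for the whole group (means over all
#' participants); the ratio is always formed from the probabilities at the
#' chosen level, and is `NA` (with a warning) when the infill probability
#' is 0 or missing.
#'
#' @param pa_table A participant-level postanticipation lag-CRP tibble from
#'   [postanticipation_lag_crp()].
#' @param aggregation `"group"`, `"experiment"`, or `"participant"`.
#' @return A tibble with `list_type`, `p_fill_in`, `p_infill`, `error_ratio`,
#'   `aggregation_level`, plus the identifying columns of the level.
#' @export
error_ratio <- function(pa_table,
                        aggregation = c("group", "experiment", "participant")) {
  aggregation <- match.arg(aggregation)
  if (!all(pa_table$mode == "postanticipation")) {
    stop("`error_ratio()` expects a postanticipation lag-CRP table.",
         call. = FALSE)
  }
  wide <- pa_table |>
    dplyr::filter(.data$lag %in% c(-1L, 1L)) |>
    dplyr::mutate(which = ifelse(.data$lag == -1L, "p_fill_in", "p_infill")) |>
    dplyr::select("participant", "experiment", "site", "list_type", "which",
                  "crp") |>
    tidyr::pivot_wider(names_from = "which", values_from = "crp")
  keys <- switch(aggregation,
    participant = c("participant", "experiment", "site", "list_type"),
    experiment = c("experiment", "list_type"),
    group = "list_type"
  )
  out <- wide |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      p_fill_in = mean(.data$p_fill_in, na.rm = TRUE),
      p_infill = mean(.data$p_infill, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      p_fill_in = ifelse(is.nan(.data$p_fill_in), NA_real_, .data$p_fill_in),
      p_infill = ifelse(is.nan(.data$p_infill), NA_real_, .data$p_infill),
      error_ratio = ifelse(!is.na(.data$p_infill) & .data$p_infill > 0,
                           .data$p_fill_in / .data$p_infill, NA_real_),
      aggregation_level = aggregation
    )
  if (any(is.na(out$error_ratio))) {
    warning("error ratio undefined where the infill probability is 0 or missing.",
            call. = FALSE)
  }
  out
}

#' Fill-in and infill counts by serial position
#'
#' For every scored postanticipation response, a -1 lag adds one fill-in
#' count and a +1 lag one infill count at the serial (output) position where
#' the anticipation occurred. Counts are totals per participant and list
#' type; with `average = TRUE` they are averaged over participants within
#' each list type.
#'
#' @inheritParams error_ratio
#' @param scored A scored, false-start-screened tibble.
#' @param average Average the per-participant counts over participants?
#' @return A tibble with `position`, `fill_in_count`, `infill_count` (and
#'   `participant` unless averaged).
#' @export
position_counts <- function(scored, average = FALSE) {
  n_items <- max(nchar(scored$input_list))
  is_item <- !scored$label %in% c("omission", "intrusion")
  rows <- scored[scored$pa_eligible &
                   scored$output_position == scored$pa_response_index &
                   is_item, , drop = FALSE]
  lag <- rows$inpos - rows$pa_anticip_inpos
  rows <- rows[!is.na(lag) & abs(lag) == 1L, , drop = FALSE]
  lag <- lag[!is.na(lag) & abs(lag) == 1L]
  base <- tidyr::crossing(
    dplyr::distinct(scored, .data$participant, .data$list_type),
    position = seq_len(n_items)
  )
  counted <- tibble::tibble(
    participant = rows$participant, list_type = rows$list_type,
    position = rows$pa_anticip_outpos, lag = lag
  ) |>
    dplyr::group_by(.data$participant, .data$list_type, .data$position) |>
    dplyr::summarise(fill_in_count = sum(.data$lag == -1L),
                     infill_count = sum(.data$lag == 1L), .groups = "drop")
  out <- dplyr::left_join(base, counted,
                          by = c("participant", "list_type", "position")) |>
    dplyr::mutate(fill_in_count = dplyr::coalesce(.data$fill_in_count, 0L),
                  infill_count = dplyr::coalesce(.data$infill_count, 0L))
  if (average) {
    out <- out |>
      dplyr::group_by(.data$list_type, .data$position) |>
      dplyr::summarise(fill_in_count = mean(.data$fill_in_count),
                       infill_count = mean(.data$infill_count),
                       .groups = "drop")
  }
  out
}

#' Average lag-CRP curves over participants
#'
#' Per list type and lag, the mean and standard error of the participant
#' lag-CRPs, using only participants with a defined probability at that lag
#' (participants without data for a lag are excluded at that lag only).
#'
#' @param tables A participant-level lag-CRP tibble (one `mode` and
#'   `repeat_policy`, or several -- curves are grouped by both).
#' @return A tibble with `list_type`, `mode`, `repeat_policy`, `lag`,
#'   `n` (participants contributing), `mean_crp`, `se_crp`.
#' @export
aggregate_crp <- function(tables) {
  tables |>
    dplyr::group_by(.data$list_type, .data$mode, .data$repeat_policy,
                    .data$lag) |>
    dplyr::summarise(
      n = sum(!is.na(.data$crp)),
      mean_crp = mean(.data$crp, na.rm = TRUE),
      se_crp = stats::sd(.data$crp, na.rm = TRUE) / sqrt(sum(!is.na(.data$crp))),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean_crp = ifelse(.data$n > 0, .data$mean_crp, NA_real_),
      se_crp = ifelse(.data$n > 1, .data$se_crp, NA_real_)
    )
}

#' Plot postanticipation lag-CRP curves
#'
#' Group mean curves (points and lines) with standard-error bars, one panel
#' per repeat policy, colour per list type.
#'
#' @param group_curves Output of [aggregate_crp()].
#' @return A ggplot object.
#' @export
plot_lag_crp <- function(group_curves) {
  ggplot2::ggplot(
    dplyr::filter(group_curves, !is.na(.data$mean_crp)),
    ggplot2::aes(x = .data$lag, y = .data$mean_crp,
                 colour = .data$list_type, group = .data$list_type)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_crp - .data$se_crp,
                   ymax = .data$mean_crp + .data$se_crp),
      width = 0.2, na.rm = TRUE
    ) +
    ggplot2::facet_wrap(~repeat_policy) +
    ggplot2::labs(x = "Lag", y = "Conditional response probability",
                  colour = "List type") +
    ggplot2::theme_minimal()
}
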