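#' Response labels used by the scorer
#' @noRd
response_labels <- c("correct", "anticipation", "postponement", "repeat",
                     "intrusion", "omission")

#' Score recall trials response by response
#'
#' Classifies every response of every trial into exactly one of six labels:
#' *correct* (the symbol matches the input list at the response's output
#' position), *anticipation* (a list item reported earlier than its input
#' position), *postponement* (a list item reported later than its input
#' position), *repeat* (a list item already emitted earlier in this trial's
#' output, when not correct), *intrusion* (a symbol not in the input list),
#' or *omission* (no response). It also derives the fields that
#' postanticipation lag-CRP scoring needs: the length of the correct prefix,
#' whether the first error is an anticipation, and -- when it is, and at
#' least one response follows it -- which response is the scored
#' postanticipation response.
#'
#' Trials become `pa_eligible` when every response before the first
#' anticipation is correct and the anticipation is followed by at least one
#' emitted response; [detect_false_starts()] can subsequently revoke
#' eligibility for fast first-position anticipations.
#'
#' @param trials A tibble of trial rows in the long dialect produced by
#'   [simulate_session()] or [read_trials()].
#' @return The input tibble, ordered by participant / trial / output
#'   position, with columns added: `inpos` (the response's input position,
#'   `NA` for omissions and intrusions), `label`, `rerecall` (the item was
#'   already recalled earlier in the trial, regardless of label), and the
#'   trial-level fields `prefix_correct_len`, `first_error_is_anticipation`,
#'   `false_start` (initialised `FALSE`), `pa_eligible`, `pa_anticip_outpos`,
#'   `pa_anticip_inpos`, `pa_response_index` (repeated on every row of the
#'   trial; `NA` where undefined).
#' @export
#' @examples
#' score_trial("ABCDEF", c("A", "B", "D", "C"))$label
score_trials <- function(trials) {
  required <- c("participant", "list_type", "trial_index", "input_list",
                "output_position", "response")
  missing <- setdiff(required, names(trials))
  if (length(missing) > 0L) {
    stop("`trials` is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  trials <- dplyr::arrange(trials, .data$participant, .data$trial_index,
                           .data$output_position)
  n_items <- nchar(trials$input_list)
  if (any(trials$output_position < 1L | trials$output_position > n_items)) {
    stop("`output_position` out of the 1..list-length range.", call. = FALSE)
  }
  uid <- cumsum(!duplicated(paste(trials$participant, trials$trial_index,
                                  sep = "\r")))
  j <- stats::ave(uid, uid, FUN = seq_along)

  response <- trials$response
  response[!is.na(response) & response == ""] <- NA_character_
  omission <- is.na(response)
  loc <- stringr::str_locate(trials$input_list,
                             stringr::fixed(dplyr::coalesce(response, "\001")))[, 1L]
  inpos <- as.integer(loc)
  intrusion <- !omission & is.na(inpos)
  is_item <- !omission & !intrusion
  rerecall <- is_item & duplicated(paste(uid, response, sep = "\r"))

  label <- character(length(response))
  label[omission] <- "omission"
  label[intrusion] <- "intrusion"
  correct <- is_item & inpos == trials$output_position
  label[correct] <- "correct"
  rep_lab <- is_item & !correct & rerecall
  label[rep_lab] <- "repeat"
  antic <- is_item & !correct & !rerecall & inpos > trials$output_position
  label[antic] <- "anticipation"
  post <- is_item & !correct & !rerecall & inpos < trials$output_position
  label[post] <- "postponement"

  # trial-level derivations
  lead_correct <- stats::ave(as.numeric(correct), uid, FUN = cumprod)
  prefix_len <- stats::ave(lead_correct, uid, FUN = sum)
  first_err_j <- prefix_len + 1
  is_first_err <- j == first_err_j
  fe_antic_row <- is_first_err & label == "anticipation"
  first_error_is_anticipation <- stats::ave(as.numeric(fe_antic_row), uid,
                                            FUN = max) > 0
  # the scored response: the row after the anticipation, which must be emitted
  next_emitted <- j == first_err_j + 1 & !omission
  has_next <- stats::ave(as.numeric(next_emitted), uid, FUN = max) > 0
  pa_eligible <- first_error_is_anticipation & has_next

  pick <- function(x, row_flag) {
    v <- ifelse(row_flag, x, NA)
    stats::ave(v, uid, FUN = function(z) {
      if (all(is.na(z))) NA_real_ else z[!is.na(z)][1L]
    })
  }
  pa_anticip_outpos <- pick(trials$output_position, fe_antic_row)
  pa_anticip_inpos <- pick(inpos, fe_antic_row)
  pa_response_index <- pick(trials$output_position, j == first_err_j + 1)
  pa_anticip_outpos[!pa_eligible] <- NA
  pa_anticip_inpos[!pa_eligible] <- NA
  pa_response_index[!pa_eligible] <- NA

  dplyr::mutate(trials,
    response = response,
    inpos = inpos,
    label = factor(label, levels = response_labels),
    rerecall = rerecall,
    prefix_correct_len = as.integer(prefix_len),
    first_error_is_anticipation = first_error_is_anticipation,
    false_start = FALSE,
    pa_eligible = pa_eligible,
    pa_anticip_outpos = as.integer(pa_anticip_outpos),
    pa_anticip_inpos = as.integer(pa_anticip_inpos),
    pa_response_index = as.integer(pa_response_index)
  )
}

#' Score a single handwritten trial
#'
#' Convenience wrapper around [score_trials()] for desk checking: builds a
#' one-trial tibble from an input list and an output sequence.
#'
#' @param input_list Character string (e.g. `"ABCDEF"`) or vector of the
#'   presented list.
#' @param output Character vector of responses in output order (`NA` for an
#'   omission).
#' @param rt_ms Optional response times (ms).
#' @param ... Metadata columns (`participant`, `list_type`, ...).
#' @return A scored one-trial tibble.
#' @export
score_trial <- function(input_list, output, rt_ms = NULL, ...) {
  if (length(input_list) > 1L) input_list <- paste(input_list, collapse = "")
  meta <- list(...)
  df <- tibble::tibble(
    participant = meta$participant %||% "P001",
    site = meta$site %||% "site1",
    experiment = meta$experiment %||% "exp1",
    list_type = meta$list_type %||% "scrambled",
    list_id = meta$list_id %||% "L1",
    repetition = meta$repetition %||% 1L,
    trial_index = meta$trial_index %||% 1L,
    input_list = input_list,
    output_position = seq_along(output),
    response = as.character(output),
    rt_ms = if (is.null(rt_ms)) NA_real_ else rt_ms
  )
  score_trials(df)
}

#' Flag false-start anticipations by response time
#'
#' First responses are typically much slower than later responses; a
#' first-position anticipation produced faster than a participant's usual
#' second response is more plausibly a motor false start (a transposed or
#' premature keystroke) than a memory error, and inflates fill-in or infill
#' rates if scored. For each participant the cutoff is the 75th percentile
#' (linear interpolation between closest ranks, i.e. rank 1 + 0.75 (n - 1))
#' of all second-response times; any trial whose first response is an
#' anticipation with a response time strictly below the cutoff is flagged
#' `false_start = TRUE` and loses postanticipation eligibility. Participants
#' with fewer than `min_second` second-response times keep all trials
#' unflagged (with a warning), since the cutoff cannot be estimated.
#'
#' @param scored A scored tibble from [score_trials()] with `rt_ms` present.
#' @param min_second Minimum number of second-response times needed to
#'   estimate the cutoff.
#' @return The tibble with `false_start` and `pa_eligible` updated.
#' @export
detect_false_starts <- function(scored, min_second = 4L) {
  if (!"rt_ms" %in% names(scored)) {
    stop("`scored` must contain response times (`rt_ms`).", call. = FALSE)
  }
  out <- split(scored, scored$participant)
  out <- lapply(out, function(df) {
    second <- df$rt_ms[df$output_position == 2L & !is.na(df$rt_ms)]
    if (length(second) < min_second) {
      warning(sprintf(
        "participant %s: only %d second-response times; false-start cutoff not estimated, no trials flagged.",
        df$participant[1L], length(second)), call. = FALSE)
      return(df)
    }
    cutoff <- unname(stats::quantile(second, 0.75, type = 7))
    flag_rows <- df$output_position == 1L & df$label == "anticipation" &
      !is.na(df$rt_ms) & df$rt_ms < cutoff
    flagged_trials <- unique(df$trial_index[flag_rows])
    hit <- df$trial_index %in% flagged_trials
    df$false_start[hit] <- TRUE
    df$pa_eligible[hit] <- FALSE
    df$pa_anticip_outpos[hit] <- NA_integer_
    df$pa_anticip_inpos[hit] <- NA_integer_
    df$pa_response_index[hit] <- NA_integer_
    df
  })
  dplyr::bind_rows(out)
}

#' Summarise response-level error rates
#'
#' Per participant and list type, the proportion of responses that were
#' correct, *order errors* (anticipations, postponements, and repeats of list
#' items), or *item errors* (intrusions and omissions). Every trial has one
#' scoring opportunity per serial position: output positions never reached
#' (after the trial ended early) count as omissions.
#'
#' @param scored A scored tibble from [score_trials()].
#' @return A tibble with columns `participant`, `list_type`, `n_trials`,
#'   `correct_rate`, `order_error_rate`, `item_error_rate` (rates sum to 1).
#' @export
summarize_errors <- function(scored) {
  scored |>
    dplyr::group_by(.data$participant, .data$list_type) |>
    dplyr::summarise(
      n_trials = dplyr::n_distinct(.data$trial_index),
      n_slots = sum(nchar(.data$input_list[!duplicated(.data$trial_index)])),
      n_correct = sum(.data$label == "correct"),
      n_order = sum(.data$label %in% c("anticipation", "postponement", "repeat")),
      n_item = sum(.data$label %in% c("intrusion", "omission")),
      n_responses = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_item = .data$n_item + (.data$n_slots - .data$n_responses),
      correct_rate = .data$n_correct / .data$n_slots,
      order_error_rate = .data$n_order / .data$n_slots,
      item_error_rate = .data$n_item / .data$n_slots
    ) |>
    dplyr::select("participant", "list_type", "n_trials", "correct_rate",
                  "order_error_rate", "item_error_rate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
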