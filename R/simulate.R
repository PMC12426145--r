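#' Parameters of the generative serial-recall model
#'
#' The simulator recalls a six-item list one output position at a time by
#' combining three retrieval cues, each of which can be weighted:
#'
#' * a *positional* cue for the current trial (`w_pos`), which activates the
#'   item whose input position matches the current output position, with
#'   exponential generalisation to neighbouring positions (`lambda_pos`) --
#'   an item-independent cue;
#' * a learned *position-to-item* memory (`w_posmem`) accumulated over
#'   repetitions of the same set -- also item-independent;
#' * a learned *item-to-item* chaining memory (`w_chain`) cued by the
#'   previously recalled item -- an item-dependent cue.
#'
#' Activations are scaled by a primacy gradient (`lambda_prim`, exponential
#' decay over input position) and by response suppression (`s`), which
#' down-weights items already recalled on this trial. Both associative
#' memories grow by `eta` per presentation. Responses are chosen by a Luce
#' rule with noise `temperature` (0 = deterministic argmax, ties to the
#' lowest input position). Omissions terminate the trial with probability
#' `p_omit` per response; extra-list intrusions occur with probability
#' `p_intrude` and are drawn uniformly from a reserved lower-case alphabet
#' disjoint from all list sets. Response times are log-normal with a slow
#' first keystroke (`rt_first_mu` vs `rt_later_mu`, common `rt_sigma`, all on
#' the log-millisecond scale). With probability `p_false_start` the first two
#' responses of a trial are transposed and the first response time is
#' resampled from below the median of the second-response distribution,
#' emulating the motor false starts the scoring stage screens for.
#'
#' @param w_pos,w_posmem,w_chain Non-negative cue weights.
#' @param lambda_pos Positional generalisation decay (per position).
#' @param lambda_prim Primacy gradient decay (per input position).
#' @param s Response-suppression strength in \[0, 1\].
#' @param eta Association learning rate per presentation.
#' @param temperature Choice noise; 0 gives deterministic argmax.
#' @param p_omit,p_intrude,p_false_start Probabilities in \[0, 1\].
#' @param rt_first_mu,rt_later_mu,rt_sigma Log-scale response-time
#'   parameters (log ms).
#' @param n_reps Default repetitions per list when simulating sessions.
#' @param seed Default seed for [simulate_experiment()].
#'
#' @return A `sim_params` list.
#' @export
sim_params <- function(w_pos = 1, w_posmem = 0.5, w_chain = 0.2,
                       lambda_pos = 1, lambda_prim = 0.3, s = 0.8,
                       eta = 0.08, temperature = 0.5,
                       p_omit = 0.015, p_intrude = 0.015,
                       rt_first_mu = log(1100), rt_later_mu = log(420),
                       rt_sigma = 0.35, p_false_start = 0.03,
                       n_reps = 10, seed = 1L) {
  p <- list(w_pos = w_pos, w_posmem = w_posmem, w_chain = w_chain,
            lambda_pos = lambda_pos, lambda_prim = lambda_prim, s = s,
            eta = eta, temperature = temperature, p_omit = p_omit,
            p_intrude = p_intrude, rt_first_mu = rt_first_mu,
            rt_later_mu = rt_later_mu, rt_sigma = rt_sigma,
            p_false_start = p_false_start, n_reps = n_reps, seed = seed)
  for (nm in c("w_pos", "w_posmem", "w_chain", "lambda_pos", "lambda_prim",
               "eta", "rt_sigma")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || is.na(p[[nm]]) || p[[nm]] < 0) {
      stop(sprintf("`%s` must be a non-negative number.", nm), call. = FALSE)
    }
  }
  for (nm in c("s", "p_omit", "p_intrude", "p_false_start")) {
    if (!is.numeric(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1) {
      stop(sprintf("`%s` must be a probability in [0, 1].", nm), call. = FALSE)
    }
  }
  if (p$temperature < 0) stop("`temperature` must be >= 0.", call. = FALSE)
  structure(p, class = "sim_params")
}

#' Reserved extra-list intrusion alphabet
#'
#' Six lower-case symbols disjoint from every (upper-case) list set, used for
#' simulated extra-list intrusions.
#' @return A character vector of length 6.
#' @export
intrusion_alphabet <- function() c("u", "v", "w", "x", "y", "z")

#' Create an empty associative memory state
#'
#' Holds the two learned cue stores of the simulator: `C`, item-to-item
#' (chaining) strengths, and `P`, position-to-item strengths, both
#' accumulated across presentations of one list set and row-normalised at
#' retrieval time.
#'
#' @param items The set's base items.
#' @param n_positions Number of serial positions (defaults to the number of
#'   items).
#' @return An environment of class `assoc_state` with matrices `C`
#'   (items x items) and `P` (positions x items).
#' @export
assoc_state <- function(items, n_positions = length(items)) {
  items <- as.character(items)
  e <- new.env(parent = emptyenv())
  e$C <- matrix(0, length(items), length(items), dimnames = list(items, items))
  e$P <- matrix(0, n_positions, length(items), dimnames = list(NULL, items))
  class(e) <- "assoc_state"
  e
}

#' Accumulate associations from one list presentation
#'
#' For each adjacent input pair (x, y) of `input_list`, `C[x, y]` grows by
#' `eta`; for each position p, `P[p, input_list[p]]` grows by `eta`. Called
#' once per simulated trial, after the recall attempt.
#'
#' @param state An [assoc_state()].
#' @param input_list Character vector of the presented list.
#' @param eta Learning rate.
#' @return `state`, invisibly (updated in place).
#' @export
learn_list <- function(state, input_list, eta) {
  idx <- match(input_list, colnames(state$C))
  if (anyNA(idx)) stop("`input_list` contains symbols unknown to this state.", call. = FALSE)
  n <- length(idx)
  state$C[cbind(idx[-n], idx[-1L])] <- state$C[cbind(idx[-n], idx[-1L])] + eta
  state$P[cbind(seq_len(n), idx)] <- state$P[cbind(seq_len(n), idx)] + eta
  invisible(state)
}

#' Retrieval activation of one candidate item
#'
#' Evaluates the simulator's activation rule for a single candidate:
#' \deqn{a(i) = e^{-\lambda_{prim}(pos_i - 1)} \left[ w_{pos}
#'   e^{-\lambda_{pos} |pos_i - k|} + w_{posmem} \hat P[k, i] + w_{chain}
#'   \hat C[prev, i] \right] (1 - s\,\mathbf{1}\{i \in recalled\})}
#' where \eqn{pos_i} is the item's input position on the current trial, k the
#' output position, and \eqn{\hat P}, \eqn{\hat C} row-normalised association
#' strengths (zero for empty rows; the chain term is zero when there is no
#' previous recalled item).
#'
#' @param item Candidate symbol (must belong to `input_list` or to
#'   [intrusion_alphabet()]; intrusion symbols have zero activation).
#' @param output_position Current output position (1-based).
#' @param prev_item Previously recalled item, or `NA` at the first output
#'   position.
#' @param recalled Character vector of items already recalled this trial.
#' @param input_list The current trial's presented list.
#' @param state An [assoc_state()].
#' @param params A [sim_params()].
#' @return A non-negative scalar activation.
#' @export
candidate_activation <- function(item, output_position, prev_item, recalled,
                                 input_list, state, params) {
  if (!item %in% input_list) {
    if (item %in% intrusion_alphabet()) return(0)
    stop("`item` is neither a list item nor an allowed intrusion symbol.",
         call. = FALSE)
  }
  if (output_position < 1L || output_position > nrow(state$P)) {
    stop("`output_position` out of range.", call. = FALSE)
  }
  a <- .activations(output_position, prev_item,
                    input_list %in% recalled, input_list, state, params)
  a[[match(item, input_list)]]
}

# Vectorised activation over all items of `input_list`.
.activations <- function(k, prev_item, recalled_mask, input_list, state, params) {
  n <- length(input_list)
  prim <- exp(-params$lambda_prim * (seq_len(n) - 1))
  cue <- params$w_pos * exp(-params$lambda_pos * abs(seq_len(n) - k))
  if (params$w_posmem > 0) {
    prow <- state$P[k, input_list]
    tot <- sum(state$P[k, ])
    if (tot > 0) cue <- cue + params$w_posmem * prow / tot
  }
  if (params$w_chain > 0 && !is.na(prev_item) && prev_item %in% colnames(state$C)) {
    crow <- state$C[prev_item, input_list]
    tot <- sum(state$C[prev_item, ])
    if (tot > 0) cue <- cue + params$w_chain * crow / tot
  }
  prim * cue * (1 - params$s * recalled_mask)
}

# Luce choice with temperature; temperature 0 = argmax, ties to lowest index.
.choose <- function(act, temperature) {
  if (temperature <= 0) return(which.max(act))
  w <- act^(1 / temperature)
  if (!all(is.finite(w)) || sum(w) <= 0) {
    return(which.max(act))
  }
  sample.int(length(w), 1L, prob = w)
}

#' Simulate one recall trial
#'
#' Generates up to one response per output position: with probability
#' `p_omit` the trial ends in an omission; with probability `p_intrude` an
#' extra-list symbol is emitted; otherwise a list item is chosen by the Luce
#' rule over [candidate_activation()]. After the recall attempt the
#' associative state is updated by [learn_list()]. Uses the current R random
#' number generator state.
#'
#' @inheritParams candidate_activation
#' @return A list with `responses` (character; `NA` marks an omission) and
#'   `rt_ms` (numeric, `NA` for omissions), both of length <= the list
#'   length.
#' @export
simulate_trial <- function(input_list, state, params) {
  n <- length(input_list)
  responses <- character(0)
  rts <- numeric(0)
  recalled <- rep(FALSE, n)
  prev_item <- NA_character_
  for (k in seq_len(n)) {
    if (stats::runif(1) < params$p_omit) {
      responses <- c(responses, NA_character_)
      rts <- c(rts, NA_real_)
      break
    }
    if (stats::runif(1) < params$p_intrude) {
      sym <- sample(intrusion_alphabet(), 1L)
      prev_item <- NA_character_
    } else {
      act <- .activations(k, prev_item, recalled, input_list, state, params)
      pick <- .choose(act, params$temperature)
      sym <- input_list[pick]
      recalled[pick] <- TRUE
      prev_item <- sym
    }
    mu <- if (k == 1L) params$rt_first_mu else params$rt_later_mu
    responses <- c(responses, sym)
    rts <- c(rts, stats::rlnorm(1, mu, params$rt_sigma))
  }
  if (length(responses) >= 2L && !anyNA(responses[1:2]) &&
      stats::runif(1) < params$p_false_start) {
    responses[1:2] <- responses[2:1]
    rts[1L] <- stats::qlnorm(stats::runif(1, 0, 0.5),
                             params$rt_later_mu, params$rt_sigma)
  }
  learn_list(state, input_list, params$eta)
  list(responses = responses, rt_ms = rts)
}

#' Simulate a practice session over one or more list sets
#'
#' Each schedule entry pairs a [make_same_set()] / [make_spun_set()] /
#' [make_scrambled_set()] list set with a repetition count. Within a set the
#' lists are presented in repeating cycles, with the order of lists shuffled
#' anew on each cycle; one [assoc_state()] is maintained per set, so learning
#' accrues within but not across sets. Uses the current RNG state unless
#' `seed` is given.
#'
#' @param schedule A `list_set`, or a list of entries `list(set = , n_reps = )`.
#' @param params A [sim_params()].
#' @param participant,experiment,site Labels stamped on every trial.
#' @param n_reps Repetitions per list for entries that do not state one
#'   (default `params$n_reps`).
#' @param seed Optional integer seed.
#' @return A tibble of trial rows in the long dialect used throughout the
#'   package: `participant`, `site`, `experiment`, `list_type`, `list_id`,
#'   `repetition`, `trial_index`, `input_list`, `output_position`,
#'   `response`, `rt_ms`.
#' @export
simulate_session <- function(schedule, params = sim_params(),
                             participant = "P001", experiment = "exp1",
                             site = "site1", n_reps = params$n_reps,
                             seed = NULL) {
  if (inherits(schedule, "list_set")) {
    schedule <- list(list(set = schedule, n_reps = n_reps))
  }
  if (!is.list(schedule) || length(schedule) == 0L) {
    stop("`schedule` must be a non-empty list of (set, n_reps) entries.",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- list()
  trial_index <- 0L
  for (entry in schedule) {
    set <- if (inherits(entry, "list_set")) entry else entry$set
    reps <- if (inherits(entry, "list_set") || is.null(entry$n_reps)) n_reps else entry$n_reps
    if (!inherits(set, "list_set")) {
      stop("Each schedule entry must contain a `list_set`.", call. = FALSE)
    }
    state <- assoc_state(set$base_items, n_positions = length(set$base_items))
    n_lists <- length(set$lists)
    for (rep_i in seq_len(reps)) {
      order <- sample.int(n_lists)
      for (li in order) {
        input_list <- set$lists[[li]]
        tr <- simulate_trial(input_list, state, params)
        trial_index <- trial_index + 1L
        m <- length(tr$responses)
        out[[length(out) + 1L]] <- list(
          list_type = set$list_type,
          list_id = paste0(set$set_id, "_L", li),
          repetition = rep_i,
          trial_index = trial_index,
          input_list = paste(input_list, collapse = ""),
          output_position = seq_len(m),
          response = tr$responses,
          rt_ms = tr$rt_ms
        )
      }
    }
  }
  pos <- unlist(lapply(out, `[[`, "output_position"))
  lens <- vapply(out, function(x) length(x$output_position), integer(1))
  tibble::tibble(
    participant = participant,
    site = site,
    experiment = experiment,
    list_type = rep(vapply(out, `[[`, character(1), "list_type"), lens),
    list_id = rep(vapply(out, `[[`, character(1), "list_id"), lens),
    repetition = rep(vapply(out, `[[`, integer(1), "repetition"), lens),
    trial_index = rep(vapply(out, `[[`, integer(1), "trial_index"), lens),
    input_list = rep(vapply(out, `[[`, character(1), "input_list"), lens),
    output_position = as.integer(pos),
    response = unlist(lapply(out, `[[`, "response")),
    rt_ms = unlist(lapply(out, `[[`, "rt_ms"))
  )
}

#' Simulate a multi-participant serial-learning experiment
#'
#' Emulates a within-subject design in which every participant practises each
#' requested list type. Each participant receives non-overlapping sets of six
#' upper-case letters, drawn at random, one set per list type: the same set
#' repeats one list six times, the spun set contains the six rotations, and
#' the scrambled set is a Williams balanced Latin square. Sessions present
#' the sets in blocks, cycling through each set's lists `n_reps` times.
#' Participants get independent, reproducible random substreams derived from
#' `seed`.
#'
#' @param n_participants Number of simulated participants.
#' @param list_types Subset of `c("same", "spun", "scrambled")`.
#' @param params A [sim_params()].
#' @param n_reps Repetitions per list.
#' @param seed Integer seed (default `params$seed`).
#' @param experiment,site Labels.
#' @return A tibble of trial rows (see [simulate_session()]).
#' @export
#' @examples
#' trials <- simulate_experiment(2, n_reps = 2, seed = 42)
#' dplyr::count(trials, participant, list_type)
simulate_experiment <- function(n_participants,
                                list_types = c("same", "spun", "scrambled"),
                                params = sim_params(), n_reps = params$n_reps,
                                seed = params$seed, experiment = "exp1",
                                site = "site1") {
  list_types <- match.arg(list_types, several.ok = TRUE)
  makers <- list(
    same = function(items, id) make_same_set(items, n_lists = 6, set_id = id),
    spun = function(items, id) make_spun_set(items, set_id = id),
    scrambled = function(items, id) make_scrambled_set(items, set_id = id)
  )
  sessions <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    set.seed(participant_seed(seed, i))
    letters_i <- sample(LETTERS, 6L * length(list_types))
    schedule <- lapply(seq_along(list_types), function(j) {
      items <- letters_i[(6L * (j - 1L) + 1L):(6L * j)]
      list(set = makers[[list_types[j]]](items, paste0(list_types[j], "_", i)),
           n_reps = n_reps)
    })
    sessions[[i]] <- simulate_session(
      schedule, params = params,
      participant = sprintf("P%03d", i),
      experiment = experiment, site = site
    )
  }
  dplyr::bind_rows(sessions)
}

# Derived per-participant seed, kept inside 32-bit integer range.
participant_seed <- function(seed, i) {
  as.integer((as.double(seed) + 999983 * as.double(i)) %% .Machine$integer.max)
}
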