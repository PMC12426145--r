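test_that("the canonical anticipation example is scored correctly", {
  sc <- score_trial("ABCDEF", c("A", "B", "D", "C"))
  expect_equal(as.character(sc$label),
               c("correct", "correct", "anticipation", "postponement"))
  expect_true(all(sc$pa_eligible))
  expect_equal(sc$pa_response_index[1], 4L)
  expect_equal(sc$pa_anticip_outpos[1], 3L)
  expect_equal(sc$pa_anticip_inpos[1], 4L)
  expect_equal(sc$prefix_correct_len[1], 2L)
})

test_that("label assignment covers every response class exactly once", {
  sc <- score_trial("ABCDEF", c("A", "B", "A", "u", NA))
  expect_equal(as.character(sc$label),
               c("correct", "correct", "repeat", "intrusion", "omission"))
  # fully correct trial: no anticipation, not pa-eligible
  sc2 <- score_trial("ABCDEF", strsplit("ABCDEF", "")[[1]])
  expect_true(all(sc2$label == "correct"))
  expect_false(any(sc2$pa_eligible))
  # every response gets exactly one defined label
  set.seed(31)
  for (i in 1:50) {
    out <- sample(c(strsplit("ABCDEF", "")[[1]], "u", NA), sample(1:6, 1),
                  replace = TRUE)
    if (any(is.na(out))) out <- out[seq_len(which(is.na(out))[1])]
    sc <- score_trial("ABCDEF", out)
    expect_false(any(is.na(sc$label)))
  }
})

test_that("eligibility requires a correct prefix and a following response", {
  # intrusion before the anticipation breaks the prefix
  sc <- score_trial("ABCDEF", c("A", "u", "D", "C"))
  expect_false(any(sc$pa_eligible))
  # anticipation as the last response has nothing to score
  sc <- score_trial("ABCDEF", c("A", "B", "D"))
  expect_false(any(sc$pa_eligible))
  # a repeat first error is not an anticipation
  sc <- score_trial("ABCDEF", c("A", "B", "A", "C"))
  expect_false(any(sc$pa_eligible))
  # anticipation at the first position can be eligible
  sc <- score_trial("ABCDEF", c("B", "C", "D"))
  expect_true(all(sc$pa_eligible))
  expect_equal(sc$pa_anticip_inpos[1], 2L)
})

test_that("false-start screening uses the per-participant 75th percentile", {
  # four second responses with RTs 200..260 -> interpolated cutoff 245 ms
  outputs <- list(c("A", "B", "C"), c("A", "B", "C"), c("A", "B", "C"),
                  c("A", "B", "C"), c("B", "C", "D"), c("B", "C", "D"),
                  c("C", "B", "A"))
  rts <- list(c(900, 200, 210), c(900, 220, 210), c(900, 240, 210),
              c(900, 260, 210), c(240, 300, 300), c(245, 300, 300),
              c(100, 300, 300))
  trials <- make_trials("ABCDEF", outputs, rts)
  scored <- detect_false_starts(score_trials(trials))
  by_trial <- scored[scored$output_position == 1, ]
  # trial 5: first-position anticipation at 240 < cutoff -> flagged
  expect_true(by_trial$false_start[by_trial$trial_index == 5])
  expect_false(by_trial$pa_eligible[by_trial$trial_index == 5])
  # trial 7 first response C (anticipation) at 100 -> flagged
  expect_true(by_trial$false_start[by_trial$trial_index == 7])
  # correct first responses are never flagged
  expect_false(any(by_trial$false_start[by_trial$trial_index %in% 1:4]))
})

test_that("the false-start comparison is strict and first-position only", {
  # second responses 200,220,240,260,300 -> interpolated 75th percentile 260
  outputs <- list(c("A", "B"), c("A", "B"), c("A", "B"), c("A", "B"),
                  c("B"), c("A", "B", "E", "D"))
  rts <- list(c(900, 200), c(900, 220), c(900, 240), c(900, 260),
              c(260), c(900, 300, 240, 300))
  trials <- make_trials("ABCDEF", outputs, rts)
  scored <- detect_false_starts(score_trials(trials))
  # trial 5: first-position anticipation with RT exactly at the cutoff is
  # not "shorter than" it
  expect_false(any(scored$false_start[scored$trial_index == 5]))
  # trial 6: an anticipation at output position 3 is never flagged
  expect_false(any(scored$false_start[scored$trial_index == 6]))
})

test_that("too few second responses leaves trials unflagged with a warning", {
  trials <- make_trials("ABCDEF", list(c("B", "C"), c("A", "B")),
                        rts = list(c(10, 200), c(900, 250)))
  expect_warning(scored <- detect_false_starts(score_trials(trials)),
                 "second-response")
  expect_false(any(scored$false_start))
  expect_true(any(scored$pa_eligible))
})

test_that("error summaries count trailing omissions as item errors", {
  scored <- score_trials(make_trials("ABCDEF", list(c("A", "B", "D", "C"))))
  s <- summarize_errors(scored)
  expect_equal(s$order_error_rate, 2 / 6)
  expect_equal(s$item_error_rate, 2 / 6)
  expect_equal(s$correct_rate, 2 / 6)

  all_ok <- score_trials(make_trials("ABCDEF",
                                     list(strsplit("ABCDEF", "")[[1]])))
  s2 <- summarize_errors(all_ok)
  expect_equal(s2$correct_rate, 1)
  expect_equal(s2$order_error_rate, 0)
  expect_equal(s2$item_error_rate, 0)
})

test_that("chaining support lowers spun order errors relative to scrambled", {
  p <- sim_params(w_chain = 0.6)
  trials <- simulate_experiment(30, list_types = c("spun", "scrambled"),
                                params = p, n_reps = 8, seed = 2024)
  rates <- summarize_errors(score_trials(trials)) |>
    dplyr::group_by(.data$list_type) |>
    dplyr::summarise(order = mean(.data$order_error_rate))
  expect_lt(rates$order[rates$list_type == "spun"],
            rates$order[rates$list_type == "scrambled"])
})
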