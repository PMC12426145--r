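items6 <- strsplit("ABCDEF", "")[[1]]

test_that("candidate activation follows the stated retrieval rule", {
  st <- assoc_state(items6)
  # full suppression of an already-recalled item
  p <- sim_params(s = 1)
  expect_equal(
    candidate_activation("C", 4, "B", recalled = c("A", "B", "C"),
                         items6, st, p), 0)
  # primacy gradient alone: item at input position 3, perfectly positional cue
  p <- sim_params(w_pos = 1, w_posmem = 0, w_chain = 0, lambda_pos = 0,
                  lambda_prim = 0.5, s = 0)
  expect_equal(
    candidate_activation("C", 3, NA, recalled = character(0), items6, st, p),
    exp(-1))
  # sharp positional tuning: only the in-position item is active
  p <- sim_params(w_pos = 1, w_posmem = 0, w_chain = 0, lambda_pos = 50,
                  lambda_prim = 0, s = 0)
  acts <- vapply(items6, candidate_activation, numeric(1),
                 output_position = 2, prev_item = NA,
                 recalled = character(0), input_list = items6,
                 state = st, params = p)
  expect_gt(acts[["B"]], 1e-10)
  expect_true(all(acts[setdiff(items6, "B")] < 1e-20))
  # intrusion symbols have zero activation; foreign symbols are rejected
  expect_equal(candidate_activation("z", 1, NA, character(0), items6, st, p), 0)
  expect_error(candidate_activation("9", 1, NA, character(0), items6, st, p),
               "intrusion")
})

test_that("noiseless positional recall reproduces the input list on every trial", {
  p <- sim_params(w_chain = 0, w_posmem = 0, lambda_pos = 5, temperature = 0,
                  s = 1, p_omit = 0, p_intrude = 0, p_false_start = 0)
  trials <- simulate_session(make_spun_set(items6), params = p, n_reps = 3,
                             seed = 5)
  scored <- score_trials(trials)
  expect_true(all(scored$label == "correct"))
  expect_equal(nrow(scored), 6 * 3 * 6)
})

test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_experiment(3, n_reps = 2, seed = 99)
  b <- simulate_experiment(3, n_reps = 2, seed = 99)
  expect_identical(a, b)
  c <- simulate_experiment(3, n_reps = 2, seed = 100)
  expect_false(identical(a, c))
})

test_that("sessions cycle each list the requested number of times", {
  p <- sim_params()
  one <- simulate_session(make_spun_set(items6), params = p, n_reps = 10,
                          seed = 2)
  expect_equal(dplyr::n_distinct(one$trial_index), 60)

  sets <- list(
    list(set = make_spun_set(items6, set_id = "sp"), n_reps = 40),
    list(set = make_scrambled_set(strsplit("MNOPQR", "")[[1]], set_id = "sc"),
         n_reps = 40)
  )
  two <- simulate_session(sets, params = p, seed = 3)
  expect_equal(dplyr::n_distinct(two$trial_index), 480)
  per_list <- dplyr::count(dplyr::distinct(two, list_id, trial_index), list_id)
  expect_true(all(per_list$n == 40))
  expect_error(simulate_session(list(), params = p), "non-empty")
})

test_that("adjacency learning builds the wrap association in spun sets", {
  p <- sim_params()
  st <- assoc_state(items6)
  spun <- make_spun_set(items6)
  for (rep_i in 1:10) {
    for (l in spun$lists) learn_list(st, l, p$eta)
  }
  # the final base item is followed by the first in 5 of the 6 rotations
  expect_gt(st$C["F", "A"], 0)
  expect_equal(unname(st$C["F", "A"] / sum(st$C["F", ])), 1)
  expect_gt(st$C["A", "B"] / sum(st$C["A", ]), 0.8)
})

test_that("false starts appear at the configured rate and are fast", {
  p <- sim_params(p_false_start = 0.5, p_omit = 0, p_intrude = 0)
  trials <- simulate_session(make_same_set(items6, 6), params = p,
                             n_reps = 30, seed = 8)
  first <- trials[trials$output_position == 1, ]
  # swapped starts produce a non-initial first response on error trials;
  # their RTs sit below the typical second-response scale
  swapped <- first[first$response != substr(first$input_list, 1, 1), ]
  expect_gt(nrow(swapped), 0.2 * nrow(first))
  second <- trials$rt_ms[trials$output_position == 2]
  expect_lt(stats::median(swapped$rt_ms), stats::quantile(second, 0.75))
})

test_that("a fill-in tendency emerges without any chaining cue", {
  p <- sim_params(w_chain = 0)
  trials <- simulate_experiment(40, params = p, n_reps = 6, seed = 71)
  scored <- suppressWarnings(detect_false_starts(score_trials(trials)))
  er <- suppressWarnings(
    error_ratio(postanticipation_lag_crp(scored, "scored"), "group"))
  expect_true(all(er$p_fill_in > er$p_infill))
})

test_that("increasing the chaining weight does not decrease spun infill", {
  rates <- vapply(c(0, 0.6), function(w) {
    p <- sim_params(w_chain = w)
    trials <- simulate_experiment(40, list_types = c("spun"), params = p,
                                  n_reps = 8, seed = 404)
    scored <- suppressWarnings(detect_false_starts(score_trials(trials)))
    pa <- postanticipation_lag_crp(scored, "scored")
    mean(pa$crp[pa$lag == 1], na.rm = TRUE)
  }, numeric(1))
  expect_gte(rates[2], rates[1])
})
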