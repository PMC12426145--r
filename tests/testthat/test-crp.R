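abc <- strsplit("ABCDEF", "")[[1]]

test_that("transition lags follow the worked definitions", {
  expect_equal(transition_lags("ABCDEF", c("A", "B", "D", "C")), c(1, 2, -1))
  expect_equal(transition_lags("ABCDEF", abc), rep(1, 5))
  expect_equal(transition_lags("ABCDEF", c("F", "A")), -5)
  # transitions across an intrusion or omission are voided
  expect_equal(transition_lags("ABCDEF", c("A", "u", "C", "D")), 1)
  expect_length(transition_lags("ABCDEF", c("A")), 0)
})

test_that("overall lag-CRP counts occurrences and opportunities per lag", {
  scored <- score_trials(make_trials("ABCDEF", list(c("A", "B", "D", "C"))))
  tab <- overall_lag_crp(scored, "scored")
  num <- stats::setNames(tab$numerator, tab$lag)
  den <- stats::setNames(tab$denominator, tab$lag)
  expect_equal(unname(num[c("1", "2", "-1")]), c(1, 1, 1))
  expect_equal(sum(num), 3)
  # -1 opportunities: possible after B (prev A has a predecessor? no ->
  # after A nothing precedes), i.e. for prev items B and D only
  expect_equal(unname(den["-1"]), 2)
  # +1 possible after every predecessor here (A, B, D)
  expect_equal(unname(den["1"]), 3)

  all_ok <- score_trials(make_trials("ABCDEF", list(abc)))
  tab2 <- overall_lag_crp(all_ok, "scored")
  defined <- tab2[!is.na(tab2$crp) & tab2$crp > 0, ]
  expect_equal(defined$lag, 1L)
  expect_equal(defined$crp, 1)
})

test_that("overall and postanticipation counts match the brute-force enumerator", {
  # short outputs here; the full length-<=4 enumeration runs in the
  # acceptance suite
  items <- c("A", "B", "C", "D")
  outputs <- all_outputs(items, 3)
  expect_gte(length(outputs), 84)
  for (policy in c("scored", "excluded")) {
    for (i in seq_along(outputs)) {
      out <- outputs[[i]]
      scored <- score_trials(make_trials(items, list(out)))
      got_ov <- crp_counts(overall_lag_crp(scored, policy))
      want_ov <- oracle_overall_counts(items, out, policy)
      expect_equal(unname(got_ov$numerator), unname(want_ov$numerator),
                   info = sprintf("overall/%s: %s", policy,
                                  paste(out, collapse = "")))
      expect_equal(unname(got_ov$denominator), unname(want_ov$denominator),
                   info = sprintf("overall/%s: %s", policy,
                                  paste(out, collapse = "")))
      got_pa <- crp_counts(postanticipation_lag_crp(scored, policy))
      want_pa <- oracle_pa_counts(items, out, policy)
      expect_equal(unname(got_pa$numerator), unname(want_pa$numerator),
                   info = sprintf("pa/%s: %s", policy,
                                  paste(out, collapse = "")))
      expect_equal(unname(got_pa$denominator), unname(want_pa$denominator),
                   info = sprintf("pa/%s: %s", policy,
                                  paste(out, collapse = "")))
    }
  }
})

test_that("postanticipation scoring takes one response relative to the anticipated item", {
  scored <- score_trials(make_trials("ABCDEF", list(c("A", "B", "D", "C"))))
  tab <- postanticipation_lag_crp(scored, "scored")
  den <- stats::setNames(tab$denominator, tab$lag)
  # anticipated item D sits at input position 4: reachable lags -3..+2
  expect_equal(unname(den[as.character(-3:2)]), rep(1, 6))
  expect_equal(sum(den), 6)
  expect_equal(tab$crp[tab$lag == -1], 1)

  # without an eligible anticipation the table is all-missing
  none <- score_trials(make_trials("ABCDEF", list(abc, c("A", "A"))))
  tab2 <- postanticipation_lag_crp(none, "scored")
  expect_true(all(tab2$denominator == 0))
  expect_true(all(is.na(tab2$crp)))
})

test_that("fill-in and infill probabilities are invariant to the repeat policy", {
  set.seed(77)
  symbols <- c(abc, "u", NA)
  n_datasets <- 200
  trials <- dplyr::bind_rows(lapply(seq_len(n_datasets), function(d) {
    outs <- lapply(1:8, function(i) {
      out <- sample(symbols, sample(2:6, 1), replace = TRUE)
      if (any(is.na(out))) out <- out[seq_len(which(is.na(out))[1])]
      out
    })
    make_trials("ABCDEF", outs, participant = sprintf("D%03d", d))
  }))
  scored <- score_trials(trials)
  a <- postanticipation_lag_crp(scored, "scored")
  b <- postanticipation_lag_crp(scored, "excluded")
  pm <- function(tab) tab[tab$lag %in% c(-1, 1),
                          c("participant", "lag", "crp")]
  expect_equal(pm(a), pm(b))
})

test_that("error ratios divide fill-in by infill at the stated level", {
  tab <- tibble::tibble(
    participant = rep(c("P1", "P2"), each = 2),
    experiment = "e1", site = "s1", list_type = "spun",
    mode = "postanticipation", repeat_policy = "scored",
    lag = rep(c(-1L, 1L), 2),
    numerator = c(2, 1, 4, 1), denominator = c(4, 4, 8, 4),
    crp = c(0.5, 0.25, 0.5, 0.25)
  )
  er <- error_ratio(tab, "group")
  expect_equal(er$p_fill_in, 0.5)
  expect_equal(er$p_infill, 0.25)
  expect_equal(er$error_ratio, 2)

  per <- error_ratio(tab, "participant")
  expect_equal(nrow(per), 2)
  expect_equal(per$error_ratio, c(2, 2))

  # zero infill probability leaves the ratio undefined, with a warning
  tab0 <- tab[tab$participant == "P1", ]
  tab0$crp[tab0$lag == 1] <- 0
  expect_warning(er0 <- error_ratio(tab0, "group"), "undefined")
  expect_true(is.na(er0$error_ratio))
})

test_that("position counts attribute fill-ins to the anticipation's output position", {
  scored <- score_trials(make_trials("ABCDEF", list(c("A", "B", "D", "C"))))
  pc <- position_counts(scored)
  expect_equal(pc$fill_in_count[pc$position == 3], 1)
  expect_equal(sum(pc$fill_in_count), 1)
  expect_equal(sum(pc$infill_count), 0)

  # conservation: total fill-in counts equal total -1 postanticipation lags
  trials <- simulate_experiment(5, n_reps = 4, seed = 303)
  sc <- suppressWarnings(detect_false_starts(score_trials(trials)))
  pa <- postanticipation_lag_crp(sc, "scored")
  pc2 <- position_counts(sc)
  expect_equal(sum(pc2$fill_in_count), sum(pa$numerator[pa$lag == -1]))
  expect_equal(sum(pc2$infill_count), sum(pa$numerator[pa$lag == 1]))
})

test_that("group curves average participants with data at each lag", {
  tab <- tibble::tibble(
    participant = c("P1", "P2", "P1", "P2"),
    experiment = "e1", site = "s1", list_type = "spun",
    mode = "postanticipation", repeat_policy = "scored",
    lag = c(-1L, -1L, -5L, -5L),
    numerator = 1, denominator = c(2, 2, 2, 0),
    crp = c(0.4, 0.6, 0.5, NA)
  )
  ag <- aggregate_crp(tab)
  at1 <- ag[ag$lag == -1, ]
  expect_equal(at1$mean_crp, 0.5)
  expect_equal(at1$se_crp, 0.1)
  expect_equal(at1$n, 2)
  # the participant without data at -5 is excluded at -5 only
  at5 <- ag[ag$lag == -5, ]
  expect_equal(at5$n, 1)
  expect_equal(at5$mean_crp, 0.5)

  same <- tab
  same$crp <- 0.4
  ag2 <- aggregate_crp(same)
  expect_true(all(ag2$mean_crp == 0.4))
  expect_true(all(ag2$se_crp == 0))
})
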