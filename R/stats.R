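#' Default-prior (JZS) Bayes factor for a t statistic
#'
#' Computes the two-sided Jeffreys--Zellner--Siow Bayes factor
#' \eqn{BF_{10}} for a one-sample/paired or two-sample t test from the t
#' statistic alone (Rouder et al.'s default-prior test). The alternative
#' places a Cauchy prior with width `scale` on the standardised effect size,
#' equivalently an inverse-gamma(1/2, scale^2/2) mixture over the relative
#' prior variance g; the marginal likelihood ratio is evaluated by adaptive
#' numerical integration of
#' \deqn{BF_{10} = \int_0^\infty (1 + Ng)^{-1/2}
#'   \left(1 + \frac{t^2}{(1 + Ng)\,\nu}\right)^{-(\nu+1)/2}
#'   \left(1 + \frac{t^2}{\nu}\right)^{(\nu+1)/2} \pi(g)\, dg}
#' with effective sample size \eqn{N = n_1} (one sample) or
#' \eqn{n_1 n_2 / (n_1 + n_2)} and \eqn{\nu = n_1 - 1} or
#' \eqn{n_1 + n_2 - 2} degrees of freedom. The integrand is evaluated on the
#' log scale, so very large factors (e.g. 1e40) are handled without
#' overflow.
#'
#' @param t Observed t statistic.
#' @param n1 Sample size (number of pairs for a paired test).
#' @param n2 Second group's size for an independent-samples test, or `NULL`.
#' @param scale Cauchy prior width on the effect size; 0.707
#'   (\eqn{\sqrt{2}/2}, the common "medium" default) unless stated.
#' @return The Bayes factor \eqn{BF_{10} > 0} (values below 1 favour the
#'   null).
#' @export
#' @examples
#' jzs_bf10(2.5, 30)        # paired / one-sample
#' jzs_bf10(2.5, 30, 30)    # independent samples
jzs_bf10 <- function(t, n1, n2 = NULL, scale = 0.707) {
  if (!is.finite(t)) stop("`t` must be finite.", call. = FALSE)
  if (n1 < 2) stop("`n1` must be at least 2.", call. = FALSE)
  if (!is.null(n2) && n2 < 2) stop("`n2` must be at least 2.", call. = FALSE)
  if (scale <= 0) stop("`scale` must be positive.", call. = FALSE)
  if (is.null(n2)) {
    N <- n1
    nu <- n1 - 1
  } else {
    N <- n1 * n2 / (n1 + n2)
    nu <- n1 + n2 - 2
  }
  r2 <- scale^2
  log_igamma <- function(g) {
    # inverse-gamma(1/2, r^2/2) density, log scale
    0.5 * log(r2 / 2) - lgamma(0.5) - 1.5 * log(g) - r2 / (2 * g)
  }
  integrand <- function(g) {
    lf <- -0.5 * log1p(N * g) -
      (nu + 1) / 2 * log1p(t^2 / ((1 + N * g) * nu)) +
      (nu + 1) / 2 * log1p(t^2 / nu) +
      log_igamma(g)
    exp(lf)
  }
  val <- tryCatch(
    stats::integrate(integrand, 0, Inf, rel.tol = 1e-10, abs.tol = 0,
                     subdivisions = 500L),
    error = function(e) e
  )
  if (inherits(val, "error") || val$message != "OK") {
    msg <- if (inherits(val, "error")) conditionMessage(val) else val$message
    stop(sprintf("JZS integration failed (t = %.4g, N = %.4g, nu = %.4g): %s",
                 t, N, nu, msg), call. = FALSE)
  }
  val$value
}

#' t test with Bayes factor on per-participant values
#'
#' Two-sided paired or independent-samples t test in the form used for
#' lag-CRP contrasts: the estimate is the mean difference, its standard error
#' is reported alongside t, df, and p, and a JZS Bayes factor is attached.
#' Participants missing a value are dropped pairwise in paired mode and
#' within group in independent mode (the analysis excludes participants with
#' no data for the analysed lag). Independent tests pool the variance
#' (classical Student t), so a two-group one-way ANOVA satisfies F = t^2.
#'
#' @param a,b Numeric vectors; in paired mode aligned by position
#'   (participant).
#' @param mode `"paired"` or `"independent"`.
#' @param scale Prior width for [jzs_bf10()].
#' @return A one-row tibble: `test_kind`, `estimate`, `se`, `statistic`,
#'   `df`, `p`, `bf10`, `n_used`.
#' @export
t_test_bf <- function(a, b, mode = c("paired", "independent"),
                      scale = 0.707) {
  mode <- match.arg(mode)
  if (mode == "paired") {
    if (length(a) != length(b)) {
      stop("paired mode requires aligned vectors of equal length.",
           call. = FALSE)
    }
    keep <- stats::complete.cases(a, b)
    a <- a[keep]
    b <- b[keep]
    n <- length(a)
    if (n < 2L) stop("insufficient data: fewer than 2 complete pairs.",
                     call. = FALSE)
    d <- a - b
    est <- mean(d)
    sdd <- stats::sd(d)
    if (sdd == 0) {
      # degenerate: all differences identical
      se <- 0
      tt <- if (est == 0) 0 else sign(est) * Inf
      p <- if (est == 0) 1 else 0
    } else {
      se <- sdd / sqrt(n)
      tt <- est / se
      p <- 2 * stats::pt(-abs(tt), df = n - 1)
    }
    bf <- if (is.finite(tt)) jzs_bf10(tt, n, scale = scale) else Inf
    tibble::tibble(test_kind = "paired_t", estimate = est, se = se,
                   statistic = tt, df = n - 1, p = p, bf10 = bf, n_used = n)
  } else {
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    n1 <- length(a)
    n2 <- length(b)
    if (n1 < 2L || n2 < 2L) {
      stop("insufficient data: each group needs at least 2 observations.",
           call. = FALSE)
    }
    ht <- stats::t.test(a, b, var.equal = TRUE)
    tt <- unname(ht$statistic)
    bf <- jzs_bf10(tt, n1, n2, scale = scale)
    tibble::tibble(test_kind = "independent_t",
                   estimate = mean(a) - mean(b), se = unname(ht$stderr),
                   statistic = tt, df = unname(ht$parameter),
                   p = ht$p.value, bf10 = bf, n_used = n1 + n2)
  }
}

#' One-way between-subjects ANOVA
#'
#' Standard fixed-effects F test with `k - 1` between and `N - k` within
#' degrees of freedom, used to check whether a lag-CRP differs across
#' experiments before pooling them. Missing values are dropped; groups left
#' empty are removed with a warning.
#'
#' @param values Numeric outcome.
#' @param groups Group labels, same length as `values`.
#' @return A one-row tibble: `test_kind`, `statistic` (F), `df_between`,
#'   `df_within`, `p`, `n_used`.
#' @export
oneway_anova <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- groups[keep]
  if (!is.factor(groups)) groups <- factor(groups)
  if (any(table(groups) == 0L)) {
    warning("empty groups dropped from the ANOVA.", call. = FALSE)
    groups <- droplevels(groups)
  }
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 non-empty groups.", call. = FALSE)
  if (length(values) < k + 1L) {
    stop("insufficient data for a one-way ANOVA.", call. = FALSE)
  }
  fit <- stats::anova(stats::lm(values ~ groups))
  tibble::tibble(test_kind = "oneway_anova",
                 statistic = fit$`F value`[1L],
                 df_between = fit$Df[1L], df_within = fit$Df[2L],
                 p = fit$`Pr(>F)`[1L], n_used = length(values))
}

#' Run the standard suite of postanticipation lag-CRP contrasts
#'
#' Builds, from a participant-level postanticipation lag-CRP table, the
#' paired contrasts used to characterise the fill-in tendency:
#'
#' * within each list type, crp(-1) vs crp(+1) -- the fill-in tendency test;
#' * for each available pair of list types (same vs spun, spun vs scrambled,
#'   same vs scrambled), the difference at lags +1, -1, and -5 -- infill,
#'   fill-in, and wrap-around transitions.
#'
#' Estimates are first-named minus second-named means; participants lacking a
#' value at an analysed lag are dropped pairwise. Contrasts referencing an
#' absent list type are skipped with a warning.
#'
#' @param pa_table Output of [postanticipation_lag_crp()] (participant
#'   level).
#' @param cross_lags Lags compared across list types.
#' @param scale Prior width for the Bayes factors.
#' @return A tibble with one row per contrast: `contrast`, `list_type_a`,
#'   `lag_a`, `list_type_b`, `lag_b`, and the [t_test_bf()] columns.
#' @export
run_contrast_suite <- function(pa_table, cross_lags = c(1L, -1L, -5L),
                               scale = 0.707) {
  if (!all(pa_table$mode == "postanticipation")) {
    stop("`run_contrast_suite()` expects a postanticipation lag-CRP table.",
         call. = FALSE)
  }
  present <- intersect(c("same", "spun", "scrambled"),
                       unique(pa_table$list_type))
  get_vec <- function(type, lag, participants) {
    rows <- pa_table[pa_table$list_type == type & pa_table$lag == lag, ]
    rows$crp[match(participants, rows$participant)]
  }
  participants <- sort(unique(pa_table$participant))
  rows <- list()
  add <- function(name, ta, la, tb, lb) {
    a <- get_vec(ta, la, participants)
    b <- get_vec(tb, lb, participants)
    res <- tryCatch(t_test_bf(a, b, mode = "paired", scale = scale),
                    error = function(e) {
                      warning(sprintf("contrast '%s' skipped: %s", name,
                                      conditionMessage(e)), call. = FALSE)
                      NULL
                    })
    if (!is.null(res)) {
      rows[[length(rows) + 1L]] <<- dplyr::bind_cols(
        tibble::tibble(contrast = name, list_type_a = ta, lag_a = la,
                       list_type_b = tb, lag_b = lb), res)
    }
  }
  for (type in present) {
    add(sprintf("%s -1 vs %s +1", type, type), type, -1L, type, 1L)
  }
  pairs <- list(c("same", "spun"), c("spun", "scrambled"),
                c("same", "scrambled"))
  for (pr in pairs) {
    if (!all(pr %in% present)) {
      if (any(pr %in% present)) {
        warning(sprintf("contrasts for %s vs %s skipped: list type absent.",
                        pr[1L], pr[2L]), call. = FALSE)
      }
      next
    }
    for (lag in cross_lags) {
      add(sprintf("%s %+d vs %s %+d", pr[1L], lag, pr[2L], lag),
          pr[1L], lag, pr[2L], lag)
    }
  }
  dplyr::bind_rows(rows)
}
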