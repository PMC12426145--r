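---
title: "Scoring fill-in and infill in serial recall: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring fill-in and infill in serial recall: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinfill)
```

## The problem

When people recall a short list in order, they sometimes report an item too
early (an *anticipation*: ABD... to the list ABCDEF). What they do next is
diagnostic of how serial order is represented. Going back to the skipped
item (ABDC, a *fill-in*) is what position-based ("item-independent")
retrieval predicts; pressing on to the next item (ABDE, an *infill*) is what
chaining ("item-dependent") retrieval predicts, because the just-recalled
item cues its trained successor. Serial-recall studies typically find
fill-in about twice as likely as infill.

The designs this package supports manipulate how much chaining can help.
In *same* lists the presentation order never changes; in *spun* lists the
list is rotated on each repetition (ABCDEF, FABCDE, ...), so every item
keeps its neighbours but moves through every position; in *scrambled* lists
a Williams balanced Latin square puts every item once in every position
*and* next to every other item exactly once, so neither positions nor
neighbours are consistent. If chaining contributes to learning, spun lists
should show relatively more infill — and, uniquely, elevated "wrap"
transitions from the final item to the initial item (lag −5 in six-item
lists), because the rotations train exactly that transition.

## Scoring model

Every response of every trial receives exactly one label: *correct*,
*anticipation*, *postponement*, *repeat*, *intrusion*, or *omission*.
One corner case is worth stating: a response can simultaneously satisfy
"matches the input list at its output position" and "was already emitted
earlier in the trial" (an item recalled early and then again in its own
position). The labels must partition, and we resolve the conflict in favour
of *correct*; a separate re-recall flag, independent of the label, drives
the repeat-exclusion policy below. Trailing positions never reached are
counted as omissions in error summaries, but they play no role in
postanticipation eligibility, which requires actually emitted responses.

### Lag-CRP

The lag of a transition is the signed difference between the input
positions of consecutively recalled items. Lag-conditional response
probability (lag-CRP) divides, per lag, the number of occurrences by the
number of opportunities: after an item at input position p, lag L was an
opportunity whenever 1 ≤ p + L ≤ 6. Transitions are defined only between
consecutively emitted list items; an intervening intrusion or omission
voids both adjacent transitions (a conservative reading of "transition from
the previously recalled item"). Overall curves span lags −5..+5;
lag 0 (an immediate re-recall of the previous item) is included in the
opportunity sets because it is reachable, though it is rarely plotted.

The *postanticipation* lag-CRP conditions on error commission: only the
first response after an anticipation is scored, and only when every
response before the anticipation was correct. Lags are taken relative to
the anticipated item's input position and span −5..+4. At −1 the scored
response is a fill-in, at +1 an infill; their ratio
P(fill-in)/P(infill) is the error ratio. If the response following the
anticipation is an intrusion or omission, the trial contributes nothing
(the same voiding rule as above).

Repeat responses can be handled two ways. Under the `scored` policy they
count like any other response. Under the `excluded` policy a re-recall
earns no occurrence, and opportunity counts skip lags whose target item was
already recalled — but the transition itself still contributes
opportunities at non-recalled targets. This matters: because the
pre-anticipation prefix is correct, the −1 and +1 targets of the
anticipated item can never already be recalled, so fill-in and infill
probabilities are provably identical under both policies (a property test
asserts this on 1,000 random datasets). The wrap target at −5, by
contrast, is usually the already-recalled first item, so the policies
diverge exactly where the wrap analysis needs the `scored` policy.

Within a participant and list type, numerators and denominators are summed
over trials before dividing (a ratio of sums); per-trial averaging is not
offered because each participant contributes one curve.

### The false-start screen

First keystrokes are much slower than later ones. A *first-position*
anticipation produced faster than the participant's usual second response
is more plausibly a motor slip (a transposed or premature keystroke) than a
memory error. The screen computes, per participant, the 75th percentile of
all second-response times — using the linear-interpolation percentile
definition, rank 1 + 0.75(n − 1), the default in most scientific software,
since no definition is stated in the literature this implements — and flags
first-position anticipations *strictly* faster than the cutoff ("shorter
than" is read as a strict inequality). Flagged trials lose
postanticipation eligibility. At least 4 second-response times are
required; otherwise no trial is flagged and a warning is raised. A second
motor mechanism (a first keystroke initiated first but completed second)
is described in the literature but has no stated screen, so no additional
filter is applied.

## Inferential machinery

Contrasts on participant-level postanticipation lag-CRPs use two-sided
paired t tests (or pooled-variance independent t tests, so that a
two-group one-way ANOVA satisfies F = t² to numerical precision), with
pairwise deletion of participants lacking data at the analysed lag, and no
multiple-comparison correction. The standard suite tests, per list type,
crp(−1) vs crp(+1), and across each available pair of list types the
differences at +1, −1, and −5 — twelve contrasts when all three list types
are present, five with two.

Each t test carries a Jeffreys–Zellner–Siow Bayes factor computed from the
t statistic alone: a Cauchy prior of width 0.707 on the standardised
effect size, integrated numerically over the inverse-gamma mixing variable
with the integrand evaluated on the log scale (factors of order 1e40 are
routine and must not overflow). The implementation is checked against an
independent quadrature to six decimals, and its monotonicity in |t| is
asserted. The prior width is exposed because published reports rarely
print it; note that published Bayes factors are typically computed from
unrounded t statistics, so recomputation from a t printed to two decimals
can differ in the third significant figure — the test suite therefore also
checks that published values fall inside the interval the printed rounding
allows.

Error-ratio aggregation is an explicit parameter (`participant`,
`experiment`, or `group`) because published tables mix levels: ratios are
always formed from the mean probabilities at the chosen level, and a ratio
with a zero or missing infill probability is reported as missing, never
infinite.

## The generative simulator

No simulator is defined in the serial-learning literature this package
operationalises; the one shipped here exists so that every pipeline stage
has inputs with the assumed statistical structure, and its functional forms
are fixed so tests are reproducible. Recall of each output position k
scores every candidate item i as

activation(i) = e^(−λ_prim (pos_i − 1)) ×
  [ w_pos e^(−λ_pos |pos_i − k|) + w_posmem P̂[k, i] + w_chain Ĉ[prev, i] ] ×
  (1 − s·1{i already recalled})

— a primacy gradient over input position, a positional cue with
exponential generalisation, learned position→item and item→item
(chaining) associations accumulated at rate η per presentation and
row-normalised at retrieval, and response suppression of already-recalled
items. Choice is a Luce rule with temperature τ (τ = 0 is argmax with ties
to the lowest input position, chosen so the noiseless configuration is
exactly deterministic). Omissions terminate the trial; intrusions draw
from a reserved lower-case alphabet disjoint from all list sets. Response
times are log-normal with a slow first response, and a small fraction of
trials transpose their first two responses with a fast first keystroke
resampled from below the median of the second-response distribution —
precisely the artefact the false-start screen is designed to catch (the
screen catches most but not all, as in real data).

The fill-in tendency is emergent, not built in: after an anticipation the
skipped item and the next item are equidistant from the current position,
and the primacy gradient breaks the tie towards the earlier (skipped)
item. Chaining pushes the other way — the anticipated item cues its
trained successor — which is why increasing w_chain raises infill in spun
lists, lowers their error ratio, and (because rotations train the
final→initial transition while suppression only damps it) produces the
elevated −5 wrap transitions unique to spun lists. In same lists the base
list's final item never has a successor, so wrap transitions stay near
zero there, as observed empirically.

### Default parameters

| Parameter | Default | Meaning |
|---|---|---|
| `w_pos` | 1.0 | current-trial positional cue weight |
| `w_posmem` | 0.5 | learned position→item cue weight |
| `w_chain` | 0.2 | learned item→item (chaining) cue weight |
| `lambda_pos` | 1.0 | positional generalisation decay per position |
| `lambda_prim` | 0.3 | primacy-gradient decay per input position |
| `s` | 0.8 | response suppression in [0, 1] |
| `eta` | 0.08 | association learning rate per presentation |
| `temperature` | 0.5 | Luce choice noise |
| `p_omit` | 0.015 | per-response omission probability |
| `p_intrude` | 0.015 | per-response extra-list intrusion probability |
| `rt_first_mu` | log(1100 ms) | log-scale mean of first-response RT |
| `rt_later_mu` | log(420 ms) | log-scale mean of later-response RTs |
| `rt_sigma` | 0.35 | log-scale RT standard deviation |
| `p_false_start` | 0.03 | probability of a transposed, fast first keystroke |
| `n_reps` | 10 | repetitions per list per session |

The defaults were chosen once to put the simulator in the empirically
reported regime for six-letter serial learning — recall accuracy around
0.7–0.9 improving from scrambled to spun to same lists, group fill-in
probabilities near 0.5–0.7 against infill 0.2–0.3 (ratios between about
1.7 and 3.7), and spun-list wrap probabilities near 0.1 against roughly
0.01 for scrambled lists — and are not adjusted per analysis. Ten
repetitions per list mirrors a short practice session; archival-style
schedules with 40 repetitions are available through
`simulate_session()`.

### What the simulator does and does not emulate

It emulates the statistical signatures the scoring pipeline assumes:
anticipation/fill-in/infill/repeat/omission/intrusion responses, a fill-in
tendency in every list type whose magnitude shrinks as chaining support
grows, elevated −5 wraps in spun lists, slow first responses, and
occasional false starts. It does **not** model output interference,
phonological similarity, grouping or rhythm, typing-skill effects,
fatigue, or strategy shifts, and presentation order across sets within a
session is a blocked, cycle-shuffled convenience (the literature does not
specify one). Passing tests on simulated data therefore certify the
*pipeline* — counting, conditioning, screening, inference — not any claim
about cognition; conclusions about real data require the real data.

## Numerical and design choices

* Serial positions and output positions are 1-based throughout; lists are
  validated as permutations of six unique symbols (constructors accept
  other even lengths where the Williams design generalises, but the
  analysis is specified and tested for length 6, plus 4-item lists in the
  brute-force counting tests).
* Spun sets rotate right (the last item moves to the front), matching the
  conventional ABCDEF, FABCDE, ... presentation.
* The scrambled construction is the Williams design for even n (first row
  1, 2, n, 3, n−1, 4, ...; subsequent rows increment mod n). Any square
  with both balance properties is acceptable; the construction is
  deterministic given the item order, and relabeling symbols commutes with
  all three constructors.
* Ties in deterministic choice break towards the lowest input position;
  per-participant random substreams are derived arithmetically from the
  experiment seed so sessions are independent and reproducible.
* The JZS integrand is integrated adaptively on (0, ∞) with relative
  tolerance 1e−10; integration failure is an error, never a silent
  fallback.
* Test problem sizes: the qualitative-signature check simulates 200
  participants; the null-calibration check uses 500 replicates of 16
  participants with two identically generated conditions each; the
  brute-force oracle enumerates all 340 outputs of length ≤ 4 over a
  4-item list; the repeat-policy invariance check uses 1,000 random
  datasets. These sizes were chosen to keep Monte-Carlo error well inside
  the asserted tolerances.

## Known limitations

* The pipeline ingests only the package's CSV dialect; converting
  proprietary formats (spreadsheets, E-Prime logs) is documented as out of
  scope.
* Postanticipation scoring follows the strict first-response-only
  convention; more liberal schemes (scoring several responses after an
  anticipation) are intentionally not offered.
* The error-ratio aggregation parameter reflects genuine ambiguity in how
  published group ratios were formed; when reproducing a published table,
  choose the level explicitly and report it.
* The simulator's associative stores are per-set; cross-set interference
  is not modelled.
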