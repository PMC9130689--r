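---
title: "Configurational analysis of persistently low neighborhood vaccination rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Configurational analysis of persistently low neighborhood vaccination rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geocna)
```

## The problem

Neighborhood COVID-19 vaccination coverage is shaped by social conditions —
education, racial segregation, income concentration, insurance, language,
employment, transit use, crowding — that are strongly collinear and that
plausibly act *in combination* rather than additively. Configurational
comparative methods (CCMs), and coincidence analysis in particular, address
this directly: instead of estimating marginal effects, they search for
Boolean combinations of calibrated conditions that are (quasi-)sufficient
for an outcome across a small set of cases, here ZIP Code Tabulation Areas
(ZCTAs) treated as neighborhoods.

`geocna` implements that workflow end to end for a city of 43 neighborhoods
observed at three monthly time points: multi-value calibration (including
two Index of Concentration at the Extremes measures), a binary
"persistently low vaccination" outcome, exhaustive enumeration of minimally
sufficient conditions, an iterative consistency-threshold search, and
disjunctive model building run separately for the outcome and its negation.

## Calibration

Each raw continuous variable is mapped onto three ordered levels by two
cut-points. Every scheme uses one closure convention:

* level 0 ("low") on `(-Inf, c1]`
* level 1 ("medium") on `(c1, c2]`
* level 2 ("high") on `(c2, Inf)`

Published descriptions of tertile codings are frequently inconsistent about
boundary inclusion ("≤ 20%" here, "> 20 and 40.1%" there, and rate bands
such as "< 1500 / 1501–2000" that leave the interval (1500, 1501)
unassigned). A single total, deterministic partition was preferred over
reproducing each phrasing literally; the low-side-inclusive closure matches
the majority of the source phrasings. Values exactly at a cut therefore
fall to the lower level. The empirical-tertile mode (`calibrate_tertile()`)
instead sends values exactly at the 67th percentile to *high* and at the
33rd to *low*, following the usual "greater than or equal to the 67th
percentile" rule; the asymmetry with the fixed-cut closure is intentional
and only matters for data that sit exactly on a percentile.

The shipped scheme set (`default_schemes()`) carries the nine fixed
cut-point pairs used in the analysis (education 20/40.1; uninsured 6.5/9.7;
limited English 2.2/4.7; transit 21.4/29.5; service employment 7.9/9.8;
overcrowding 1.7/2.4; ICE-Income −0.23/0.07; ICE-BlackNH −0.37/0.47; and
the three monthly vaccination-rate bands 1500/2000, 2500/3400, 3400/4500
per 10,000 residents), plus the observed raw range of each variable, which
the synthetic generator uses for back-filling.

The ICE measures are computed as `(privileged − deprived) / total`, the
standard concentration-at-the-extremes construction, ranging from −1
(extreme concentration of the deprived group) to +1 (extreme concentration
of the privileged group). Inputs may be counts or proportions.

The outcome is binary: a neighborhood is *persistently low* exactly when
its vaccination-rate level is low (0) at all three monthly dates. The three
monthly level columns stay in the case table for audit but are excluded
from the configurational search — they define the outcome and would
trivially "explain" it.

## The configurational engine

A **literal** restricts one factor to a nonempty proper subset of its
levels (`EDU=0`, `ICEBLACK=0|1`); a **configuration** is a conjunction of
literals, at most one per factor. For a configuration `X` and outcome `Y`:

* consistency = |ext(X) ∩ ext(Y)| / |ext(X)| — how reliably `X` is
  followed by `Y`;
* coverage = |ext(X) ∩ ext(Y)| / |ext(Y)| — how much of `Y` it explains.

Both are undefined (an error, not 0 or 1) on empty extensions.

`enumerate_msc()` scans every configuration up to a maximum order (default
3, a one-/two-/three-condition scan) and keeps those that are instantiated,
meet the consistency threshold, and are **minimal**: a configuration is
discarded when some relaxation of it — dropping a literal, or enlarging an
accepted set — already meets the threshold. Minimality over value-set
enlargements keeps redundantly specific rows (e.g. `ICEBLACK=0` when
`ICEBLACK=0|1` suffices) out of the condition table.

`threshold_search()` starts at consistency 1.00 and lowers the threshold in
steps of 0.05 until the condition table holds at least two configurations,
recording the trail of (threshold, row count) pairs.

`build_candidates()` assembles disjunctions of up to five condition-table
rows and retains those whose model-level consistency and coverage meet the
thresholds and that are redundancy-free: no disjunct's extension may sit
inside another's, and removing any disjunct must push coverage below the
coverage threshold. Three implementation decisions matter here:

* Rows with *identical extensions* are interchangeable explanations; the
  search keeps one representative per extension (the first in the
  condition table's canonical order, i.e. lowest complexity then
  lexicographic). The alternatives remain visible in the condition table.
* The subset search is depth-first with sound pruning (a coverage upper
  bound from the overlap-sorted remaining rows; skipping rows that add no
  new outcome case; abandoning branches in which some disjunct's unique
  contribution has already fallen below the redundancy margin).
* On heavily noisy tables the space of irredundant covers grows
  exponentially. Rather than enumerate indefinitely, the search carries a
  node budget (default 20,000) and raises a typed error when exceeded;
  `asymmetric_analysis()` converts that into an explicit "no model —
  search too large" report. A small-N configurational method has no
  business silently producing one of millions of equally defensible
  disjunctions.

`select_final()` ranks candidates by consistency, then coverage, then
complexity (total literal count). A unique top candidate becomes the final
model; an exact tie on all three keys is reported as **model ambiguity**
with the tied set, and no final model is chosen. The tie-break order is a
stipulation of this package — the source workflow states only that models
were assessed "on overall consistency and coverage" — and ambiguity is
surfaced rather than silently broken by any further key.

`asymmetric_analysis()` runs the whole chain twice, once for the outcome
literal and once for its complement, sharing no state: pathways to an
outcome's absence need not mirror the pathways to its presence (causal
asymmetry). After the msc search stops, if model building at the stopping
threshold admits no candidate (every retained configuration can still fail
the coverage threshold), the analysis keeps lowering the threshold —
re-running the msc scan — until a final model or an ambiguous tie emerges.
This mirrors the iterative, analyst-in-the-loop character of the original
workflow while keeping every step deterministic and logged in the trail.

Default model thresholds: consistency tracks the msc stopping threshold;
coverage defaults to 0.75. The source analysis does not print numeric
model thresholds; 0.75 is this package's stipulation (a model explaining
fewer than three quarters of the outcome cases is a weak candidate at
n = 43) and is configurable.

## The benchmark fixture

The full per-ZCTA factor table behind the published analysis lives in an
external repository, so `build_paper_fixture()` reconstructs a
deterministic synthetic 43-case table matched to the printed
cross-classification counts: 13 persistently-low cases; the conjunction
`EDU=0*ICEBLACK=0|1` instantiated by 12 cases, 11 of them positive
(consistency 11/12 = .92, coverage 11/13 = .85).

The printed counts for the negative side (consistency 28/30, coverage
28/29) cannot be satisfied jointly with those: on any 43-case table the
disjunction `EDU=1|2 + ICEBLACK=2` is the exact set complement of the
positive conjunction, so its extension is forced to 31 cases, and 13
positives leave 30 (not 29) non-low cases. The printed numbers are mutually
consistent only at n = 42. The fixture keeps n = 43 and the positive-side
counts; its negative side then scores coverage 29/30 = .97 (matching the
printed two-decimal value) and consistency 29/31 = .94 (one hundredth above
the printed .93). The fixture validates all of these identities at build
time.

The filler structure of the fixture is engineered, not random: the 11
block positives share one profile with the block's single negative
exception, and each positive outside the block shares its full profile
with a group of negatives. This "minimal pair" construction prevents
spurious perfectly consistent configurations from crowding the condition
table, so the discovered models are exactly the two-factor solutions — a
single conjunctive pathway into the outcome, two disjunctive pathways out
of it.

## The synthetic generator

`generate_synthetic()` emulates the study's data shape: 43 cases, 8
three-level social factors with the shipped cut-points and raw ranges, a
planted Boolean rule (default `A=0*B=0|1`, 13 rule cases), an outcome-flip
noise rate (default 0), and three monthly vaccination levels encoding the
outcome. Raw continuous values are back-filled uniformly within each
level's raw interval (half-open intervals sampled with a small inset), so
calibrating the raw table with the returned schemes reproduces the case
table exactly — a property tested at every seed.

Factor levels are not drawn independently. Real neighborhood social
conditions are strongly collinear, so levels come from a shared latent
advantage gradient with per-factor jitter (default 0.25, the probability
that a factor deviates one step from the case's latent tertile).
Independent draws would scatter 43 cases over thousands of distinct level
combinations and fill the condition table with hundreds of
perfectly-consistent one-case configurations — a regime real ACS-style
data never shows and one that makes exhaustive disjunction search
meaningless. The 13 rule cases are the most deprived cases on the latent
gradient, matching the substantive story the generator emulates.

Identifiability of the planted rule is enforced by construction: every
accepted level of each literal is occupied among the rule cases, the most
deprived rule case keeps a fully deprived profile, and for every level
outside each literal's accepted set there is one negative contrast case
deviating from that profile in that literal only. Without these minimal
pairs, a same-complexity variant of the rule (for instance `A=0|2*B=0`
when no case has `A=2, B=0`) can share the rule's extension exactly and
the final model is genuinely ambiguous — a property of the data, not a
defect of the engine, but one the recovery benchmark must exclude.

What the generator does *not* emulate: spatial autocorrelation beyond the
shared gradient, ACS sampling error, missing data, and multi-outcome
causal chains. Passing recovery tests therefore show that the engine finds
planted configurational structure under realistic collinearity and noise;
they do not show that real vaccination data contains such structure.

## Numerical choices and problem sizes

Scores are compared with a tolerance of 1e-9 when thresholds are applied;
displayed values are rounded half-up to two decimals, the reporting
precision of the field. Condition tables and candidate lists are sorted by
(consistency desc, coverage desc, complexity asc, canonical string), which
makes every output deterministic and diffable; two runs with identical
inputs are byte-identical.

The test-suite problem sizes are chosen to exercise every contract at desk
scale: oracle-equivalence over 500 random tables of up to 5 factors and 50
cases against brute-force enumeration; 100 noise-free recovery replicates
and 20 replicates at 10% outcome noise at the study shape (43 × 8); and the
deterministic fixture for the printed-count checks.

## Known limitations

* Crisp (multi-value) calibration only; no fuzzy-set membership.
* Single binary outcome; no causal chains or common-cause structures
  across multiple outcomes.
* The candidate search is exhaustive only up to extension-equivalence and
  its node budget; on noise-dominated tables it reports "no model" rather
  than an arbitrary representative of an exponential family.
* ZCTA join semantics are a single shared identifier string; boundary
  vintage mismatches between rate tables and census variables are the
  user's responsibility.
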