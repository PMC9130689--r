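# geocna

Geoconfigurational coincidence analysis of neighborhood health outcomes in
R: for whom social conditions *combine* — rather than act one at a time —
to produce an outcome such as persistently low COVID-19 vaccination rates.

`geocna` is aimed at health-equity and implementation researchers working
with small-N, case-based geographic data (tens of ZIP Code Tabulation
Areas, counties, clinics). It implements the full configurational
comparative workflow:

* **Multi-value calibration** of raw ACS-style variables into
  low/medium/high levels via fixed cut-points or empirical tertiles,
  including the Index of Concentration at the Extremes,
  ICE = (privileged − deprived) / total ∈ [−1, 1], for income and for
  Black non-Hispanic vs. White non-Hispanic composition, and dual
  (meta-factor) binary calibrations.
* A **persistently-low outcome**: level "low" at every one of three
  monthly observation dates.
* **Minimally sufficient conditions**: exhaustive enumeration of value-set
  configurations X up to order 3, scored by
  consistency = |X ∩ Y| / |X| and coverage = |X ∩ Y| / |Y|,
  keeping only configurations none of whose relaxations already meets the
  consistency threshold, with an iterative threshold-lowering search
  (1.00, 0.95, 0.90, …) until at least two configurations qualify.
* **Model building**: redundancy-free disjunctions of minimally sufficient
  conditions ("multiple pathways", equifinality), ranked by consistency,
  coverage and complexity, with explicit model-ambiguity detection — and
  run **separately for the outcome and its negation** (causal asymmetry).
* A **synthetic-data generator** with a planted Boolean causal rule,
  latent-gradient collinearity, controllable outcome noise and exact
  calibration round-trip, plus a deterministic 43-neighborhood benchmark
  fixture matched to published cross-classification counts.
* CSV / JSON / GeoJSON input and output, including a per-case membership
  layer joinable onto ZCTA boundary files for choropleth mapping.

## Worked example

The package ships a deterministic 43-neighborhood fixture whose
cross-classification matches the published counts. Running the full
asymmetric analysis on it:

```r
library(geocna)

ct <- build_paper_fixture()
reports <- asymmetric_analysis(ct)
writeLines(summarize_run(ct, reports))
```

prints

```
cases: 43
factors: EDU, ICEBLACK, ICEINC, UNINS, LEP, TRANSIT, SERVICE, OVERCROWD
outcome: LOWVAX (present in 13 cases)
[positive outcome: LOWVAX=1]
  threshold 1.00 -> 2 configuration(s)
  threshold 0.95 -> 2 configuration(s)
  threshold 0.90 -> 24 configuration(s)
  final model: EDU=0*ICEBLACK=0|1 (consistency 0.92, coverage 0.85)
  cases covered: 11 of 13
[negative outcome: LOWVAX=0]
  threshold 1.00 -> 11 configuration(s)
  threshold 0.95 -> 9 configuration(s)
  threshold 0.90 -> 9 configuration(s)
  final model: EDU=1|2 + ICEBLACK=2 (consistency 0.94, coverage 0.97)
  cases covered: 29 of 30
```

Reading the models: low college education **and** low/medium concentrated
racial privilege together identify the persistently-low neighborhoods
(11 of the 12 neighborhoods instantiating the conjunction are persistently
low — consistency 11/12 = 0.92 — and it covers 11 of the 13 persistently
low neighborhoods — coverage 11/13 = 0.85). For the *absence* of the
outcome the structure is different: medium/high education **or** high
concentrated racial privilege, each pathway sufficient on its own — causal
asymmetry in action.

The same chain runs end to end from raw data:

```r
gen <- generate_synthetic(synthetic_spec(seed = 1))       # raw CSV-shaped table
res <- geocna_run(gen$raw, geocna_config(schemes = gen$schemes),
                  out_dir = "out/")                       # calibrate + search + models
format(res$reports$positive$final)
#> [1] "A=0*B=0|1"
```

which recovers the planted rule `A=0*B=0|1` with consistency and coverage
1.00, and writes the calibrated case table, both condition tables, both
model reports (JSON), the per-case membership table and a run summary to
`out/`. A thin command-line wrapper with `run`, `calibrate`, `msc`,
`simulate` and `fixture` subcommands is in `inst/cli/geocna.R`.

## Package layout

* `R/calibration.R` — ICE, fixed-cut and tertile calibration, meta-factors,
  the persistent outcome, shipped cut-point schemes
* `R/literals.R`, `R/case_table.R`, `R/metrics.R` — the data model:
  value-set literals, configurations, solution formulas, case tables,
  consistency/coverage
* `R/msc.R` — minimally sufficient conditions and the threshold search
* `R/model.R` — candidate building, selection, ambiguity, asymmetric
  analysis
* `R/synthetic.R`, `R/fixture.R` — the generator and the benchmark fixture
* `R/pipeline.R`, `R/io.R` — one-command runs and CSV/JSON/GeoJSON I/O
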