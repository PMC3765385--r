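# fastview

Street-audit scoring, sampling and reliability analysis for walkability
research.

Researchers studying how neighbourhood environments shape walking need
objective street-level data — pavement quality, crossings, lighting,
maintenance — that mapping databases rarely hold. Street audits collect it,
either on foot or from desk-based street-level imagery, but an audit
instrument is only useful if different auditors (and the same auditor on
different days, and the desk-based mode against the on-site gold standard)
produce the same ratings. `fastview` packages the FASTVIEW audit instrument
and everything needed to run and evaluate such audits:

* **Schema** — the nine-category FASTVIEW rubric (each category holds 1–3
  factors with response levels ordered most positive first) as a
  machine-readable JSON definition, with record validation and polarity
  lookup.
* **Scoring** — the data-reduction rule: within a category, all responses at
  the positive extreme → *good* (2), all at the negative extreme → *poor*
  (0), anything else → *fair* (1); N/A responses are ignored, and a link's
  two road sides combine by a worst-side rule.
* **Sampling** — clip a planar road network to a circular audit buffer
  (default 800 m), segment it into junction-to-junction links constrained to
  50–300 m (long edges split into equal parts), and draw a seeded 25% simple
  random sample.
* **Reliability** — percent observed agreement plus chance-corrected kappa
  for the three classic designs: intra-rater (two occasions, Cohen's
  κ = (p_o − p_e)/(1 − p_e)), inter-rater (m raters, Fleiss' κ), and
  criterion (desk vs on-site, Cohen's κ), with Landis–Koch interpretation
  bands and per-design report tables.
* **Simulation** — a synthetic multi-rater generator (true ratings from a
  prevalence vector, reports through per-rater confusion matrices) whose
  closed-form kappa (`theoretical_kappa()`) makes every statistic testable
  against a known ground truth.

## Worked example

```r
library(fastview)

sch <- fastview_schema()
score_category(
  c("Pavement width (metres)" = ">3",
    "Street furniture placement" = "Aligned to side",
    "Presence of cars parked on the pavement" = "No cars on pavement"),
  "Pavement width and obstructions", sch)
#> [1] 2

study <- simulate_study(sim_config(seed = 7))   # 54 links, 3 raters
reliability_report(study$inter, "inter_rater")
#> Reliability (inter_rater)
#> Category                         % Agreement  K     Interpretation
#> Pavement width and obstructions  79.6         0.67  substantial
#> Pavement surface quality         76.5         0.61  substantial
#> Kerb paving quality              80.2         0.69  substantial
#> Road permeability                86.4         0.79  substantial
#> Way finding and legibility       76.5         0.63  substantial
#> Lighting                         86.4         0.79  substantial
#> Personal security                77.8         0.64  substantial
#> User conflict                    81.5         0.70  substantial
#> Environment quality              79.0         0.59  moderate
#> ------------------------------------------------------------------
#> mean                             80.5         0.68
#> min                              76.5         0.59
#> max                              86.4         0.79
```

Each row is one walkability category: the percentage of links on which the
three simulated auditors agreed (mean over rater pairs) and Fleiss' kappa
with its verbal band. Under the default simulation (0.9 rater accuracy,
prevalence 0.2/0.5/0.3 over poor/fair/good) agreement sits around 80% with
substantial kappas, consistent with the closed-form model value
`theoretical_kappa(c(.2, .5, .3), symmetric_confusion(0.9))` ≈ 0.71 for a
rater pair.

The published per-category scores from the instrument's original field
evaluation ship with the package:

```r
fastview_published_scores() |>
  dplyr::filter(design == "intra_rater") |>
  summarize_reliability()
#> mean_agreement 81.1, min 66.7, max 90.0, mean_kappa 0.42
```

A thin command-line wrapper covers the pipeline
(`inst/cli/fastview.R score | reliability | sample-links | simulate`); see
`?cli_run`.

## Documentation

The methods vignette (`vignettes/street-audit-reliability.Rmd`) describes
the scoring rule, the agreement statistics and their failure modes, the
sampling geometry, the simulation model, and the package's design choices
and limitations.
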