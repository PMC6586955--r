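# lftrack

Linear feature tracking (LFT) analysis of high-frequency GPS bursts.

Animals such as red foxes appear to travel *along* linear landscape
features — roads, forest edges, streams — rather than merely crossing
them. This behavior plays out on a time scale of one to a few minutes,
invisible to conventional GPS schedules. Burst telemetry (here: bursts of
20 fixes at 15 s spacing, 10–20 minutes apart) makes it observable, and
`lftrack` implements the complete statistical pipeline for such data:

* **Preprocessing** — burst segmentation from a position stream,
  post-release exclusion, and a travel filter retaining bursts with
  corrected sinuosity ≤ 0.5 m⁻¹ᐟ² and mean speed ≥ 0.1 m/s.
* **Path selection** — for each burst that encounters a feature buffer
  (exact point-to-polyline distance < 10 m), the observed ("case")
  trajectory from first buffer entry is compared with 10 correlated-
  random-walk ("control") trajectories built from its own step-length and
  turning-angle distributions, via conditional logistic regression
  (burst = stratum, trajectory = robust cluster):
  within stratum *s* with case rows *C*, the likelihood contribution is
  exp(β′Σ_C x) / Σ over equally sized row subsets of exp(β′Σ_S x),
  maximized through its Cox risk-set equivalence and validated against an
  exact subset-enumeration oracle.
* **Event detection** — an LFT event is a maximal run of in-buffer
  positions with ≥ 3 positions, ≥ 35 m of path, and displacement-to-
  distance ratio > 0.5.
* **Time to abandonment** — Kaplan–Meier curves and medians (departure =
  first fix outside the buffer; right-censoring at burst end; unknown
  starts excluded; 45 s floor), percentile bootstrap CIs resampling
  individuals then bursts, and Cox contrasts between feature types
  (individual strata, burst clusters, Breslow ties).
* **Speed during LFT** — linear mixed model on log event speed with
  feature type fixed and burst-in-individual random intercepts (REML).
* **Synthetic data** — a two-state movement simulator (free CRW vs.
  feature tracking with per-type speeds and geometric durations), the
  burst schedule with battery-depletion switch, and Rayleigh GPS error,
  so the whole pipeline is testable end to end without field data.

Positions are expected in a projected planar CRS (meters). Inputs are
plain CSV (positions) and GeoJSON polylines typed `road`, `forest_edge`
or `stream` (features); outputs are CSV tables and JSON model summaries.

## Worked example

Simulate a six-fox, eight-hour deployment under the default study
conditions and run the pipeline:

```r
library(lftrack)

ds  <- simulate_dataset(sim_config(n_individuals = 6,
                                   duration_s = 8 * 3600), seed = 1)
res <- run_lft_pipeline(ds$fixes, ds$features, lft_config())
#> 107 bursts, all retained as travel, 70 with a feature encounter;
#> detected events: 33 road, 38 forest edge, 14 stream (86 "any")

road <- res$records[res$records$ftype == "road", ]
km_median(km_fit(road))
#> [1] 180          # seconds; 18 records, 8 observed departures
set.seed(2)
ci <- hierarchical_bootstrap_ci(road, "median", B = 1000)
c(ci$lower, ci$upper)
#> [1]  60 210      # percentile 95% CI, individuals-then-bursts resampling

cc <- case_control_data(filter_travel_bursts(ds$fixes, lft_config())$fixes,
                        ds$features, lft_config())
fit_conditional_logistic(cc, "in_any")
#>     term coef robust_se    z        p ci_lower ci_upper
#> 1 in_any 1.77     0.139 12.8 2.41e-37      1.5     2.04
```

The positive coefficient (log-odds 1.77, robust SE 0.14) says the
observed paths stay inside feature buffers far more than their CRW
alternatives — the simulator's tracking state, recovered by the analysis.
The median time to abandoning a road is 180 s here; small-sample medians
are wide, as the bootstrap interval shows.

A thin command-line wrapper with `simulate`, `preprocess`, `detect`,
`select`, `tte`, `speed` and `run-all` subcommands is installed at
`inst/cli/lft.R` (see `system.file("cli", "lft.R", package = "lftrack")`).

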