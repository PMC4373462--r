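# copdpersist

Persistence and switching analysis of inhaled COPD medication from
pharmacy dispensing records.

## What this package is for

Whether a COPD patient stays on a long-acting β2-agonist (LABA) inhaler
may depend on the device: single-dose dry-powder inhalers (DPIs) require
loading a capsule per use (Breezhaler, Handihaler), multiple-dose DPIs
hold a reservoir of doses (Diskus, Turbuhaler). Claims and dispensing
databases let this be studied at population scale — if the record of
refills is converted into a defensible persistence outcome.
`copdpersist` implements that conversion and the study design around it,
for pharmacoepidemiologists working with dispensing data:

* **new-user cohort selection** — LABA initiators (salmeterol R03AC12,
  formoterol R03AC13, indacaterol R03AC18) aged ≥ 55, naive to long-acting
  respiratory medication for 2 years, with complete registration and data,
  likely-asthma and dual initiators excluded — with an auditable
  per-filter exclusion flow;
* **the refill-gap persistence engine** — coverage intervals of
  `units dispensed / prescribed daily dose` days per fill, optional
  carry-over of surplus supply, and discontinuation at the theoretical end
  of the last prescription before the first gap exceeding a threshold
  (60 days by default; 30/90-day sensitivity analyses). A patient with no
  gap longer than the threshold in the first year is persistent:

  $$S(t)=\Pr\bigl(\text{no uncovered stretch} > g \text{ days before } t\bigr),\qquad g = 60$$

* **switching classification** — the first long-acting fill in the year
  after discontinuation, classified as restart, within-DPI switch,
  pMDI-LABA switch, LABA/ICS switch, LAMA switch, or permanent
  discontinuation;
* **ATC-proxy covariates** — twelve comorbidities from chronic
  co-medication (≥ 2 fills in year 1, with a cardiovascular hierarchy),
  SABA use, oral corticosteroid courses, dosing regimen, prescriber;
* **statistics** — Fisher exact / Mann-Whitney cohort screening at
  α = 0.05, Kaplan-Meier persistence curves, and univariate/multivariate
  Cox proportional hazards for the device effect (Efron ties, Wald CI);
* **a synthetic dispensing-data generator** with recorded ground truth
  (true discontinuation day, post-gap action, expected exclusion path), so
  the whole pipeline is testable without access to a proprietary claims
  database.

## Worked example

Simulate a dispensing database of 1,000 patients and run the full
analysis:

```r
library(copdpersist)

cfg <- run_config(simulation = simulation_config(n_patients = 1000, seed = 42),
                  seed = 42)
res <- run_pipeline(cfg)

res$exclusion_flow
#>   filter                  n_removed n_remaining
#> 1 laba_initiators                 0        1000
#> 2 underage                       48         952
#> 3 not_naive                       0         952
#> 4 incomplete_registration         0         952
#> 5 asthma_medication             105         847
#> 6 missing_essential_data        194         653
#> 7 dual_initiation               117         536
#> 8 death_within_followup          14         522
#> 9 pmdi_initiation               154         368
```

One thousand simulated LABA initiators shrink to a 368-patient DPI cohort;
each count is the number removed by the first filter that patient failed.
Persistence rises with the permitted gap and with switching allowed:

```r
subset(res$persistence$summaries, device_cohort == "overall")
#>                       scenario   n persistent_pct
#> 1                        gap30 368       22.82609
#> 2                        gap60 368       24.72826
#> 3                        gap90 368       35.32609
#> 4                   gap60_min2 360       25.27778
#> 5 gap60_min2_switching_allowed 360       31.11111
```

Of the non-persistent patients with enough follow-up, 40% restarted their
initial inhaler within a year of the gap and 15% stopped long-acting
therapy for good:

```r
subset(res$switching$fractions, device_cohort == "overall")
#>                    category  n fraction
#> 1           restart_initial 64  0.40000
#> 2         switch_within_dpi  4  0.02500
#> 3       switch_to_pmdi_laba  8  0.05000
#> 4        switch_to_laba_ics 45  0.28125
#> 5            switch_to_lama 15  0.09375
#> 6 permanent_discontinuation 24  0.15000

res$comparison$multivariate
#> Cox device effect (vs single_dose_dpi): HR 0.955 (95% CI 0.677-1.348), p = 0.794
#>   n = 368, events = 277; adjusters: age_years
```

The generator applied no device effect here, and the Cox hazard ratio for
multiple-dose versus single-dose inhalers is compatible with 1, as it
should be. `run_pipeline(cfg, out_dir = "report")` writes the same results
as a CSV/JSON bundle with a manifest; `inst/cli/copd-persist` exposes the
stages (`simulate`, `build-cohort`, `persistence`, `switching`,
`covariates`, `compare`, `run`) as shell subcommands.

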