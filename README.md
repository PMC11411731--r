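# hosplink

Longitudinal record linkage of hospital site cohorts.

Annual registry snapshots of hospital sites (one row per site per year)
carry no persistent identifier: the administrative code — an institution
identification code (IIC) shared by all sites of a hospital association
plus a site code (SC) — changes when associations reorganise or numbering
schemes are replaced, and addresses change through relocations and
geocoding errors. hosplink links such cohorts year over year for
longitudinal studies: which site in year two is the same site as this one
in year one, which sites opened, closed, split or merged?

## Method

For every cross-year pair of records the package computes a total
similarity score, the sum of two sub-scores:

* **code sub-score** ∈ {0, 2, 4}: 4 for an identical IIC–SC combination,
  2 for an identical IIC with a differing SC, 0 otherwise (an `iic_only`
  mode handles years straddling an SC renumbering);
* **location sub-score** ∈ {0, 1, 2, 4}: from the forward and backward
  nearest-neighbour relations of the great-circle distance matrix — 4 for
  an identical address (relocation distance 0), 2 for mutually nearest
  sites at positive distance, 1 for a one-way nearest relation, 0
  otherwise.

Totals lie in {0, 1, 2, 3, 4, 5, 6, 8}; 8 means no change in either key
variable. Linkages are accepted one-or-none per facility, greedily by
descending score above a tolerance threshold; tied top scores go to a
manual review queue, and accepted links crossing a municipality boundary
are discarded. Accepted links with total 8 mark *constant* facilities,
lower totals *changed* ones; unmatched records are *openings*/*closures*,
with division/merge flags from pre-selection candidate multiplicity.
Pairwise link sets chain into a multi-year panel with stable identifiers,
and linkage quality is scored against gold-standard pairs as true / false
/ missed matches next to a code-only baseline. A seeded synthetic panel
generator with registry-like event rates provides ground-truthed test
data.

## Worked example

```r
library(hosplink)

# a two-year synthetic panel: 500 sites, 5% SC churn plus default rates
panel <- generate_panel(simulation_config(n_facilities = 500, n_years = 2,
                                          p_sc_change = 0.05, seed = 7))
run <- link_cohorts(panel$cohorts[["2016"]], panel$cohorts[["2017"]])
run
#> <link_run> 2016 -> 2017
#>   cohort sizes: 500 / 497 ; similarity pairs: 508
#>   accepted: 496 ; queued pairs: 0 ; cross-city rejected: 0
#>   continuity: constant 928 | changed 64 | opened 1 | closed 4

score_against_gold(run$links, panel$gold[["2016-2017"]])
#> <evaluation_report> reference pairs: 496
#>   true matches:   496 (100.0%)
#>   false matches:  0 (0.0%)
#>   missed matches: 0 (0.0%)

base <- baseline_code_linker(panel$cohorts[["2016"]], panel$cohorts[["2017"]])
score_against_gold(base, panel$gold[["2016-2017"]])
#> <evaluation_report> reference pairs: 496
#>   true matches:   468 (94.4%)
#>   false matches:  0 (0.0%)
#>   missed matches: 28 (5.6%)
```

Of 500 first-year sites, 497 remain (4 closed, 1 opened); the full method
recovers all 496 true links — the 64 *changed* continuity entries are the
facilities whose SC or location moved but whose score still identified
them — while linking on codes alone misses the 28 sites whose codes
churned.

A command-line front end wraps the same functions
(`inst/cli/hosplink.R`, subcommands `simulate`, `link`, `evaluate`,
`profile`; see `--help`-style comments in the script header), and cohort
CSVs with arbitrary column names are ingested via the `schema` argument of
`read_cohort()`. The methods vignette
(`vignettes/hospital-linkage.Rmd`) documents the model, parameter
defaults and design decisions.

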