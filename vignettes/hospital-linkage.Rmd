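---
title: "Linking hospital sites across years: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking hospital sites across years: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hosplink)
```

## The problem

Annual registry snapshots of hospital sites carry no persistent
facility identifier. A site is described each year by an institution
identification code (IIC, the remuneration-entity code, shared by all sites
of a hospital association), a site code (SC, distinguishing sites within an
association) and its address. Both codes change for administrative reasons
— associations reorganise, SC numbering schemes get replaced wholesale —
and addresses change through relocations and geocoding errors. Following
one site through a series of annual cohorts therefore requires linking
records across years under uncertainty about which variables moved.

hosplink implements a similarity-matrix linker over the two variables that
profiling shows to be simultaneously highly distinctive and highly stable:
the administrative code and the geocoded location. Everything else (name,
ownership, beds) is carried along for reporting but deliberately excluded
from scoring; redundant key variables add computation without adding
discrimination.

## The score

For every year-one record $A$ and year-two record $B$ the total score is
the sum of two sub-scores.

**Code sub-score** $\in \{0, 2, 4\}$: 4 if IIC and SC both match, 2 if
only the IIC matches, 0 otherwise. Under `sc_mode = "iic_only"` (for year
pairs straddling an SC renumbering) the SC is ignored and an IIC match
alone scores 4. A missing SC counts as a non-match: absence cannot confirm
site identity, and treating it as a match would silently inflate scores
exactly in the years where codes are least reliable.

**Location sub-score** $\in \{0, 1, 2, 4\}$: built from the forward
(year-one to year-two) and backward nearest-neighbour relations of the
great-circle distance matrix. The pair earns a forward component of 2 when
$B$ is $A$'s nearest year-two record at distance zero, 1 when nearest at
positive distance, 0 otherwise; the backward component is symmetric. Tied
minimal distances score all tied candidates identically. Because a
zero-distance pair is automatically nearest in both directions, the
components sum to 4, 2, 1 or 0 — never 3 — and the total score lattice is
$\{0, 1, 2, 3, 4, 5, 6, 8\}$ with 8 (no change in either key variable) the
maximum and 7 unattainable. These closure properties are enforced by
property-based tests.

Only rank order and exact zeros of the distances matter, which drives two
numerical choices:

* distances are spherical (haversine, radius 6371 km); ellipsoidal
  refinement would change no rank at these scales;
* distances at or below `zero_distance_epsilon_m` (default 10 m) are
  snapped to exactly zero, absorbing geocoder jitter while keeping distinct
  buildings distinct. The registry's relocation-equals-zero notion is not
  formally defined for coordinates, so this epsilon is our
  operationalisation; 10 m is well below the typical distance between
  neighbouring buildings and well above double-precision noise.
* argmin sets use a 1 nanometre-scale tolerance (1e-9 km) so analytically
  tied distances are not split by floating-point rounding.

## Decisions

Per facility and year the linker accepts at most one linkage ("one or
none"). Candidates at or above `tolerance_threshold` are taken greedily in
deterministic order — total descending, distance ascending, then
lexicographic ids. The default threshold of 1 admits any positive score,
matching the observed practice of accepting links down to a lone one-way
nearest-neighbour relation; raising it trades missed matches for fewer
false ones, and the trade is monotone (a tested invariant).

When a facility's best *still-available* candidates tie on the total, the
whole connected group of tied pairs goes to a review queue and those
facilities stay provisionally unlinked. We deliberately refuse to
auto-resolve ties: the reference workflow resolves them manually against
external sources, and `resolve_review()` merges the analyst's choices back.
A tie that disappears because a competitor was already matched at a higher
score is not queued.

An accepted linkage whose endpoints lie in different municipalities
(case-folded, punctuation-stripped comparison) is discarded afterwards.
The filter runs once, post-selection, and freed partners are not
re-matched: re-matching is not part of the described workflow, and a
single deterministic pass keeps runs reproducible. A missing municipality
keeps the pair with a warning, since the filter cannot be evaluated.

Continuity typing follows from the final matching: an accepted pair with
total 8 is a *constant* facility (type 1), below 8 *changed* (type 2); an
unmatched year-two facility is *newly opened* (type 3), an unmatched
year-one facility *closed* (type 4). Divisions and mergers are not extra
types of a one-to-one matching — a division is one changed plus one opened
site — so they are reported as flags derived from pre-selection candidate
multiplicity, and their interpretation is left to the analyst.

Chains across more than two years are the connected components of the
accepted-linkage graph, which for a partial matching are simple paths;
identifiers are `"<first year>:<first record id>"`, so extending a panel
never renames existing chains. Gaps are not bridged: a facility absent one
year and back the next gets a new identifier, because bridging would
silently contradict the opening/closure accounting.

## Evaluation

`score_against_gold()` counts true matches (accepted ∩ reference), false
matches (accepted ∖ reference) and missed matches (reference ∖ accepted);
true + missed equals the reference total by construction, and the success
rate is true/total. The baseline comparator, `baseline_code_linker()`,
links identical codes only — the natural "just use the identifier"
approach — and leaves duplicated codes unlinked as ambiguous.
`profile_variable()` reproduces the distinction / value-stability counts
used to justify the choice of key variables.

## The synthetic generator

Real registry extracts are access-restricted, so `generate_panel()`
produces panels with known ground truth. Municipalities are Gaussian
clusters (default scale 2 km) scattered over a 47–55°N, 6–15°E patch;
only rank-order distances matter, so spatial realism beyond clustering
would add nothing. Each transition applies exactly one event per facility.
Default rates — 2% SC change, 0.9% IIC change, 0.6% relocation, 0.5%
closure, 0.5% openings, remainder constant — sit inside the ranges
reported for the German hospital registry (roughly 93–98% unchanged pairs,
1–6% SC-only changes, 0.7–1.1% IIC changes, 0.4–0.8% relocations, 0.1–1.2%
openings/closures per year). Options reproduce the two stresses that make
code-only linkage fail in practice: a wholesale SC renumbering year
(`sc_regime_switch_year`) and single-year address errors
(`perturb_addresses()`, displacements of 0.1–1 km, far above the zero
epsilon). Splits and mergers are off by default (they are rare, order
0.1–0.2%) but supported.

What the generator does *not* emulate: compound events (a facility both
relocating and changing codes in one transition, unless splits are
enabled), cross-municipality relocations, clerical errors that persist
across years, and any clinical content. Passing tests on synthetic panels
therefore demonstrate the mechanics of the method — score taxonomy,
decision logic, accounting identities — not its error rate on real data.

## Problem sizes and determinism

The shipped tests run the score-lattice property over ≥1,000 random cross
pairs, compare nearest-neighbour and selection results against brute-force
oracles on 100 random instances up to 20×20, verify perfect recovery on an
all-constant 1,000-site five-year panel, and verify that the full method
strictly beats the code-only baseline (with nonzero baseline misses) on a
1,000-site panel with the churn rates above. These sizes exercise every
code path at comfortable desk scale; the implementation itself holds dense
distance matrices up to a few thousand sites per year, which covers
national hospital registries.

All randomness flows through explicit seeds (`simulation_config(seed = )`,
CLI `--seed`); identical inputs and configuration yield byte-identical
outputs, and every CLI run echoes its configuration into the run report so
it can be reproduced from the report alone.

## Known limitations

* Greedy selection does not globally maximise the score sum; on random
  instances it coincides with the exhaustive optimum in the large majority
  of cases and never exceeds it, and discrepancies are confined to
  low-score conflict clusters that the review queue surfaces anyway.
* The municipality filter depends on consistent municipality strings;
  boundary reforms or spelling drift across years will cause false
  rejections (the filter can be disabled).
* Facilities missing coordinates can only link through codes, and a pair
  of facilities that swap addresses within one municipality in the same
  year is indistinguishable from a double relocation.
* Review-queue resolutions re-enter the pipeline verbatim; the package
  never second-guesses them.
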