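---
title: "Auditing taxonomic certainty in ivy occurrence databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing taxonomic certainty in ivy occurrence databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivyaudit)
```

## The problem

Occurrence databases carry three distinct sources of taxonomic
uncertainty: heterogeneous names, heterogeneous species concepts (the same
name used for different delimitations), and plain identification error.
Name harmonization tools address the first; the second and third require
knowledge of the group's nomenclatural history and, in the worst case,
access to the specimen. Western European ivies (*Hedera*) are a stress
test: six species whose diagnosis rests on microscopic leaf trichomes, a
two-century history of the epithet *canariensis* being applied to ivies
from the Canary Islands, Madeira, the Azores and southwestern Iberia
alike, and a persistent folk belief that all mainland European ivy is
*H. helix*.

`ivyaudit` operationalizes an audit of this uncertainty. Its input is a
table of records that each carry a verbatim *original* determination and a
*revised* determination produced by a reference taxonomist re-examining
the specimen. The package never re-identifies anything: the revised name
is data, and the audit quantifies how the original names relate to it.

## The classification model

After the circularity filter (records determined by the reference
taxonomists themselves are removed — the reference cannot audit itself),
each record is classified in a fixed decision order:

1. the original name does not reach species rank (empty, `Hedera`,
   `Hedera sp.`) → **not identified**;
2. the (original, revised) pair is catalogued in the concept-rule table →
   the catalogued category: **correct**, **misidentification**, **soft
   taxonomic change** (synonym, rank change, merge, or a split producing
   allopatric taxa — all resolvable by standard nomenclatural validation)
   or **hard taxonomic change** (a split with no spatial segregation, or
   with nomenclatural confusion — not resolvable without the specimen);
3. an uncatalogued pair whose names agree rank-free (including the autonym
   infraspecific, e.g. `H. maroccana var. maroccana` against
   *H. maroccana*) → correct;
4. anything else → **unresolvable**: reported, logged, and excluded from
   every denominator.

Two representation choices matter. First, infraspecific *ranks* are
collapsed in all matching keys: herbarium labels use var./subsp./f.
interchangeably for the same legacy concepts, so `H. helix var.
canariensis` and `H. helix subsp. canariensis` are one row and one rule.
Second, the rule table is a data file, not code. The same original name
legitimately falls in different categories against different revised
species — `H. canariensis` against *H. maderensis* is a hard change
(the epithet was historically applied to Madeiran plants), while
`H. canariensis` against *H. azorica* is a plain misidentification — and
such assignments depend on nomenclatural history that code should not
hard-wire.

For the packaged ivy rule table, a handful of assignments in the
*H. helix* column are not uniquely determined by the published per-species
marginals. We fixed them as: `H. hibernica` → *helix* (9 records),
`var. sarniensis` → *helix* (1) and `H. colchica` → *helix* (2, a distinct
extant species) are misidentifications; every other legacy name resolving
to *H. helix* (algeriensis, caucasica, taurica, the old varieties
including the autonym `var. helix`) is a soft change. This reproduces the
published misidentification/soft split (12/50) and is flagged in the rule
table's notes as the one reconstruction a future maintainer should review
against the original supplementary catalogue.

One published inconsistency is resolved in favour of the tables: the
*H. azorica* row is stated with an ambiguous ratio, but the classification
matrix column sums to 40 and the printed percentages (35/65/48/15/0/3) are
jointly consistent only with 14 correct : 26 incorrect and 19
misidentifications; the audit adopts that reconstruction. Similarly, the
running text gives *H. iberica* 13 soft changes where the matrix cell and
the percentage force 1; the matrix wins.

## Statistics

**Chi-squared goodness of fit.** Correct vs incorrect counts per group are
tested against equal expected frequencies: `chi2 = (a-b)^2/(a+b)`, 1 df,
no continuity correction, p from the upper tail. Codes: `****` ≤ 1e-4,
`***` ≤ 1e-3, `**` ≤ 0.01, `*` ≤ 0.05, `m.s.` ≤ 0.08, `n.s.` otherwise.
No multiple-testing correction is applied across groups. Two numerical
choices are deliberate:

* *No Yates correction.* The plain statistic reproduces every published
  significance code except one: *H. maderensis* at 5:17 gives p ≈ 0.0105,
  one notch weaker (`*`) than the published `**`. No standard variant
  (plain, Yates, exact binomial) lands at ≤ 0.01 for 5:17, so we report
  the computed code and record the mismatch rather than tuning the test
  per row. The published text also calls the overall 538:473 imbalance
  non-significant while coding it `*`; we report the computed p = 0.041
  and code `*`.
* *Percentages round half-up* to integers (121/222 = 54.5 → 55,
  19/40 = 47.5 → 48), matching the published table where banker's
  rounding would not.

**Binomial GLM.** The per-record error indicator (incorrect = any of the
four error categories) is regressed on species (categorical; reference =
alphabetically first level, *H. azorica* in the packaged world) and on the
number of congeners sharing range boundaries in the record's region
(numeric 1–3). Fitting is delegated to `stats::glm`; the package's
contract is the family/link/design matrix, not the optimizer.
Quasi-complete separation is flagged (non-convergence or |estimate| > 15)
with estimates still returned.

## Geographic curation

Regions are scored by their native congener count: 3 in mainland Spain, 2
in mainland Portugal, France, the United Kingdom and Ireland, 1 elsewhere
and on each Macaronesian archipelago; one species = low expected
uncertainty. The island group takes precedence over the country so that
Macaronesian records score as their archipelago; unlisted regions default
to one species with a warning (the rest-of-countries rule).

Online records pass only from low-uncertainty regions — there a
name-level validation suffices, since the only uncertainty is outdated
nomenclature. Thinning enforces a minimum inter-record great-circle
distance per species: greedy sequential scan in a deterministic order
(reviewed records first, then record id), retaining a record iff it is at
least one buffer away from every retained conspecific. Buffers: 10 km
continental, 1 km island. Design choices: greedy with a fixed ordering
(the source procedure names no algorithm; reviewed-first privileges
higher-quality records and makes outputs byte-reproducible); haversine on
a sphere of radius 6 371 008.8 m (the ≤ 0.5% sphere error is irrelevant
against 1–10 km buffers); island vs continental decided by the
`island_group` field, not point-in-polygon tests, because the buffers are
stated per archipelago; thinning applied per species, never across
species, so genuine co-occurrences survive. The merge keeps every
coordinate-bearing reviewed record untouched (that database was already
curated and buffered upstream), and resolves exact cross-source
duplicates (same species, distance zero) in favour of the reviewed
record.

## The synthetic world

The generator states the world the audit assumes. Per region, true
species are drawn uniformly from the regional pool; the verbatim original
name is drawn from the true species' *name model* — a distribution over
emitted names, each tagged with the truth category it represents;
coordinates are uniform in the region's bounding box; the revised species
equals the true species (a database fully re-determined by the reference
taxonomist). Every record carries its sampled truth label, and by
construction the classifier must agree with truth *exactly* (not
statistically) whenever the emitted name is catalogued — a property the
tests assert record by record.

`real_structure_config()` instantiates the audited ivy world: the six
species, the packaged region table, and name models equal to the
empirical column distributions of the packaged classification matrix
(e.g. the *H. hibernica* model emits `Hedera helix` with probability
103/222). Defaults chosen once:

* `n_per_species = 2000`, split across nine regions (bounding boxes are
  coarse rectangles over Iberia, France, the UK, Ireland, Germany and the
  three archipelagos — spatial realism is irrelevant to the audit
  statistics; only thinning needs points).
* `uncertainty_effect = 0.9`: the per-record total error mass is tilted
  on the log-odds scale by 0.9 per congener beyond the first in the
  record's region, relative weights within the error mass preserved. The
  audited world shows 29% error in low-uncertainty and 62% in
  high-uncertainty regions, a log-odds gap of ≈ 1.39 across a 1 → 2-or-3
  species step (≈ 1.5 species on average), i.e. ≈ 0.9 per species. With
  the effect at its default the GLM benchmark recovers positive signs for
  *H. hibernica*, *H. iberica* and the species-count covariate and a
  negative sign for *H. helix*; with `uncertainty_effect = 0` the
  covariate has nothing to estimate (name models are then per-species
  everywhere), which is the configuration the null-calibration test
  uses.
* Blocked-identifier injection defaults to 0 and is switched on only in
  circularity-filter tests.

What a green synthetic test does **not** establish: realistic spatial
clustering (points are uniform), abundance structure (uniform within
pools), collector-specific biases, or any feedback of misidentification
over time. The generator validates the machinery and the statistical
contracts, not ivy ecology.

## Known limitations

* The packaged rule table is a reconstruction constrained by the
  published marginal tables; the *H. helix*-column assignments noted
  above are the least-determined entries.
* The two published region-split counts (321:128 and 213:343) cannot be
  recomputed desk-side because the record-level region assignments live
  only in the deposited database; the package reproduces their
  significance codes from the printed counts and everything else from
  the matrix.
* Coordinates are validated and passed through, never georeferenced; no
  datum transformations are attempted (inputs are taken as WGS84 decimal
  degrees).
* `unresolvable` records (names absent from the rule table) are excluded
  from all denominators and surfaced in logs; the packaged fixture
  contains none, so the published numbers are unaffected by this policy.
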