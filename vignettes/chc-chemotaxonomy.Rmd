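---
title: "Cuticular hydrocarbon chemotaxonomy: models, conventions and design notes"
author: "chctax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cuticular hydrocarbon chemotaxonomy: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chctax)
```

Insect cuticular hydrocarbons (CHCs) -- n-alkanes, monoenes and
methyl-branched alkanes with 20--40 carbons -- are stable, heritable surface
lipids whose relative composition differs among species and, more finely,
among geographic populations. `chctax` implements the complete desk side of
a CHC chemotaxonomy study: identifying components from GC--MS evidence,
summarizing and contrasting population profiles, and condensing mean
profiles into ordinal character matrices whose UPGMA trees can be compared
with trees from independent genetic markers. The bundled reference data
describe the elytral CHCs of the Asian larch bark beetle *Ips subelongatus*
from six sites in northeastern China (30 components, C24--C31).

This vignette records the models, unit conventions, default parameters and
the design decisions taken where the procedure was genuinely open.

## Compound model and nomenclature

A component is one of four classes: n-alkane, alkene (monoenes only),
monomethyl- or dimethyl-branched alkane. The shorthand grammar is
`n-C25`, `7-C25:1`, `3-meC25`, `9,13-dimeC29`, with `X` for an unknown
branch position (`5,X-dimeC29`). Two storage conventions matter:

* **Double-bond positions keep the nearer-terminus numbering** of the
  field's names ("7-pentacosene"), with no canonicalization to IUPAC
  lowest locants from the far end. The DMDS arithmetic below consumes the
  stored position directly, so renumbering would silently break the
  fragment identities.
* **Unknown branch positions stay unknown.** `X` parses to `NA` and all
  mass rules refuse such compounds rather than impute a position; the
  catalog's recorded ions stand in for a prediction when a peak must still
  be matched.

One catalog entry (peak 25) was reported under two different double-bond
positions in different parts of the source data; the catalog keeps the
retention-listing identification (`7-C31:1`) and carries the alternative
(`9-C31:1`) in an `alt_label` column so the conflict is visible rather
than silently resolved.

## Nominal-mass fragment rules

All masses are nominal integers (CH~2~ = 14, H = 1, SCH~3~ = 47): printed
diagnostic ions in CHC work are nominal, so isotopes and mass defects are
deliberately out of scope. Molecular ions are `14C + 2` (saturated) and
`14C` (monoene), with `C` the total carbon count including branch methyls.

Electron impact cleaves preferentially at the C--C bonds flanking a methyl
branch. For each flanking bond both charged fragments are emitted, each in
an even (`14m`) and odd (`14m + 1`) mass variant, where `m` counts the
carbons of the fragment including any branch methyls it retains. Published
tables mix the two variants (for example 168/252 beside 112/309), so
matching is subset-based, never exact-set. Methyl loss (M-15) is always
emitted; ethyl loss (M-29) only for 3-methyl compounds, where it is the
characteristic high-mass ion. The low-mass alkene series (83, 97, 111) is
a fixed class signature: these homologous ions carry no positional
information and are attached to every monoene rather than predicted per
compound.

The test suite checks this closed-form rule against an independent oracle
that builds the explicit carbon skeleton, enumerates every C--C bond
cleavage and sums atomic masses. Two recorded ions in the bundled catalog
are *not* producible by any single-bond cleavage of the named isomer: 436
for `7-meC31` (one mass unit above the predicted methyl loss at 435, and
exactly the value obtained if M-15 is computed from the chain carbons
while forgetting the branch carbon) and 126/168 for `5,17-dimeC31`
(consistent with co-eluting positional isomers such as 7,11- or
5,19-dimeC31, a common situation in late dimethylalkane peaks). They are
retained verbatim as recorded identification evidence, and the tests that
compare recorded against predicted ions flag exactly these two rows.

DMDS derivatization adds two thiomethyl groups across a double bond
(+94). Cleavage between the derivatized carbons gives the fragment pair
`14d + 47` and its complement against the adduct `14n + 94`:

```{r dmds}
dmds_fragments(25, 7)
locate_double_bond(27, c(173, 299, 472))
```

Inversion scans d = 2 .. floor(n/2) (near-terminus numbering); a
candidate matching both fragments outranks one matching a single
fragment, and any residual tie is an explicit ambiguity error.

## Retention indices

Indices are computed by *linear* interpolation between bracketing ladder
alkanes (the van den Dool--Kratz convention for temperature-programmed
runs), not the logarithmic isothermal formula, although the field
habitually says "Kovats indices" for both: the linear form reproduces the
bundled reference indices (2572, 2657, 2750, ...) exactly, the
logarithmic one does not. Values are rounded half-up because reference
indices are printed as integers.

```{r ki}
ladder <- build_ladder(chc_catalog())
retention_index(c(35.21, 36.27, 37.39), ladder)
```

Two further conventions:

* **The in-sample ladder is the default.** The six identified n-alkanes
  (C25--C30) anchor the scale; whether the original measurements used the
  in-run alkanes or an external standard run is not recorded, and the
  in-sample ladder reproduces every printed index to within one unit.
* **Extrapolation is opt-in.** Peaks eluting outside the ladder span
  (before C25 or after C30 here) error by default; with
  `extrapolate = TRUE` the terminal ladder interval's slope is extended.
  The bundled catalog needs this for the earliest peak and the six peaks
  beyond C30, and the terminal-slope extension reproduces all of their
  printed indices to <= 1 unit. Ladder gaps (a C20/C25/C30 standard mix)
  are interpolated across the spanning interval.

## Profiles, summaries and contrasts

Relative abundances are simple area normalization: `100 * area / sum(area)`
per individual. "nd" (not detected) is stored as an exact zero with a
`detected = FALSE` flag -- absence is information, not missingness -- and
propagates as 0 into distances and as code 0 into character matrices.
Percentage-only input is accepted and renormalized to 100.

Sex contrasts use Student's two-sample t (equal variances) by default to
mirror routine practice in this literature; Welch is available via
`var_equal = FALSE`. Multi-group contrasts are one-way ANOVA followed by
the Student--Newman--Keuls stepwise range procedure at alpha = 0.05,
implemented on studentized-range critical values (`qtukey`), with the
Tukey--Kramer standard error for unequal group sizes and the containment
rule (a non-significant range closes all its sub-ranges). Letters are
assigned on means ordered by value, so they are invariant under group
relabeling. One degenerate corner is resolved explicitly: zero residual
variance with equal means returns a single shared letter (the trivially
homogeneous case), while zero residual variance with unequal means is an
error, since range statistics are undefined there.

## Distances, ordination, PERMANOVA

Bray--Curtis dissimilarity (`sum|a-b| / sum(a+b)`) is computed by
`vegan::vegdist`. Individual-level analyses (NMDS, PERMANOVA, heatmap
clustering) use relative percentages; taxon-level trees use the ordinal
codes -- that is the stated construction of the character matrix, and a
flag allows percentage input instead.

NMDS wraps `vegan::monoMDS` (global model, Kruskal stress-1 in [0, 1]),
taking the best of 20 random starts plus a metric-scaling start, all
under a recorded seed. PERMANOVA is authored in-package in Anderson's
one-way formulation computed directly from the distance matrix
(`SS_total = sum d^2 / n` over pairs, within-group analogues per group),
with free permutation of raw labels, 999 permutations by default and
`p = (b + 1) / (n_perm + 1)`; results are bit-reproducible given the
seed, and the implementation is cross-checked against `vegan::adonis2`
in the tests (F and R^2 agree to 1e-10). One caveat worth recording:
when all pairwise distances are equal, the decomposition still allocates
among-group sum of squares (R^2 = 0.2 for a 3/3 split of six items, in
both this implementation and `adonis2`); the correct "no structure"
signature there is F = 1 with permutation p = 1.

## Ordinal coding and trees

Mean percentages are coded 0 (nd), 1 (< 0.5), 2 (0.5--1), 3 (1--5),
4 (> 5). The stated bins leave the boundaries 0.5, 1 and 5 ambiguous; the
package fixes `[0.5, 1) -> 2`, `[1, 5] -> 3`, `(5, Inf) -> 4`, a
convention that keeps every bundled printed mean unambiguous under its
displayed rounding, and `bounds` overrides it.

UPGMA is authored in-package as the classic size-weighted
agglomeration: merge the closest pair, average distances weighted by
cluster size, node height = half the merge distance (ultrametric by
construction). Ties at the minimum distance merge the lexicographically
smallest label pair, so trees are fully deterministic. The result is an
`hclust`-compatible object, so `cutree`, plotting and `ape::as.phylo`
apply; `stats::hclust(method = "average")` serves as an independent
cross-check in the tests.

Newick serialization is canonical -- children ordered by smallest
descendant label, `%.12g` branch lengths -- so write/read/write round
trips are byte-identical. Tree comparison is the Robinson--Foulds count
of bipartitions present in exactly one tree (trees read as unrooted,
root-duplicated splits deduplicated), normalized by the total split
count; it is validated against a quartet-based brute-force oracle and
`phangorn::RF.dist`.

On the bundled six-population data both routes to a tree -- ordinal codes
of the reference means, and centroids of simulated individuals -- join
GHIM with YCHL first and place the remaining four populations in the
other limb, the two-cluster structure the profile differences suggest
(high branched-alkane, low n-alkane in GHIM/YCHL).

## The synthetic-data generator

The simulator exists so that every downstream stage is testable at
individual level even though the bundled reference data are means +- SE:
it draws per-individual compositions whose population-level means and
standard errors match the configured ones.

* **Model: logistic-normal, not Dirichlet.** Compositions are
  `softmax(log(mean) + sigma * eps)` with independent Gaussian `eps`.
  A single Dirichlet concentration cannot reproduce the bundled SEs,
  which vary per component far from proportionally; per-component
  perturbation scales can.
* **Calibration.** Each component's sigma is bisected (30 iterations, two
  coordinate sweeps) against a common-random-number Monte Carlo estimate
  (400 draws) of the realized individual-level sd, targeting
  `se * sqrt(n)`; the delta-method value `sd / (p(1-p))` seeds the
  bracket. The procedure is seeded and deterministic. Negative SEs are a
  configuration error; a target SE of exactly zero is clamped to sigma 0,
  because under compositional renormalization a strictly zero sd is
  unattainable while any other component varies (and the bundled tables
  do print 0.0 SEs for trace components).
* **Censoring.** Simulated components below 0.01% are recorded as nd and
  the composition renormalized, mirroring the trace "nd" entries of real
  integrations; components with mean 0 are structural absences and never
  appear.
* **Raw areas.** Compositions are multiplied by a log-normal total-area
  scalar so that the area-normalization path is exercised end to end.
* **Sexes** are assigned binomially at the configured ratio; an optional
  per-component multiplicative shift on male means induces sex
  dimorphism.

What the generator does **not** emulate, and hence what passing tests do
not establish about real data: within-individual covariance between
components (perturbations are independent; real co-regulated hydrocarbon
families covary), retention-time drift between runs, detector saturation
and integration error, and intensity structure of mass spectra. The
generator reproduces first and second moments of the compositions, which
is what the distance-based analyses consume.

## Problem sizes and numerical checks

The statistical calibration checks run at the bundled study design
(58 individuals in groups of 10/12/10/8/12/6, 30 components): 500 null
data sets simulated from a common mean with 999-permutation PERMANOVA
each (type-I error asserted within 0.05 +- 0.02), and 50 data sets from
the six reference means (null rejected at p <= 0.01 in at least 95%).
Dispersion calibration uses 400 Monte Carlo draws per bisection step;
empirical means are checked against generating means at 3 SE
(with a multiplicity allowance across 30 components), and coding of
pooled simulated means must recover the generating codes for every
component whose mean is at least 0.05 points from a bin boundary --
exactly on a boundary the generating and realized bins legitimately
differ.

## Known limitations

* The bundled population data are printed means +- SE, so the original
  individual-level ordination statistics (stress values, a specific
  PERMANOVA R^2) are not reproducible and are not targeted; the
  individual level is covered by the calibrated simulator instead.
* The overall class percentages reported for the pooled sexes
  (42.3/25.8/22.3/9.2) are reconstructed from the bundled sex means only
  to within about one percentage point under n-weighted pooling
  (42.95/26.12/22.10/8.99); no weighting recovers them exactly, so the
  tests assert the reconstruction at +-1.5 points.
* Fragment prediction covers single-bond cleavages at branch points plus
  the two standard neutral losses; rearrangement ions and co-eluting
  isomer mixtures (see the two flagged catalog rows) are out of scope.
* Dienes, E/Z isomerism and oxygenated surface lipids are not modelled;
  alkenes carry exactly one double bond.
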