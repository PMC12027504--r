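# chctax

Cuticular hydrocarbon (CHC) chemotaxonomy from GC–MS peak tables.

Insects carry a species- and population-specific blend of long-chain
surface hydrocarbons (n-alkanes, monoenes, methyl-branched alkanes,
C20–C40). `chctax` is for entomologists and chemical ecologists who want
to go from raw GC–MS evidence to population-level and taxon-level
conclusions without leaving R: it identifies components, summarizes and
contrasts profiles, and turns mean profiles into chemotaxonomic character
matrices and trees that can be compared with trees from independent
genetic markers. The package bundles a complete worked dataset: the 30
elytral CHC components of the bark beetle *Ips subelongatus* with
retention times, diagnostic ions, sex means and the mean profiles of six
geographic populations.

## What it computes

**Identification.**

* Retention indices by linear temperature-programmed interpolation on an
  n-alkane ladder: with bracketing alkanes n and n+k,
  `KI = 100n + 100k (t − t_n)/(t_{n+k} − t_n)`, rounded half-up.
* Diagnostic electron-impact ions of methyl-branched alkanes: for each
  C–C bond flanking a branch carbon, both charged fragments in even
  (14m) and odd (14m + 1) nominal-mass variants, where m counts the
  fragment's carbons including retained branch methyls; plus M−15
  always and M−29 for 3-methyl compounds.
* DMDS double-bond localization: the dimethyl-disulfide adduct of a
  monoene (M + 94) cleaves between the derivatized carbons into the pair
  `14d + 47` and `(14n + 94) − (14d + 47)`; `locate_double_bond()`
  inverts observed fragments to the position d.
* `annotate_peak()` ranks catalog candidates by ion evidence within a
  retention-index window.

**Profiles and statistics.** Area normalization to relative percentages
("nd" is an exact zero with a detection flag), per-group mean ± SE,
class composition, Student's t sex contrasts, one-way ANOVA with
Student–Newman–Keuls letters, Bray–Curtis distances
(`Σ|a−b| / Σ(a+b)`), NMDS (Kruskal stress-1), seeded one-way PERMANOVA
(pseudo-F, R², permutation p).

**Chemotaxonomy.** Ordinal coding of mean percentages
(0 = nd; 1: < 0.5 %; 2: 0.5–1 %; 3: 1–5 %; 4: > 5 %), UPGMA trees with
deterministic tie-breaking and canonical newick export, Robinson–Foulds
comparison against trees from other markers (e.g. COI).

**Simulation.** A seeded logistic-normal generator of individual-level
compositional profiles around population means, with dispersion
calibrated to printed standard errors and detection censoring — so the
whole pipeline is testable at individual level from bundled means alone.

## Worked example

```r
library(chctax)

## identify a peak: retention index, then candidates by ion evidence
ladder <- build_ladder(chc_catalog())
retention_index(37.29, ladder)
#> [1] 2741
annotate_peak(2741, c(112, 309), chc_catalog())
#>     label peak_no   ki ki_diff ion_match
#> 1 7-meC27      10 2741       0         1
locate_double_bond(27, c(173, 299, 472))
#> [1] 9

## simulate the six-population study design and test population structure
cfg <- sim_config(seed = 17)
prof <- profile_matrix(simulate_individuals(cfg),
                       components = chc_catalog()$label)
prof
#> <chc_profile> 58 individuals x 30 components; populations: MJHL, WDLN, GHIM, YCHL, EDJL, ARIM
permanova(bray_curtis(prof), prof$population, n_permutations = 999, seed = 17)
#> <chc_permanova> pseudo-F(5, 52) = 46.164, R2 = 0.816, p = 0.001 (999 permutations, seed 17)

## chemotaxonomic tree from the bundled reference means
cm <- coded_matrix(population_means(), chc_catalog())
write_newick(upgma(bray_curtis(cm)))
#> [1] "(((ARIM:0.0333333333333,MJHL:0.0333333333333):0.0398401189812,(GHIM:0.0168539325843,YCHL:0.0168539325843):0.0563195197303):0.0377441218098,(EDJL:0.0446428571429,WDLN:0.0446428571429):0.0662747169815);"

class_composition(population_mean_matrix(), "ARIM")
#>   n_alkane     alkene monomethyl   dimethyl
#>       28.9       52.7       14.3        4.1
```

Reading the output: the peak at 37.29 min indexes at 2741 and its ions
112/309 are exactly the branch-point fragments of 7-methylheptacosane.
The simulated study separates populations decisively (p at the
permutation floor 1/1000; R² ≈ 0.8 of distance variance among
populations). The coded-matrix tree pairs GHIM with YCHL at the lowest
height — the two high-branched-alkane populations — with the remaining
four populations in the other limb; ARIM's profile is dominated by
alkenes (52.7 % of the total).

A thin command-line front end over the same functions is installed at
`inst/scripts/chctax` (`chctax ions 7-meC27`, `chctax dmds --chain 27
--db 9`, `chctax ki --ladder ladder.csv --rt 35.21`, `chctax tree
--means means.csv --out tree.nwk`, ...).

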