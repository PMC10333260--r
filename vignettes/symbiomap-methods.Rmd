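---
title: "Methods: resampling null models and functional annotation of a symbiont-host interactome"
author: "SymbioMap package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resampling null models and functional annotation of a symbiont-host interactome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SymbioMap)
```

# Scope

SymbioMap analyses bipartite interaction maps between the secreted effector
proteins of a root-colonising microbe and the proteins of its plant host,
as produced by systematic yeast two-hybrid screening. The package covers
five connected analyses:

1. **Convergence statistics** — resampling null models asking whether one
   organism's effectors converge on unexpectedly few host targets
   (intraspecies convergence), whether several organisms share more
   targets than chance (interspecies convergence), and whether an
   organism's targets are unexpectedly rich in annotated (e.g.
   hormone-pathway) proteins.
2. **Annotation propagation** — detection of hormone interaction points:
   direct (first-degree) effector contacts with hormone-annotated host
   proteins, and second-degree contacts reached through an un-annotated
   target that neighbours an annotated protein in a reference host
   interactome; and the assembly of a functionally informed network whose
   edges are typed by the agreement between an effector's experimentally
   measured hormone effects and its target's annotations.
3. **Reporter-screen scoring** — normalisation and effect calling for a
   dual-reporter (luciferase / glucuronidase) protoplast screen.
4. **Phenotyping metrics** — hormone tolerance index, anthocyanin
   content, germination rates, relative expression, and the standard
   group comparisons.
5. **Candidate filtering** — rule-based selection of effector candidates
   from precomputed sequence and expression features.

A seeded synthetic-data module generates every input the pipeline
consumes, with planted ground truth, so the statistical machinery can be
calibrated and its recovery measured without any external data.

# The resampling null models

## Intraspecies convergence

The observed statistic is the number of unique host targets of an
organism's effector set. Under the null hypothesis of indiscriminate
targeting, each of the N observed interactions (N = total effector-host
pairs) could have hit any protein of the sampling pool: a null replicate
draws N proteins *with replacement*, uniformly from the pool, and records
how many distinct proteins were drawn. Convergence — redundant targeting
of the same host proteins — shows up as an observed unique-target count
in the lower tail of this occupancy distribution. The empirical p-value
is the fraction of replicates whose unique count is *strictly below* the
observed count; ties do not count toward significance. When no replicate
qualifies, the p-value is stored as 0 with a floor flag and is displayed
as the configured floor string (`"<0.001"` at the default 10,000
replicates), reproducing the reporting convention of empirical p-values
without discarding the information that the count was zero.

The sampling unit is the *protein*, not the edge: although procedures of
this family are often described as degree-preserving network rewiring,
the implemented null draws pool proteins with replacement, which is the
procedure the statistic (unique draws vs unique targets) requires. A
`degree_weighted` option draws pool proteins proportionally to their
reference-interactome degree, as a sensitivity analysis against the
possibility that highly connected proteins are more likely to be
recovered by two-hybrid screening.

The default pool is the reference-interactome node set intersected with
the experiment's search space. Both an explicit protein vector and a full
reference object are accepted, because it is genuinely ambiguous whether
such analyses should sample from all reference proteins or only those
interrogated by the screen; the package makes the choice explicit at the
call site.

## Interspecies convergence

For organisms tested in a common search space (networks are restricted
to it first), the observed statistic is the size of the intersection of
the organisms' unique-target sets. Each null replicate redraws *every*
organism's target set — N_org proteins with replacement, deduplicated —
and records the intersection size; the p-value counts replicates
*strictly above* the observed overlap. Interactions flagged as
discoverable only in a hormone-protein extension of the search space are
dropped by default in all cross-organism comparisons, since proteins
interrogated for only one organism would otherwise inflate or deflate
overlap estimates.

## Annotated-target excess

Whether an effector set's unique targets contain unexpectedly many
annotated proteins is tested conditionally on the number of unique
targets U: each replicate draws U proteins *without replacement* from
the pool (a random network with U targets) and counts annotated ones.
Without-replacement sampling is the natural choice because a target set
is a set of distinct proteins; the null is then exactly hypergeometric,
which the test suite exploits as an independent oracle. The upper tail
is non-strict (count ≥ observed), the conservative convention for a
test whose inequality is not otherwise pinned down.

## Numerical and reproducibility conventions

* A seed is mandatory in every `rewiringConfig`; the same seed and
  configuration give bit-identical results.
* Empirical p-values are exact fractions over `reps`; no continuity or
  +1 corrections are applied, so the floor flag is the only departure
  from the raw fraction.
* Observed statistics are integers; all tie handling is as stated above.

# Hormone interaction points and the functionally informed network

A first-degree record is an effector interaction with a hormone-annotated
target; its hormone set is the target's. A second-degree record arises
when an un-annotated target has an annotated neighbour in the reference
interactome: the target mediates, and one record is emitted per annotated
neighbour reached (a path of length two from the effector). Longer paths
are deliberately excluded — beyond two steps, annotation transfer in a
dense interactome loses specificity. Second-degree counts are unique
annotated proteins reached, not neighbour-edges. Effectors are
partitioned `has_1st` / `only_2nd` / `none`, with direct contacts taking
precedence when both exist.

The functionally informed network keeps effectors with at least one
significant reporter-screen call (either direction) and at least one
physical target. Edge types: **II** when the target carries no
annotation; **I** when the effector's screen-derived hormone set
intersects the target's annotation set; **III** when both are annotated
but disjoint. The three fractions partition the edge set; adding an
annotation can move an edge out of type II but can never create one.
The hormone vocabulary is fixed to nine labels (ABA, AUX, CK, JA, SA,
ET, BR, GA, SL); unknown labels are rejected at load so typing mistakes
surface early rather than as silently un-annotated proteins.

# Reporter-screen scoring

Wells are filtered per plate: the threshold is half of the "highest 10%"
GUS value, implemented as the mean of the top `ceiling(0.1 n)` readings
(a plate-maximum variant is available; the mean-of-top-decile is robust
to a single outlier well). The retained set is invariant under positive
rescaling of a plate's GUS channel. Luciferase is then normalised by GUS
per well, replicates are averaged (pooling plates after per-plate QC),
and each effector x reporter combination yields a mock ratio and a
treatment ratio against the empty-vector control. Their product is the
effect statistic: it rewards effectors that push the reporter in the
same direction with and without hormone stimulation, and its absolute
log2 is the ranking factor. Calls use strict boundaries — a product of
exactly 2 at the default 2-fold threshold is not significant — and
top-N selection breaks ties lexicographically by effector id so the
selection is deterministic. Empty-vector baselines are aggregated
globally across plates; a per-batch variant was considered and rejected
as the default because plate-batch structure is not always recorded,
and the QC step already removes the wells that would distort a global
baseline.

For mutant-protoplast assays, normalised activities are divided by the
wild-type mock mean within each biological-replicate batch (making the
wild-type mock exactly 1), then analysed by two-way ANOVA
(genotype x treatment) with Tukey all-pairs comparisons of the cell
means, reported as compact letter groups computed by insert-and-absorb
over the 5% Tukey-adjusted differences.

# Phenotyping metrics

The tolerance index is `100 * (line response / mean control response) - 100`,
where a line's response is its treated/mock trait ratio in percent.
Responses are computed per line from replicate means; control lines enter
as line-level responses and are then averaged, so the mean tolerance of
the controls themselves is 0 by construction and the index is invariant
to measurement units. The response is the treated/mock percentage (not
the percent *reduction*); this makes the sign convention come out as
stated — negative tolerance means the line's growth is attenuated more
than the controls' — and a reduction-based variant is available via
`responseAs`.

Anthocyanin content is `(A530 - 0.25 * A_far) * 5`; the far-red channel
is treated generically because published protocols vary between 637 and
657 nm for the correction wavelength while using the same constants.
Negative values are reported as-is with a warning rather than clipped.

Group comparisons use the Welch two-sample two-tailed t-test (no
equal-variance assumption) and one-way ANOVA with Tukey comparisons.
Degenerate inputs — both groups constant and equal — return p = 1 by
convention so pipelines do not fail on flat fixtures.

# Candidate filtering

Candidates are retained when they have a complete ORF, a predicted
signal peptide, no transmembrane domain outside it, and colonisation
up-regulation. The external predictors (signal peptide, transmembrane,
domain content) are consumed as precomputed feature columns — their
execution is versioned, heavyweight and out of scope; the filtering
logic is the analysis step. "Up-regulated during colonisation" is
operationalised as a maximum log2 fold-change of at least 1 over the
configured timepoints, an any-of rule across early and late colonisation
stages; no published numeric cutoff exists for this criterion, so it is
a configurable default. Domain presence is recorded but is not a
rejection rule. Rules apply in a fixed order and each rejection carries
the first failing rule, so retained plus rejected always partition the
input and the retained set is monotone in every threshold.

# The synthetic-data generators

The generators emulate the statistical structure the analyses assume,
at one tenth of the motivating study's scale for speed: a 1200-protein
host interactome (standing in for a ~12,000-protein screening space,
with a nested 800-protein subspace), 33 interacting effectors per
organism with a shifted-geometric degree distribution averaging ~6.3
targets (about 207 interactions), 106 effector candidates screened
against five hormone reporters in duplicate with ~31% of combinations
carrying a true effect, and per-label hormone-annotation coverage of
0.04 so that roughly 30% of host proteins carry at least one of the
nine labels — matching the observation that a majority of targets in
such maps are hormone-un-annotated.

Planted structure enters in two places. Intraspecies convergence is
planted by target reuse: each new interaction reuses an already-targeted
host protein with probability `rho`, otherwise (with probability
`sigma`) draws from other organisms' target pools, otherwise draws
uniformly from the search space. With `rho = sigma = 0` the generator
*is* the null model of the resampling tests, which is what makes the
calibration experiment meaningful. Reporter wells get multiplicative
structure: a log-normal transformation efficiency shared by both
channels, independent log-normal channel noise (the configured well CV
is the total per-channel CV, split evenly on the log scale between the
two sources), a fold effect applied to both conditions for true
modulators, and a small fraction of collapsed-efficiency wells as QC
targets. Phenotyping lines encode their planted tolerance through the
response fraction `controlResponse * (100 + tolerance) / 100`.

Ground truth is returned as provenance alongside every dataset; recovery
tests read truth only from provenance, never from the generated
measurements.

What the generators do **not** emulate: interactome false
negatives/false positives of two-hybrid screening, correlated plate
effects beyond the shared efficiency term, hormone crosstalk between
reporters, and any sequence-level realism. Passing recovery tests
therefore demonstrates that the statistical machinery is correct and
well calibrated under its own assumptions — not that those assumptions
hold for any particular real screen.

# Calibration and recovery experiments

The acceptance suite runs four simulation studies, sized to finish in a
few minutes:

* **Oracle agreement.** On enumerable sizes (pool ≤ 12, N ≤ 6) the
  Monte-Carlo p-values are compared at 10,000 replicates to exact
  results from an independent dynamic-programming occupancy oracle, the
  hypergeometric tail, and the 1/pool closed form for the two-organism
  single-target case, within three binomial standard errors.
* **Calibration.** 500 null datasets (`rho = sigma = 0`). The null
  statistic is discrete, and the test counts only replicates strictly
  below the observed value, so the attainable size depends on the
  statistic's granularity: at the study-like scale (N ≈ 207 draws from
  a 1200-protein pool) the occupancy distribution has a standard
  deviation of only ~3.7 unique targets and tail atoms of ~0.026, which
  makes the realised size of a nominal 5% test swing as high as ~0.076
  depending on where the threshold falls between atoms. The calibration
  study therefore uses 600 effectors averaging 6 targets over a
  6000-protein pool (N ≈ 3600, null sd ≈ 20, tail atoms ≈ 0.005, exact
  expected size 0.051 by the same dynamic-programming computation). The
  observed fraction of p < 0.05 is required to lie in [0.03, 0.07].
  Deduplication of repeated effector-target pairs before testing makes
  the test very slightly conservative (the observed unique count comes
  from marginally fewer collisions than the null allows).
* **Recovery.** With `rho = 0.5` at study size, the intraspecies test
  must reject at 5% in at least 90% of 200 datasets (in practice it
  rejects in essentially all of them — halving the unique-target count
  is a massive signal). Screens with planted 2.5-fold effects on both
  conditions, 20% well CV and duplicate wells must reach ≥ 80%
  sensitivity with ≤ 10% false calls over 100 screens of 40 effectors
  each; a planted tolerance of -20 points must be recovered within ±5
  points, averaged over 20 datasets of 30 plants per line and condition
  with three control lines.
* **Invariants.** Degree partitions, exclusive/shared partitions and
  type I/II/III fractions are checked on every generated dataset.

# Known limitations

* Empirical p-values have resolution 1/reps; analyses needing smaller
  p must raise `reps` (cost is linear).
* The interspecies null redraws all organisms; a conditional variant
  (resampling only the focal organism) is not provided.
* Term enrichment is classic per-term testing; no ancestor propagation
  or term-graph decorrelation is performed, so the input annotation map
  carries responsibility for any propagation.
* The compact-letter-display algorithm is the simple insert-and-absorb
  scheme; it is correct but not guaranteed to use the minimal number of
  letters.
* Interaction deduplication treats the pair (effector, target) as the
  unit; interaction stoichiometry or bait/prey orientation is not
  modelled.

# A minimal worked example

```{r example, eval = FALSE}
cfg  <- simConfig(seed = 42, rho = 0.5)
ref  <- genReferenceInteractome(cfg)
nets <- genEffectorNetworks(cfg)$networks
pool <- spaceMembers(genSearchSpaces(cfg)$full)

res <- intraspeciesConvergence(nets$Si, pool,
                               rewiringConfig(reps = 10000, seed = 43))
res
formatPValue(res)

ann   <- genAnnotations(cfg, interactomeNodes(ref))
ships <- findShips(nets$Si, ref, ann$hormones)
table(ships$effectorClass)
```
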