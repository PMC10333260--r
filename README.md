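# SymbioMap

Analysis toolkit for symbiont-host effector interactomes: resampling
null models for target convergence, hormone-annotation propagation,
reporter-screen scoring and whole-plant phenotyping metrics.

## The problem

Plant-colonising microbes — pathogens and beneficial symbionts alike —
secrete effector proteins that physically bind host proteins to rewire
host physiology. Systematic yeast two-hybrid screening of an effector
repertoire against a host protein library yields a bipartite
effector-host interaction map. Three questions follow immediately:

* Do the effectors of one microbe **converge** on fewer unique host
  proteins than chance would allow (redundant targeting of functionally
  important hubs)?
* Do evolutionarily distant microbes **share** host targets beyond
  chance (a universal microbe-host interface)?
* Which host pathways — in particular the phytohormone network — do the
  targets belong to, and do the physical contacts predict the hormone
  functions measured for each effector in cell-based reporter screens?

SymbioMap implements the statistics behind these questions for users
analysing their own interaction tables, plus the downstream functional
layers: reporter-screen normalisation and hit calling, hormone-tolerance
phenotyping metrics, and effector-candidate filtering.

## The core statistics

**Intraspecies convergence.** With N observed effector-host
interactions and U unique targets, each null replicate draws N proteins
with replacement from a reference pool (by default the host reference
interactome intersected with the screen's search space) and counts the
distinct proteins drawn. The empirical p-value is

    p = #{replicates with distinct count < U} / reps

(lower tail, strict). A result with no qualifying replicate is flagged
and printed as `<0.001` at the default 10,000 replicates.

**Interspecies convergence.** For organisms screened in a common search
space, each replicate redraws every organism's unique-target set
(N_org draws with replacement, deduplicated) and records the size of
the intersection; the p-value counts replicates strictly above the
observed overlap (upper tail).

**Annotated-target excess.** Conditional on U unique targets, each
replicate draws U proteins without replacement and counts members of an
annotated set (e.g. hormone proteins); the p-value is the non-strict
upper tail. The null is exactly hypergeometric, which the test suite
uses as an independent oracle.

**Annotation propagation (hormone interaction points).** An effector
contacting an annotated host protein forms a first-degree record; an
effector whose un-annotated target neighbours an annotated protein in
the reference interactome forms a second-degree record through that
mediator. Combining the physical map with reporter-screen calls yields
a functionally informed network whose edges are typed I (screen-derived
effector hormone set matches the target's annotation), II (target
un-annotated) or III (mismatch).

**Reporter screen.** Luciferase activity is normalised per well by a
co-transformed glucuronidase control; wells below half of a plate's
top-decile GUS mean are omitted; each effector x hormone combination is
scored by the product of its mock and treatment ratios versus the empty
vector, called significant beyond a 2-fold change, and ranked by
|log2 product|.

## Worked example

Generate a synthetic study with planted convergence (`rho = 0.5`: half
of all interactions reuse an already-targeted protein), then test for
it:

```r
library(SymbioMap)

cfg  <- simConfig(seed = 42, rho = 0.5)
ref  <- genReferenceInteractome(cfg)
nets <- genEffectorNetworks(cfg)$networks
pool <- spaceMembers(genSearchSpaces(cfg)$full)

nets$Si
#> EffectorHostNetwork [Si in full_space]: 152 interactions, 33 effectors, 86 host targets

res <- intraspeciesConvergence(nets$Si, pool,
                               rewiringConfig(reps = 10000, seed = 43))
res
#> RewiringResult (lower tail): observed = 86, null mean = 142.84 (sd 2.81), p = <0.001 [10000 replicates]
```

The 33 effectors hit only 86 distinct host proteins where random
targeting of the same 152 interactions would hit ~143; no null
replicate came close, so the empirical p-value is reported at its floor,
`<0.001`. Propagating hormone annotations over the reference
interactome then classifies each effector by how it reaches the hormone
network:

```r
ann   <- genAnnotations(cfg, interactomeNodes(ref))
ships <- findShips(nets$Si, ref, ann$hormones)
table(ships$effectorClass)
#>  has_1st     none only_2nd
#>       22        1       10
```

22 effectors touch an annotated hormone protein directly, 10 reach one
only through an un-annotated mediator, and 1 has no hormone contact at
either degree.

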