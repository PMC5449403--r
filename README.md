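# ecoextent

Quantifying how far a pipeline, road or other linear construction affects
the surrounding plant community, from belt-transect vegetation surveys.

## The problem and the method

A linear corridor clears its working strip, but its ecological footprint
extends outward: compacted soil, maintenance traffic and colonising pioneer
species alter community structure for tens to hundreds of metres. Raw
diversity comparisons are a poor yardstick for that footprint — pioneers
*gain* from disturbance, and sparse accompanying species add noise.
`ecoextent` follows the **dominance structure** instead:

1. Per species and belt transect, the importance value

   *IV = (Rd + Rf + Rc) / 3*

   averages relative density (stalk counts), relative frequency
   (plot occupancy) and relative cover, each pooled over the transect's
   plots so that every component sums to 1 across species.
2. Species are clustered by their IV-against-distance profiles with a
   modified TWINSPAN (two-way indicator species analysis): pseudospecies
   cut levels 0/0.02/0.05/0.10/0.20, first correspondence-analysis axis by
   reciprocal averaging, a dichotomy near the weighted axis middle refined
   by indicator pseudospecies — dividing the most heterogeneous cluster
   (mean pairwise Bray–Curtis) at each step.
3. Each cluster's integrated importance value (IIV, the mean of member
   IVs) is tracked along the distance gradient and classified into response
   groups: **G1** disturbance-promoted pioneers, **G2** suppressed original
   dominants (the indicator group), **G3** the rest.
4. The K-points are read off the group trajectories: **K2**, where the G2
   trajectory stabilises inside a ±15 % band around its far-field level, is
   the effect extent; **K3**, the interval where G2 overtakes G1, brackets
   the edge-effect transition zone.

A synthetic survey generator with known true extent (negative-binomial
counts, logistic distance responses in log distance) makes the whole chain
testable end to end.

## Worked example

The package ships the published 8-species × 13-transect IV table of a
desert-steppe survey crossed by three parallel pipelines
(`table1Fixture()`; transects I, I-O, Oil, O-II, II inside and between the
corridors, then 10–1000 m outward).

```r
library(ecoextent)

fx  <- table1Fixture()
cl  <- modifiedTwinspan(ivMatrix(fx), nClusters = 3)
cl
#> SpeciesClustering: 8 species in 3 clusters (2 divisions)
#>   Cluster 1: Achnatherum splendens, Galium verum, Nitraria sibirica
#>   Cluster 2: Kalidium foliatum, Scorzonera sinensis
#>   Cluster 3: Kalidium gracile, Leymus secalinus, Phragmites australis

iiv <- integratedIV(fx, cl)
ga  <- assignGroups(iiv)
ga
#> GroupAssignment:
#>   Cluster 1 -> G3 (near 0.004, far 0.095, trend +0.93)
#>   Cluster 2 -> G2 (near 0.143, far 0.423, trend +0.74)
#>   Cluster 3 -> G1 (near 0.294, far 0.179, trend -0.60)

effectExtent(iiv, ga)
#> ExtentEstimate:
#>   K1 (G1 stabilisation): 1000 m
#>   K2 (effect extent):    100 m
#>   K3 (crossover):        (50 m, 100 m]
```

The classification recovers the published three clusters: the reed and
grasses that turned corridor-dominant (G1, IIV high near, falling
outward), the two original dominants whose IIV climbs from 0.14 near the
pipelines to 0.42 far away (G2), and three sparse accompanying species
(G3). The G2 trajectory enters its far-field band at the 100 m transect
(K2), and dominance flips between 50 m and 100 m (K3) — the zone where
community structure is actually turning over. The field assessment itself
placed the extent at 300 m by additionally weighing diversity profiles;
the package reports the mechanical 100 m together with every parameter
that produced it, so that judgement stays visible.

On a simulated survey with known truth:

```r
x <- generateSurvey(syntheticConfig("s1_like"), seed = 42)  # true extent 300 m
iv <- importanceValues(x)
cl <- modifiedTwinspan(ivMatrix(iv), nClusters = 3)
iiv <- integratedIV(iv, cl)
effectExtent(iiv, assignGroups(iiv))
#> ExtentEstimate:
#>   K1 (G1 stabilisation): unresolved
#>   K2 (effect extent):    300 m
#>   K3 (crossover):        (50 m, 100 m]
#>   note: K1 unresolved: G1 never stabilises within the survey
#>   note: transition zone: stabilisation (K2 = 300 m) and dominance crossover (100 m) disagree
```

`runReport()` chains every stage (validation, IV, clustering, groups,
extent, diversity indices) into one JSON report with CSV artefacts, and
`inst/scripts/ecoextent.R` exposes the same stages as shell subcommands.
The methods vignette (`vignettes/effect-extent-methods.Rmd`) documents the
model, every tunable parameter, and the package's conventions.

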