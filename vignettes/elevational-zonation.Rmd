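---
title: "Detecting elevational zonation in species assemblages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting elevational zonation in species assemblages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elevzone)
```

## The question

Altitudinal limits such as 500, 900, 1,000 or 3,000 m asl have long been
used to separate "lowland" from "montane" (Andean) anuran faunas. Whether
such limits correspond to real discontinuities in species composition
along the mountainside is an empirical question: if community composition
turns over smoothly, any fixed elevation is an arbitrary cut; if there
are compositional breaks, they need not sit where tradition puts them.

`elevzone` operationalizes the question as a dissimilarity-based pipeline:

1. curate occurrence records (coordinate validity, deduplication to
   unique species-localities, synonym harmonization, assignment to
   analysis entities such as individual cordillera slopes);
2. assign elevations (from the record or a DEM) and group records into
   200-m elevation bands, yielding a band x species presence-absence
   matrix;
3. compute total beta diversity between every pair of bands;
4. cluster bands by UPGMA and ask how many elevational groups the data
   support (gap statistic) and how stable each group is (bootstrap
   Jaccard support);
5. compare detected compositional breaks against proposed altitudinal
   limits, and compute for each proposed limit the fraction of taxa whose
   elevational range *spans* it.

## The dissimilarity and its decomposition

For two bands sharing `a` species, with `b` and `c` species unique to
each, the total Jaccard-family dissimilarity is

$$\beta_{cc} = \frac{b + c}{a + b + c},$$

which decomposes additively into species *turnover* (replacement),

$$\beta_{-3} = \frac{2\min(b, c)}{a + b + c},$$

and *richness difference*,

$$\beta_{rich} = \frac{|b - c|}{a + b + c}.$$

The identity $\beta_{cc} = \beta_{-3} + \beta_{rich}$ holds exactly, and
all three lie in $[0, 1]$. Total beta is a metric on non-empty bands;
the test suite verifies the triangle inequality exhaustively on all
small binary matrices and checks every computed value against an
independent set-arithmetic oracle.

## Banding conventions

Bands are half-open intervals $[b, b + w)$ labeled by their lower edge,
with $w = 200$ m and origin 200 m by default, producing the labels 200,
400, ..., 4,400 for a typical Andean gradient. The default occupancy rule
is *record-based*: a species occupies a band only where it has a record,
so occupancy can be non-contiguous — which is what real curated data
produce and what makes non-contiguous band groups possible. The
alternative `range_fill` mode (every band between a species' observed
minimum and maximum) is retained for sensitivity analysis. Bands left
without species are dropped; this provably does not change any pairwise
dissimilarity among the remaining bands.

Records below the grid origin are outside the study frame and excluded
at banding time; records without an obtainable elevation are counted and
excluded there too, keeping the cleaning and elevation concerns separate.
When both a DEM value and a record elevation exist the DEM wins; DEM
sampling is nearest-cell, which at ~90 m resolution is within the
georeferencing error of typical occurrence records.

## UPGMA and determinism

Bands are clustered with true (size-weighted) UPGMA on $\beta_{cc}$.
Because beta values are small rationals, tied linkages are common; ties
are broken deterministically in favor of the pair whose sorted member
labels are lexicographically smallest, so the same matrix yields the
same tree on every platform. Merge heights are the raw linkage
dissimilarities; only the Newick export halves them so that leaf-to-root
path lengths reproduce the ultrametric cophenetic distances.

## How many groups? The gap statistic and its null

For each candidate number of groups $k$ we record the pooled
log within-group dispersion
$\log W_k$, with
$W = \sum_r \frac{1}{2 n_r} \sum_{i,j \in r} D_{ij}$, and compare it with
the same quantity computed on reference band matrices drawn from a null
model; $\mathrm{gap}(k)$ is the mean difference, $s_k$ its simulation
error, and the selected $k$ is the smallest one with
$\mathrm{gap}(k) \ge \mathrm{gap}(k+1) - s_{k+1}$ (the one-standard-error
rule; a global-maximum rule is available). $k = 1$ reads "no elevational
groups detected".

The choice of null model deserves care, and is the one place where this
package departs from the most obvious construction. Independent
Bernoulli nulls (per-cell presence with the species' marginal
prevalence) destroy not only elevational structure but also *range
cohesion* — the fact that a species' occurrences concentrate in one
stretch of the gradient. Against such a null, real or simulated gradient
data "beat" the reference at every $k$, because average-linkage
clustering keeps finding exploitable structure that the scattered
reference lacks; the gap curve then rises monotonically and the rule
over-partitions even noise-free planted data. We therefore default to a
*bounded range-shuffle* null: each species keeps its observed occupancy
pattern (breadth, number of occupied bands, internal gaps), the pattern
is randomly reflected and slid to a uniformly random position along the
band axis, without wraparound. This preserves everything about
individual ranges and destroys exactly the cross-species *alignment* of
range limits — which is what elevational zonation is. With it, planted
zonation is recovered reliably and structureless matrices yield
$k = 1$. The Bernoulli nulls remain available (`null = "prevalence"`,
`"uniform"`) for comparison.

Reference draws occasionally leave a band (or species) empty; such rows
and columns get a single presence planted at a random position so the
dissimilarity stays defined and matrix dimensions stay fixed. All
randomness derives from one integer seed, drawn sequentially in a fixed
order, so results are bit-reproducible for a given seed and replicate
count; desk-scale defaults use 1,000 reference draws, and analyses in a
hurry can drop to 200 with little loss (the selection rule operates far
above the Monte-Carlo noise floor in clear-cut data).

## Group support: bootstrap Jaccard stability

Support for each of the $k$ groups is the clusterwise Jaccard bootstrap:
resample species (the matrix columns) with replacement, drop bands left
empty, recompute dissimilarities, the UPGMA tree, and the $k$-group cut,
and score each original group by its best Jaccard match among the
replicate's groups (bands absent from a replicate are ignored on both
sides). $J_b$ for a group is its mean best match over replicates; values
near 1 indicate groups robust to sampling of the species pool, and
$k = 1$ has $J_b = 1$ by construction. Species, not bands, are
resampled: bands are the objects being classified, and uncertainty comes
from which taxa happen to be sampled. Replicates in which fewer than two
(or fewer than $k$) bands survive are skipped and counted; more than
half skipped is an error.

## Spanned-range statistics

A taxon's range $[\min, \max]$ *spans* a proposed limit $B$ when
$\min < B$ and $\max > B$, strictly on both sides — a range that merely
touches the limit does not span it. Genus and family ranges are union
ranges (minimum and maximum pooled over member species) before the test,
so a genus may span a limit although no member species does; this
aggregation can only widen ranges, which is why family percentages are
at least genus percentages in well-sampled data. Detected breaks are
reported as the boundary elevation between adjacent groups (ordered by
mean band elevation); when unoccupied bands separate two groups the
midpoint of the empty interval is reported and flagged, and interleaved
groups are flagged as overlapping.

## The synthetic generator and what it does (not) show

The generator plants a known zonation: $K$ zones over a 200-4,600 m
frame split at chosen break elevations (defaults 2,600 and 4,000 m),
each with its own species pool (default 25 species per zone), Poisson
record counts per species (default mean 5), uniform record elevations
within each species' range, optional Gaussian elevation noise, uniform
coordinates in a bounding box, and zone-blocked genera and families so
family-level summaries have structure.

Range breadths are lognormal; the default (median twice the gradient
extent, sdlog 0.2) is deliberately wider than any zone so that, after
clipping to the zone, every non-straddling species occupies its whole
zone. That makes zone membership the *only* compositional signal — the
meaning of a planted-zonation scenario. Narrower breadths instead
produce continuous within-zone turnover, a different (gradient-like)
structure that the gap statistic legitimately resolves into more than
$K$ groups; they are useful for sensitivity analyses, not for ground
truth. With probability `overlap_fraction` a species is centered near a
zone edge instead and its range is not clipped, blurring the planted
breaks; support values $J_b$ decline monotonically along an overlap
gradient.

The generator emulates none of the following features of real
occurrence data: spatially autocorrelated sampling effort, elevation
measurement bias, taxonomic impediment varying by group, or realistic
richness gradients within zones. Passing the planted-recovery tests
therefore shows the machinery is correct and calibrated, not that any
particular real gradient has $K$ zones.

The degradation helper injects exact duplicates, (0,0) and out-of-range
coordinates, and synonym renames (with the matching synonym table), so
the cleaning stages can be exercised against known bookkeeping.

## Numerical and edge-case choices

- Deduplication rounds coordinates to 4 decimals (~11 m) by default;
  the precision is exposed because "unique locality" is not a
  scale-free notion.
- $\log W$ is floored at machine epsilon so zero-dispersion partitions
  (duplicate bands) stay finite.
- `beta_pair` on two empty bands is an error; empty bands cannot reach
  the statistics because banding drops them.
- Points exactly on a shared polygon edge belong to the first feature
  in file order; overlapping polygons warn.
- Entity polygons are read from GeoJSON and DEMs from ESRI ASCII grids —
  both plain-text formats with simple, auditable parsers.
- Validation problem sizes (20 seeds at 200 reference draws; bootstrap
  replicate counts of 500-2,000) were chosen so the full suite runs on a
  laptop in a few minutes while keeping Monte-Carlo error well below the
  decision margins involved.

## Known limitations

- Coordinate cleaning implements only self-contained validity rules;
  gazetteer-based tests (country borders, centroids, sea) are out of
  scope.
- The gap statistic inherits the general weakness of cluster-number
  selection on gradient data: smooth turnover without discrete zones can
  still be partitioned, and the selected $k$ then describes convenient
  segments rather than natural breaks. Comparing against the
  range-shuffle null mitigates but does not eliminate this.
- Bootstrap Jaccard support here is stability under species resampling;
  it is not a frequentist p-value for the existence of a group.
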