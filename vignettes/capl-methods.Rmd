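---
title: "Combined family and case-control association testing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined family and case-control association testing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capl)
```

## The problem

Genome-wide association studies come in two flavours — nuclear families
(transmission-based designs, robust to stratification when parents are
typed) and unrelated cases and controls (cheap, powerful, but confounded by
population substructure).  Public repositories hold both, and power grows
substantially when they are analysed jointly.  The statistic implemented
here does that: it is an extension of the APL ("association in the presence
of linkage") family test in which **unrelated cases and controls are
treated as one-sib families with two missing parents**, so a single
family-based framework covers every design, while population stratification
is handled by clustering individuals into subpopulations from genome-wide
marker data.

## The statistic

For a biallelic marker, genotypes count copies of a *counted allele*
(0/1/2).  Each nuclear unit $i$ contributes

$$c_i = X_i - n_i \sum_{k,m,j} w_i(k, m, j)\, e(m),$$

where $X_i$ is the observed number of counted-allele copies among the
unit's genotyped affected siblings, $n_i$ their number, $e(m) = (g_1 +
g_2)/2$ the null-expected copies per offspring under parental mating type
$m$ (the unordered parental genotype pair, six states), and $w_i$ the
posterior weight of subpopulation $k$, mating type $m$ and sib-pair IBD
state $j$ given the unit's observed genotypes.  The per-marker statistic is
$T = \sum_i c_i$; under the null hypothesis of no linkage or no
association, $E[T] = 0$.  Control singletons have $n_i = 0$ and anchor the
allele-frequency estimation only.

On complete triads with one subpopulation the posterior is degenerate at
the observed mating type and $T$ collapses to the classic TDT count
$(b - c)/2$ over heterozygous parents — a reduction the test suite asserts
exactly.

## Missing parents, mating types and IBD

The posterior weights are

$$w_i(k, m, j) \propto \pi_{ik}\, P(m \mid p_k)\, \kappa_i(m)\, z_j\,
P(\text{sib genotypes} \mid m, j),$$

normalised over all states.  The pieces:

* $P(m \mid p_k)$ — HWE mating-type probabilities under the
  subpopulation's counted-allele frequency $p_k$, with the factor 2 for
  heterogeneous pairs.
* $\kappa_i(m)$ — compatibility with observed parental genotypes.  We use
  the *ordered-assignment* factor: the number of ordered parental
  assignments of $m$ consistent with the observations divided by the
  number of ordered assignments of $m$.  With both parents observed or
  both missing this is the obvious 0/1 indicator; with exactly one parent
  observed a bare indicator would double-count heterogeneous mating types
  (the factor 2 in $P(m)$ counts two ordered assignments, one of which the
  observation rules out), whereas the ordered factor makes the implied
  conditional over the unobserved parent exactly HWE.
* $z_j$ — the probability that an affected sib pair shares $j \in
  \{0,1,2\}$ alleles identical by descent.  Under the null of no linkage
  $z = (\tfrac14, \tfrac12, \tfrac14)$; linkage distorts it in ascertained
  affected pairs, which is why inference of missing parents must model it.
* $P(g_1, g_2 \mid m, j)$ — the exact conditionals of the labelled-gamete
  model.  Conditioning on $j$ at a parent constrains *which labelled
  allele* went to each sib: at $j = 0$ a parent's two distinct labelled
  alleles go one to each sib (anti-correlating the genotypes), at $j = 2$
  both sibs receive the identical gamete pair, and at $j = 1$ one parent
  (chosen uniformly) shares and the other does not.  A defining sanity
  check, asserted to $10^{-12}$ in the tests, is that mixing the three
  tables with the null $z$ reproduces the unconditional full-sib
  distribution, i.e. two independent Mendelian draws.  (Constructions that
  let the "non-shared" parent transmit independently fail this identity,
  because an independent draw can coincide with the shared label — an
  event that *is* a higher IBD state; such a construction biased
  $\hat z$ to the $z_0$ boundary on null data in early testing.)

Units with more than two genotyped affected siblings are handled by
modelling the two with the smallest individual identifiers exactly (the
IBD model is a pair model); all genotyped affected sibs still enter $X_i$
and $n_i$.  Families that fail a Mendelian-consistency screen at a marker
are dropped at that marker only and counted.

## Population substructure

Individuals are clustered once, genome-wide, from the allele-sharing
distance $d(i,j) = 1 - \mathrm{IBS}(i,j)/2$ averaged over markers
non-missing in both individuals — bounded in $[0,1]$ and computed in
compiled code.  Ward's agglomerative clustering (Lance–Williams recurrence
on squared dissimilarities, the "ward.D2" convention; ties broken towards
the smallest index pair) is cut at a user-chosen $K$; the method never
auto-selects $K$.  Cluster labels feed two things:

* **origin priors** per family, $\pi_{ik} = (c_{ik} + \varepsilon) /
  (c_i + K\varepsilon)$ with $c_{ik}$ the unit's members in cluster $k$ and
  $\varepsilon = 0.01$ keeping every origin strictly positive;
* **initial allele frequencies** for the EM, the per-cluster sample
  frequencies.

The priors are fixed inputs to the per-marker EM: one marker carries little
ancestry information relative to the genome-wide clustering, so the EM
outputs posterior probabilities of origin but does not update the priors.

## The per-marker EM

E-step and M-step alternate on
$(p_1,\dots,p_K, z)$: sufficient statistics are the posterior-expected
parental counted-allele copies per subpopulation ($S_{pk}$), expected unit
counts ($N_k$), and expected sib-pair IBD-state counts ($S_{zj}$); updates
are $p_k' = S_{pk}/(4N_k)$ (four parental allele slots per unit, clamped to
$[10^{-6}, 1-10^{-6}]$) and $z' = S_z / \sum_j S_{zj}$, with $z$ frozen at
the null when no two-affected-sib units exist.  Iteration stops when the
largest absolute parameter change drops below `tol = 1e-6` or after
`maxIter = 50` iterations — 20–40 iterations is the typical regime, and the
observed-data log-likelihood is non-decreasing at every step (asserted in
tests).  A useful closed-form anchor: with $K = 1$ and only
cases/controls, the EM fixed point is the sample allele frequency, reached
geometrically at rate $\tfrac12$.  With small numbers of sib pairs the
$z$ component can crawl towards a boundary and use the full iteration
budget; the estimates at `maxIter` are reported with `converged = FALSE`.

The hot loop (E/M iteration) is implemented in C++; `emEStep()` /
`emMStep()` are the plain-R reference implementation, and the suite checks
the two routes against each other on a shared trajectory.

## Bootstrap variance

The variance of $T$ includes the variability of clustering and EM
estimation, so each of the $B$ replicates resamples whole family units with
replacement (one pooled frame — singletons included), **re-clusters** the
resampled individuals by indexing the cached distance matrix (pairwise
distances never change under resampling, so nothing is recomputed),
rebuilds origin priors, re-runs the EM and recomputes $T^*$.  The report is
$\widehat{\mathrm{sd}} = \mathrm{sd}(T^*_1,\dots,T^*_B)$ with denominator
$B-1$; $z = T/\widehat{\mathrm{sd}}$ and the p-value is two-sided normal.
$T$ is not centred by the bootstrap mean since $E[T] = 0$ under the null by
construction.  Replicates where the EM fails are dropped and counted; more
than 20% failures, or a zero SD, marks the marker `degenerate_variance`.
`B = 200` by default (200–1000 is the sensible range).  Per-marker
replicate seeds are a pure function of the global seed and the marker
index, which makes results byte-identical across worker counts and
processing orders.

## The synthetic-data generator

`simulateStudy()` emulates the published simulation designs:
subpopulation allele frequencies follow the Balding–Nichols model
(ancestral frequency uniform on $[0.1, 0.9]$, per-subpopulation Beta drift
with parameter $F_{ST}$, clamped to $[0.01, 0.99]$); founders are HWE;
children receive tracked gametes (so true IBD states are known);
affection follows a multiplicative penetrance model
$f_g = f_0 \cdot \mathrm{GRR}^g$ ($f_0 = 0.1$, $\mathrm{GRR} = 1$ — the
null — by default); and designs are ascertained by rejection sampling
(triad: one affected child; multiplex: two affected children; cases and
controls by phenotype).  In `linked` mode the analysed marker *is* the
disease locus; in `unlinked` mode a hidden locus drives affection and every
analysed marker is null.  `scenarioOneConfig()` and `scenarioTwoConfig()`
reproduce the published design mixes (2000/2000/750/750 in one population;
1000/1000 cases/controls per population with triads from one population and
multiplex families from the other), with a `scale` knob for desk-scale
runs; marker counts default to hundreds rather than the array-scale
half-million, which only changes how much information the clustering step
has.

What the generator does *not* emulate: linkage disequilibrium between
markers (each segregates independently), genotyping error, missingness
patterns, age or covariate structure, and forward-time drift (the
two-population divergence is a single $F_{ST}$ knob).  A green simulation
test therefore establishes correctness of the probability model and the
estimation machinery, not robustness to those real-data features.

## Numerical and design choices

* Counted allele: PLINK A1 for binary input, lexicographically smallest
  observed allele for text input (deterministic across runs); recoding the
  counted allele negates $T$ and leaves $|z|$ and the p-value unchanged.
* Allele-frequency clamp $[10^{-6}, 1-10^{-6}]$ avoids degenerate
  mating-type distributions; monomorphic markers are reported as such and
  not tested.
* $z$ is *not* constrained to the triangle of possible sib-sharing vectors;
  raw multinomial EM updates keep the monotonicity guarantee.
* One $z$ per marker, shared across subpopulations — linkage is a property
  of the locus, not of ancestry.
* Unaffected siblings in multi-member families are kept for origin priors
  but not used in the likelihood; the statistic is defined over affected
  sibs, and controls enter as singleton units.
* The "nodes" control-file key of the original cluster deployment is
  accepted and ignored with a warning: a single-machine worker pool
  (forked processes over even, contiguous marker blocks) provides the same
  mathematical contract, and determinism is guaranteed by the per-marker
  seed derivation rather than by scheduling.
* Test-suite simulation sizes: the null-calibration check runs 400
  simulated stratified datasets with 25 units per design per subpopulation
  and $B = 100$ — scaled down from the hundreds-of-units design for
  single-CPU runtime, keeping the dataset count (which sets the width of
  the binomial acceptance envelope) at full size.  The
  bootstrap-vs-Monte-Carlo standard-deviation comparison runs at 120
  triads/250 datasets with the stated ±25% band.

## Limitations

Only nuclear units are modelled (multi-generation pedigrees must be split
beforehand); markers are biallelic autosomal (no X/Y/MT handling, no
PLINK 2 or VCF input); sibships beyond two affected sibs are approximated
as described; and the bootstrap — the honest but expensive part of the
method — dominates runtime, which is why the per-marker loop parallelises
and why distance entries are cached rather than recomputed.
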