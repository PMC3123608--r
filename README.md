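# capl — combined family and case-control association testing

`capl` implements the combined APL (CAPL) test for genetic association:
one statistic that jointly analyses nuclear families (triads, multiplex
families with affected sib pairs) and unrelated cases/controls, while
correcting for population stratification.  It is aimed at statistical
geneticists who want to pool family-based and case-control GWAS panels —
possibly drawn from different populations — into a single analysis.

## The method in brief

Unrelated individuals are folded into the family framework as one-sib
families with two missing parents.  For each marker (genotypes count
copies of a counted allele), every unit contributes the difference between
the observed counted-allele copies in its affected siblings and their
expectation conditional on the parental mating type *m*:

> T = Σᵢ [ Xᵢ − nᵢ Σ_{k,m,j} wᵢ(k,m,j) · e(m) ],  e(m) = (g₁+g₂)/2

The weights w are posteriors over subpopulation *k*, mating type *m* and
sib-pair IBD state *j*, estimated per marker by an EM that integrates over
missing parental genotypes while accounting for linkage through the IBD
sharing parameters z = (z₀, z₁, z₂).  Population substructure enters
through Ward clustering of a genome-wide identity-by-state distance
matrix; cluster memberships set each family's prior probabilities of
origin.  The variance of T comes from a bootstrap that resamples whole
family units and repeats clustering and EM in every replicate;
z-score = T / sd(T*), two-sided normal p-value.  On complete triads the
statistic reduces exactly to the TDT count (b − c)/2.

A synthetic-data generator (`simulateStudy()`) reproduces the method's
published simulation designs — Balding–Nichols subpopulations, ascertained
triads/multiplex families, cases and controls, tracked true IBD — and
doubles as the fixture factory for the test suite.

## Worked example

```r
library(capl)

# two drifted populations; triads from one, affected sib pairs from the
# other, cases/controls from both; all markers null (GRR = 1)
cfg <- scenarioTwoConfig(nMarkers = 150, fst = 0.1, scale = 25/750, seed = 11)
study <- simulateStudy(cfg)
study
#> CaplStudy: 150 marker(s) x 307 individual(s), 182 family unit(s)
#>   units: case_singleton=66, control_singleton=66, multiplex=25, triad=25

res <- caplAnalyze(study, K = 2, B = 100, seed = 1, verbose = FALSE)
res[2, c("SNP", "N_FAM_USED", "P_HAT_1", "P_HAT_2", "Z0", "Z1", "Z2", "T", "BOOT_SD", "Z", "P", "STATUS")]
#>    SNP N_FAM_USED    P_HAT_1   P_HAT_2        Z0         Z1        Z2          T BOOT_SD         Z         P STATUS
#> 2 snp2        182 0.03386292 0.1299118 0.6936766 0.01468801 0.2916354 -0.4052218 2.59726 -0.156019 0.8760181     ok
```

`P_HAT_1`/`P_HAT_2` are the EM estimates of the counted-allele frequency
in the two inferred subpopulations (they differ — that is the drift the
clustering corrects for), `Z0..Z2` the estimated sib-pair IBD sharing
(noisy at this scale: only 25 sib pairs inform it), `T` the
observed-minus-expected statistic, `BOOT_SD` its bootstrap standard
deviation over 100 re-clustered, re-estimated replicates, and `P` the
two-sided normal p-value — not significant, as expected under the null.

The same pipeline runs from PLINK files (text `.ped/.map` or binary
`.bed/.bim/.fam`) via a control file:

```r
caplPipeline("run.ctl")          # input/subpopulations/out + defaults
```

or from the shell: `Rscript inst/exec/capl.R --control run.ctl
--threads 4`.  Output is one TSV row per marker and is byte-identical for
any thread count at a fixed seed.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

simulates desk-scale versions of the two published study designs, writes
them as PLINK text and binary files, and runs the complete pipeline on
each (clustering with K = 2 where two populations are present, per-marker
EM, statistic and bootstrap), logging per-stage progress and writing the
JSON report to `--out`.
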