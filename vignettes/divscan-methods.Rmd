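---
title: "Methods and design of divscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of divscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

divscan implements the analytical core of a small-cohort conservation-genomics
study: genome-wide diversity quantification from multi-sample variant calls,
read-depth segmental-duplication (SD) detection, two-population demographic
inference from the joint allele-frequency spectrum (AFS), branch-specific
Dn/Ds scanning on a fixed five-taxon tree, and similarity-graph clustering of
genes into families. A synthetic-data module generates every input with known
truth, so each stage is testable end to end without external data. This
vignette records the models, the parameters that matter, the numerical
choices, and the design decisions taken where the methods literature leaves
the details open.

## The diversity battery

All diversity measures consume a *variant set*: a site table (scaffold,
1-based position), a dosage matrix of alternate/derived allele counts per
diploid individual (0/1/2), and optionally a per-sample depth matrix.

* `filter_by_depth()` keeps sites whose depth lies in `[5, 30]` in **every**
  sample (bounds inclusive). The conjunction across samples follows the
  per-sample phrasing of the filter it implements; sites with missing depth
  are dropped and logged.
* `filter_by_mask()` removes a site iff a mask interval (BED, 0-based
  half-open) satisfies `start < pos <= end` for the 1-based VCF position —
  the standard point-in-interval rule across the two coordinate dialects.
* `window_density()` tiles each scaffold from position 0 with fixed windows
  (50 kbp default); scaffolds shorter than one window are excluded and the
  trailing partial window is dropped. The partial-window fate is our choice;
  only the short-scaffold exclusion is inherited from the method described.
* `classify_het_hom()` counts one individual's heterozygous sites in 100-kbp
  windows and labels a window heterozygous iff the count is strictly greater
  than 40. Because it is unstated whether published homozygosity percentages
  count excluded short scaffolds in the denominator, both denominators are
  reported (`percent_homozygous` over classified windows, and
  `percent_homozygous_genome` over total scaffold length).
* `detect_roh()` is a PLINK-style scan: windows of 20 consecutive SNVs, a
  window "hits" when it contains at most 1 heterozygote, a SNV is in ROH
  state when more than 5 % of its covering windows hit, and maximal runs of
  ROH-state SNVs are kept when they span at least 10 kbp with at least one
  SNV per 50 kbp. The window-hit proportion (0.05) and the one-heterozygote
  allowance are PLINK's defaults, adopted because only the three headline
  flags are specified by the protocol we follow.
* `classify_tandem_repeats()` labels records as microsatellite (monomer
  < 5 bp), complex (monomer > 4 bp, GC in [20, 80] %, array > 100 bp,
  entropy > 1.76, copy-number length variation > 4 bp, imperfect), and
  large (subgrouped at 1/3/10 kbp). Complex and large are deliberately not
  exclusive; both flags are retained.

## Read-depth segmental duplications

The caller follows the classical read-depth recipe. Masking unions repeat
and tandem annotations with over-represented k-mers (36-mers sampled every
31 bp; three or more exact occurrences in the unmasked assembly) and adds
36 bp of padding to each masked flank, because a split read overlapping a
masked segment would otherwise depress apparent coverage near mask edges.
Scaffolds under 10 kbp and putative sex scaffolds (an input list; no rule is
re-derived here) are excluded.

Windows hold exactly 1000 unmasked positions, so their genomic span may
exceed 1 kbp. Window read depth (RD) is the sum of per-position read starts
over unmasked positions. Control statistics are estimated by iteratively
discarding windows more than 3 standard deviations from the current mean
("most extreme" is operationalized as symmetric 3-sd trimming to
convergence; the cutoff is configurable because the original tool does not
publish its criterion). Copy number is `CN = 2 * RD / mean(control RD)`, so
control windows average CN 2 by construction — the calibration the
acceptance script recomputes.

A duplication block is a maximal run of consecutive windows above the soft
threshold (control mean CN + 2 sd) in which at most one window fails the
hard threshold (mean + 3 sd), with at least 5 windows, at least 10 kbp of
genomic span, and no member CN above 100. Thresholds are computed per
sample from control-window CN; whether the sd is taken on RD or CN is
immaterial (they differ by a constant factor). Assembly gaps are subtracted
from reported spans; cross-sample sharing is a base-pair-level intersection,
and genes are reported when at least 60 % of the gene overlaps shared
duplications.

## Two-population AFS demography

The observed statistic is the joint AFS `X`, with `x[i, j]` the number of
polarized SNVs with derived count `i` in population 1 and `j` in population
2; the fixed corners `(0, 0)` and `(n1, n2)` are masked. Fitting maximizes a
Poisson composite likelihood `sum x ln m - m - ln x!` over unmasked cells,
with the overall mutation-rate scale profiled out analytically
(`theta_hat = sum x / sum m`), treating SNVs as freely recombining.

Expected spectra come from a discrete Wright-Fisher frequency-grid chain
rather than a PDE solver: the density of segregating sites on a grid of
`G + 1` population frequencies is propagated by binomial resampling steps.
An epoch of scaled duration `tau` (units of `2 N_ref` generations) at
relative size `nu` takes `n ~ G tau / nu` steps with an effective binomial
size `g ~ nu / dtau`, so drift accrues at rate `1/nu`; `g` is quantized to a
geometric ladder so transition matrices can be cached across likelihood
evaluations, and per-epoch propagation is collapsed to `log n` matrix
products (`A^n` and the accumulated injection `sum A^k e1` by binary
doubling). New mutations inject mass `theta G dtau / 2` into the singleton
class per step, which reproduces the classical stationary density
`theta / i` for a constant-size population; the ancestral state is obtained
by iterating that chain to convergence. After the split the two populations
evolve independently (each with its own step size) unless migration couples
them, in which case a shared-step loop applies the deterministic first-moment
migration map `x1 <- x1 + M dtau (x2 - x1)` (mass redistributed linearly
between flanking grid classes) before each binomial step. Present-day grid
densities are projected to the sample sizes hypergeometrically. Step counts
and effective binomial sizes are capped in extreme parameter corners; those
corners are far from any optimum and the caps keep worst-case evaluations
bounded.

Four two-population models are parameterized explicitly (the protocol we
follow names them only in prose): IM `{nu1, nu2, tau_split, M}`; BIM
`{nu_b, tau_b, nu1, nu2, tau_split}`; SBR `{tau_split, nu1_b, nu2_b, tau_b,
nu1_r, nu2_r, tau_r}`; ISB `{nu_growth, tau_growth, tau_split, nu1_b,
nu2_b, tau_b1, tau_b2}` with both bottleneck onsets inside the split
(fitted as fractions of `tau_split` so the constraint holds throughout the
search). Sizes are relative to the ancestral diploid size, times are in
`2 N_ref` generations (converted to years only at reporting time via a
3-year generation), and `M = 2 N_ref m`.

Optimization is multi-start Nelder-Mead in log10-parameter space: a pool of
random candidates (plus deterministic coverage starts spanning the no-,
moderate- and deep-bottleneck regimes) is screened with a single likelihood
evaluation; the best few are optimized with restarts (a single Nelder-Mead
pass rarely converges in 5-7 dimensions); optional basin hopping perturbs
the incumbent optimum by log-normal factors and re-optimizes, which escapes
the ridge-shaped competing optima that bottleneck likelihoods are prone to.
Everything is deterministic given the seed. Model comparison ranks by
log-likelihood and runs chi-square likelihood-ratio tests only for pairs
explicitly declared nested; parameter variance comes from a block bootstrap
(1-Mb blocks by default) that respects linkage within blocks.

### Identifiability and the recovery experiment

A 9 x 7 joint AFS from 8 + 6 haploid genomes carries very unequal
information about the ISB parameters. A Fisher-information analysis at the
simulation truth shows the ancient-epoch parameters (`nu_growth`,
`tau_growth`, `tau_split`) have Cramer-Rao relative standard errors far
above 100 % at this sample size — they are structurally unidentifiable and
no estimator can recover them reliably — while the four bottleneck
parameters (`nu1_b`, `nu2_b`, `tau_b1`, `tau_b2`) are well conditioned when
the bottlenecks are long enough to accumulate both drift and new mutations.
The package's recovery experiment therefore evaluates the bottleneck sizes
and onset times, at a truth chosen for identifiability (moderate
bottlenecks of relative size 0.2/0.1 lasting 0.2/0.1 scaled time units),
and simulates cohorts as many short loci (350 bp) so that the realized AFS
is close to the independent-sites regime the composite likelihood assumes.
With long loci, shared genealogies overdisperse the AFS several-fold
relative to Poisson, and the extra scatter is absorbed into exactly the
soft bottleneck-severity direction of the likelihood surface.

## Branch Dn/Ds

The published analysis used codon maximum likelihood; divscan deliberately
replaces that engine with transparent counting machinery whose every step
is unit-testable: Fitch parsimony reconstruction of ancestral sequences per
nucleotide column (ties broken deterministically in A < C < G < T order and
reported as a tie fraction), followed by Nei-Gojobori (1986) counting of
synonymous/nonsynonymous sites and differences on every branch
(parent-child pair), with multi-step codon differences averaged over
stop-free minimal pathways and optional Jukes-Cantor correction. Site
totals are counted on the child sequence, so `N + S = 3 x codons` exactly
on every branch. Numerical agreement with codon-ML software is expressly
not a goal; the bootstrap-distribution design of the original figure is
preserved (codon-column resampling of the concatenated supergene, with
per-column attributions precomputed so each replicate is a resampled sum).

The per-gene foreground test uses the statistic
`T = omega_foreground - omega_background` (background counts pooled over
all non-foreground branches; pooling keeps short internal branches from
destabilizing the ratio). The default null construction is a percentile
codon-column bootstrap: resample columns, recompute `T`, and report
`p = (1 + #{T* <= 0}) / (B + 1)` — the position of zero in the bootstrap
distribution of the elevation. The percentile form was chosen over two
alternatives that calibrate poorly here: per-column label permutation runs
anticonservative when branch lengths are very unequal (permuted foreground
columns inherit the longer branches' counts), and the recentred "basic"
bootstrap collapses under the strong right-skew that small synonymous
counts induce in omega ratios. The permutation variant is retained as an
option and is exact for equal branch lengths. Branches with zero
synonymous differences are handled by a synonymous pseudocount (0.5 by
default) or excluded, and the choice is recorded in the result. Genes whose
foreground omega exceeds every other branch are flagged, mirroring the
pre-screen of the original workflow.

The codon simulator is a Goldman-Yang-style process (target-frequency
proportional rates, `kappa` for transitions, branch-specific `omega` for
nonsynonymous exchanges, stop codons excluded from the state space) run by
Gillespie simulation, so realized per-branch synonymous/nonsynonymous
substitution counts are recorded exactly. Default branch lengths on the
five-taxon tree (dog outgroup, then human, then cheetah vs cat + tiger)
are of felid-comparative magnitude (0.01-0.2 expected substitutions per
codon).

## Gene families

Edges connect genes when strictly more than 1/3 of each gene aligns, with
weight `Hscore = 100 sc(G1, G2) / max(sc(G1, G1), sc(G2, G2))` where `sc`
is the bit score. The x100 scaling is a deliberate reading: the formula as
usually printed is a ratio at most 1, while the stated range 0-100 and the
threshold of 5 only cohere on the percent scale. Clustering is constrained
average-linkage agglomeration: merge the pair with the highest mean
inter-cluster Hscore, refusing merges at or below Hscore 5, below edge
density 1/3, above 500 members, or into a family that already contains an
outgroup gene (a lone outgroup gene may still be absorbed, after which its
family stops growing — the reading under which outgroup genes can
delimit families at all). Ties break on the lexicographically smallest
member, making results independent of record order. Whether the aligned
fraction refers to full gene length or alignable region is ambiguous in the
source protocol; full gene length is assumed and the threshold is a
parameter.

## The synthetic-data module

`simulate_two_pop_cohort()` is an event-driven structured coalescent
(piecewise-constant sizes, symmetric migration, compiled inner loop) over
independently segregating loci with infinite-sites mutations; ancestral
alleles are known by construction, so polarization is exact.
`simulate_depth_track()` draws per-position read starts as Poisson (or
negative binomial) with mean scaled by true local copy number over 2, zero
in assembly gaps; "depth" is per-position read starts throughout, since the
SD caller consumes window sums only. `planted_genome()` writes tandem
motifs and a small library of interspersed elements (each copied to several
locations, so k-mer over-masking sees genuinely repeated text), records the
truth for masks, gaps and copy-number gains. `simulate_similarity_graph()`
emits all-vs-all bit-score records with planted family structure.

The mutation rate is interpreted per generation inside all simulators; a
per-year rate (the default 0.3e-8, a cross-species divergence estimate) is
converted via the generation time (3 years), because the source protocol
uses the rate alongside a 3-year generation time without stating its units.
Both interpretations are available through `mutation_rate_units`.

What the generator does *not* emulate: sequencing error, read-level
artifacts, alignment and calling bias, indels or structural variants other
than planted copy-number gains, linkage beyond locus-level tree sharing,
GC-content or mappability covariates of depth. Passing tests therefore
demonstrate correctness of the analytical machinery under the stated
statistical models, not robustness to real-data artifacts.

## Problem sizes and numerical defaults

The experiments the test-suite runs use these sizes, chosen as desk-scale
study conditions: diversity and ROH checks on 0.1-1 Mb toy scaffolds; SD
calling on a 5-Mb two-scaffold genome at 10x with six planted duplications
of copy number 4/6/8 and 25-40 kbp length, plus twenty 1-Mb duplication-free
genomes for specificity; the neutral-limit spectrum at grid size 200 against
120 simulated cohorts; demographic recovery on ten cohorts of 35 Mb in 1e5
loci (about 7e4-1e5 segregating sites each) with full four-model comparison
on three of them; selection-scan calibration on 200 null replicates of 300
codons and power on twenty replicates of 1500 codons; family recovery on
planted graphs of 12-18 genes. Fitting uses grid size `4 x max(n1, n2)`,
5 screened Nelder-Mead starts with restarts, and 12 basin hops for the
seven-parameter ISB model.

## Known limitations

* The grid expectation carries O(1/G) discretization error; marginals agree
  with coalescent simulation to about 1-2 % at G = 64. Parameter estimates
  absorb residual family error, which is why recovery tolerances are
  meaningful at the tens-of-percent, not percent, level.
* Composite-likelihood p-values and bootstrap variances assume free
  recombination between SNVs; with long loci they are anticonservative.
* Fitch parsimony under-counts substitutions on long branches; the Dn/Ds
  ratios are therefore counting estimates, not ML estimates, and agreement
  with codon-ML software is out of scope.
* The ISB ancient-epoch parameters are reported but should not be
  interpreted at these sample sizes (see identifiability above).
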