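---
title: "Models and methods behind popgenpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind popgenpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

popgenpipe reimplements, as one tested pipeline, the inference chain used
in genome-wide SNP studies of population structure and recent selection:
genotype quality control, pairwise Weir–Cockerham $F_{ST}$, LD-based
effective-population-size ($N_e$) histories, $F_{ST}$/$N_e$-based
divergence times summarised as a UPGMA tree, and a cross-population
XP-EHH selection scan with a joint XP-EHH/$F_{ST}$ candidate-region
caller. A forward Wright–Fisher simulator with recombination, population
splits and hard sweeps provides ground-truthed data for validating every
stage. This vignette records the models, the parameters that matter, and
the design decisions taken where the methods literature leaves choices
open.

## Quality control

Samples and variants are filtered in the order used by standard array-QC
tooling: sample missingness, then variant missingness, minor allele
frequency, and the Hardy–Weinberg exact test (`filter_variants()`,
defaults: missingness > 10%, MAF < 0.01, HWE $p < 10^{-4}$). The HWE
test conditions on the observed allele counts and sums the probabilities
of all heterozygote configurations no more probable than the observed
one (the standard two-sided exact test; no mid-$p$ correction).

LD pruning (`ld_prune()`) slides a 200-variant window stepping 25
variants; within a window, while any pair of retained variants has
genotype-dosage $r^2 > 0.4$, the pair with the highest $r^2$ loses its
lower-MAF member (tie: the later position). Pair order and tie-breaking
are not specified by the tools this mirrors; the highest-$r^2$-first rule
was chosen because it is deterministic and order-independent.

Relatedness uses the KING-robust between-family estimator
$$\hat\varphi = \frac{N_{het,het} - 2N_{opp}}{2\min(N^i_{het}, N^j_{het})}
  + \frac12 - \frac{N^i_{het}+N^j_{het}}{4\min(N^i_{het}, N^j_{het})},$$
computed within population labels only. Pairs above the configurable
threshold (default 0.0084, a published study setting that approximately
flags 2nd-degree and closer relatives on large SNP panels) are resolved
greedily: the member with more over-threshold partners is dropped, ties
broken by higher missingness, then later sample order. Note that on
small panels (a few thousand SNPs) the sampling noise of $\hat\varphi$
exceeds 0.0084, so analyses of small simulated panels should raise the
threshold; the pipeline exposes it in `qc_config()`.

## Weir–Cockerham $F_{ST}$

`wc_fst_locus()` implements the two-population variance components
$a$ (between populations), $b$ (between individuals within populations)
and $c$ (within individuals) of the Weir–Cockerham (1984) estimator,
with $\theta = a/(a+b+c)$; genome-wide estimates are the ratio of sums
$\sum_\ell a_\ell / \sum_\ell (a+b+c)_\ell$. Per-locus $\theta$ may be
negative; pairwise matrix entries are clamped to zero only where they
feed the logarithmic divergence formula, and raw values are preserved in
the output.

Per-SNP $F_{ST}$ "p-values" for the region caller are upper-tail
empirical ranks against the genome-wide per-locus distribution
(`fst_empirical_pvalues()`): assumption-free, inclusive of the locus
itself, and threshold-compatible with a $p < 0.01$ rule when at least
1000 loci are defined (a warning is raised below that).

## $N_e$ from linkage disequilibrium

Mean dosage $r^2$ is accumulated within sliding recombination-distance
categories of width 0.005 cM stepping 0.001 cM from 0.005 to 0.25 cM
(246 categories; `make_bins()`); a SNP pair contributes to every
category containing its cM separation, and pairs enter only if both SNPs
have MAF ≥ 0.05 (configurable). Each category is inverted through
$$E[r^2] = \frac{1}{\alpha + 4N_ec} + \frac{1}{n},$$
with $c$ the category midpoint in Morgans and $n$ the diploid sample
size, giving $\hat N_e = (1/(\bar r^2 - 1/n) - \alpha)/(4c)$ and an
epoch of roughly $1/(2c)$ generations ago. The 95% CI propagates
$\bar r^2 \pm 1.96\,\mathrm{se}$ through the same inversion. Long-term
$N_e$ is the harmonic mean over categories with a defined estimate.

Two points deserve emphasis:

* **The constant $\alpha$.** $\alpha = 2$ (the mutation–drift form
  commonly applied to array data) is the package default; $\alpha = 1$
  (the drift-only form) is selectable. On data from the package's own
  simulator — which models standing variation only, with no mutation —
  the drift-only form is the correct one, and the validation experiments
  use it. On real SNP-array data at these time depths the default is
  appropriate.
* **Epoch coverage.** A category at distance $c$ reflects ancestry
  roughly $1/(2c)$ generations back. If the analysed history is shorter
  than that (in simulations: the burn-in before sampling; in real data:
  e.g. a founding bottleneck), those categories estimate the older
  regime instead. The parameter-recovery experiments therefore restrict
  the grid to categories with $1/(2c)$ within the simulated history;
  with the default grid the harmonic mean would otherwise be inflated by
  categories that "see" the linkage-equilibrium founder pool, and the
  effect grows as the analysed $c$ range maps to epochs beyond the
  burn-in (so it is strongest for small $N$ at fixed grid).

## Divergence times and the UPGMA tree

Under pure drift, $F_{ST}$ between two isolated populations of constant
size $N_e$ satisfies $F_{ST} = 1 - (1 - 1/(2N_e))^T$ after $T$
generations; `divergence_time()` inverts this as
$T = \ln(1-F_{ST})/\ln(1-1/(2N_e))$, and years use a 25-year generation
by default. For a population pair, the $N_e$ entering the formula is the
harmonic mean of the two long-term estimates — the combination rule is
an interpretation (the source methods pass "the $N_e$ values" without
stating one) and is flagged as such. Negative $F_{ST}$ estimates are
clamped to zero first, mapping to $T = 0$.

`upgma()` is a from-scratch average-linkage agglomeration: join the
closest pair (ties: lexicographically smallest pair of cluster labels,
a cluster labelled by its smallest leaf), place the node at half the
join distance, update distances by size-weighted averaging. The output
is ultrametric by construction and serialised as Newick with branch
lengths in years (matching the years-before-present framing of the tree
figure it reproduces); the time unit affects scale only, not topology.

## XP-EHH and the candidate-region caller

EHH from a core SNP is the probability that two random haplotypes from a
population are identical at every SNP from the core out to a given
extension; the core's own alleles are pooled (the partition starts as a
single group), as the cross-population statistic requires. `ihh()`
integrates EHH over cM by the trapezoid rule in both directions,
truncating a direction where the EHH of the *pooled* target+reference
haplotype set drops below 0.05 (that segment is included), at inter-SNP
gaps over 200 kb, or at the chromosome end; the cutoff and gap bound
follow the documented defaults of the standard scanning tool. The score
is $\ln(\mathrm{iHH}_{target}/\mathrm{iHH}_{ref})$, normalised
genome-wide to mean 0, sd 1; positive values mean unusually long
haplotypes in the target. SNPs below pooled MAF 0.05 or with an
undefined ratio are skipped and counted, and normalisation is refused
below 100 scored SNPs.

Candidate regions require two or more SNPs that are simultaneously in
the top 0.1% of the empirical score distribution and above score 2
(both printed thresholds applied conjunctively), clustered at up to
500 kb gaps, and the spanned interval must contain at least one SNP
(top or not) with empirical $F_{ST}$ $p < 0.01$. The clustering window
is a design choice — "genomic region" is not defined by the source
methods; published spans of 55 kb–2 Mb are consistent with sub-Mb
clustering — and is exposed in `scan_config()`. One consequence of the
pooled-EHH truncation worth knowing: directly at a completed sweep the
reference iHH integrates over a longer stretch (the pooled EHH stays
high), so the score profile often dips slightly at the swept site and
peaks on both flanks. On maps where 1 cM ≈ 1 Mb, a 1 Mb clustering
window (matching the ±1 cM localisation scale of the validation
experiments) joins the two flanks; the sweep-detection experiments use
that setting.

## The forward Wright–Fisher simulator

`simulate_panel()` runs a diploid, discrete-generation Wright–Fisher
model: each offspring draws two parents uniformly (fitness-weighted
1 : 1+s : 1+2s at the swept locus during a sweep), and each transmitted
gamete recombines with a Poisson number of crossovers per chromosome
(rate = map length in Morgans) at positions uniform in cM. Loci are
placed uniformly on a 1 cM/Mb map. Founder haplotypes are drawn
site-independently with frequencies from Uniform(0.05, 0.5) — linkage
equilibrium — and realistic LD builds up during a burn-in before the
first split. Populations split by copying the parental pool and evolve
independently (no migration, no mutation: standing variation only).
Monomorphic-at-sampling loci are dropped. Identical seeds give
byte-identical output; a sweep whose allele fails to reach its
configured final frequency is retried on a derived seed up to 25 times
(conditioning on establishment).

Sweeps are *hard* by construction: at the sweep's start generation the
chosen locus is set to its start frequency and all initial carriers
share a single ancestral haplotype over the sweep chromosome, modelling
a single-origin allele that has just escaped early stochastic loss;
recombination during the sweep then erodes the shared tract. Without
this, carriers drawn on 2Nf distinct backgrounds would constitute a
soft sweep with a much weaker haplotype signal.

Because variation is standing-only, heterozygosity decays as
$e^{-t/(2N)}$ during a burn-in of length $t$: the nominal default of
$10N$ generations would erase nearly all polymorphism, so practical runs
truncate it (a warning notes that ancestral LD may not be fully
equilibrated). The validation experiments use $2N$: long enough that
$r^2$ at the analysed distances approaches its quasi-stationary level,
short enough that over a third of founder loci remain usable.

## What the synthetic data do and do not show

The generator reproduces the features the statistics consume — drift at
known $N_e$, known split times, recombination on a known map, LD decay
with distance, and single-origin sweeps — so passing tests demonstrate
that the estimators recover known truth under their own model
assumptions. It does not emulate mutation, migration/admixture,
demographic growth, genotyping error, array ascertainment, or phasing
error; agreement here does not certify behaviour of any one real
dataset, where those processes are present.

## Problem sizes and numerical choices

The validation experiments are sized for a desk-scale run: drift
calibration uses two populations of $N = 1000$ split 100 generations,
with about 12,000 segregating SNPs, over 10 seeds; $N_e$ recovery uses
$N \in \{200, 1000\}$ with 100 sampled diploids, 20 chromosomes of
50 cM and over 20,000 segregating loci, 5 seeds each; divergence-time
recovery uses 10 replicates of the split design with about 11,000 loci;
sweep detection uses 10 replicates of a 4-chromosome genome with about
10,000 scored SNPs. The Wright–Fisher generation step, binned $r^2$
accumulation and the EHH scan are implemented in C++ (via Rcpp) with
bit-packed haplotype storage internally.

Degenerate inputs are handled explicitly: monomorphic sites give HWE
$p = 1$ and undefined $F_{ST}$ components; categories with fewer than
50 SNP pairs, or whose adjusted $r^2$ inverts to a non-positive $N_e$,
are flagged unusable and excluded from the harmonic mean; CI endpoints
that fail to invert become 0 or $\infty$; empirical p-values are
inclusive ranks so $p \in (0, 1]$; UPGMA ties are broken
lexicographically for determinism.

## Known limitations

* The $F_{ST}$ p-value is an empirical genome-wide rank, not a sampling
  p-value; it measures outlyingness, not significance.
* Long-term $N_e$ inherits the biases of the $E[r^2]$ inversion: the
  $\alpha$ form must match the data's mutation regime, and categories
  indexing epochs outside the data's history estimate the older regime
  (see above).
* The divergence formula assumes pure drift in isolated populations of
  constant size; migration or growth biases $T$.
* Phased input is assumed for the scan; phasing is out of scope.
* The simulator's founder spectrum is uniform, not a stationary
  frequency spectrum, and there is no mutation; very long burn-ins are
  therefore not meaningful.
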