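---
title: "Methods: diversity, LD and linkage-phase persistence in structured random-mating populations"
author: "popldiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, LD and linkage-phase persistence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`popldiv` implements the statistical toolkit used to compare *within-* and
*across-population* sampling strategies for panels of open-pollinated crop
populations (landraces): genetic diversity, analysis of molecular variance,
population structure, linkage disequilibrium (LD) decay, and persistence of
linkage phase. All statistics operate on a single container, the
`pop_panel`: an individuals x markers matrix of alt-allele dosages in
{0, 1, 2} with missing calls, an ordered marker map (1-based physical
positions, VCF convention), a sample-to-population assignment, and — for
phased data — the underlying gametes. LD and phase statistics work on
gametes (`hap_set`), extracted with `panel_haplotypes()`; a missing
genotype call masks both of an individual's gametes.

Because the real datasets this methodology targets are large external
downloads, the package ships a forward Wright–Fisher generator
(`simulate_panel()`) that produces panels with *known truth*, so that every
downstream statistic is testable end to end. The test-suite and the
acceptance script run entirely on such synthetic panels.

# The synthetic-population generator

The model is deliberately transparent rather than maximally realistic:

1. **Standing variation.** SNP positions are uniform (without ties) on each
   chromosome. Ancestral allele frequencies are drawn from a density
   proportional to $1/x$ truncated to $[1/(2N_a), 1-1/(2N_a)]$
   ($N_a$ = `ancestral_Ne`), the shape of the neutral equilibrium
   spectrum. An ancestral pool of $2N_a$ gametes is drawn per site.
2. **Optional ancestral burn-in** (`ancestral_generations`, default 0): the
   pool is evolved by random mating with recombination before the split.
   With the default 0 the pool is in linkage equilibrium; a positive value
   builds *shared ancestral LD*, which is the truth model behind
   between-population linkage-phase persistence. Real landraces share such
   LD, so the LD/phase experiments use a burn-in of 150 generations at
   $N_a = 100$; experiments about the site frequency spectrum use no
   burn-in so the spectrum stays neutral.
3. **Split and drift.** The pool splits into `n_pops` isolated populations
   of diploid size $N_e$ (`within_pop_Ne`) that mate randomly for $t$
   (`split_generations`) generations. Crossovers per gamete and chromosome
   are Poisson with rate `recomb_rate_per_bp * chrom_length_bp`, positions
   uniform; selfing can be forced with probability `selfing_rate` per
   offspring. No mutation, migration or selection after the split.
4. **Sampling.** `n_ind_per_pop` diploid individuals are drawn per
   population (phased output), missingness is applied i.i.d., optional
   array-style ascertainment drops SNPs whose minor-allele frequency in a
   discovery subset of 8 individuals (spread round-robin across
   populations) falls below `ascertainment_maf`, and sites fixed in the
   drawn panel are removed.

**Calibration of the defaults.** Pure drift gives an expected
identity-by-descent coefficient $F = 1 - (1 - 1/(2N_e))^t$. Two-level
AMOVA on *individual-level* squared modified Rogers' distances has
within-population component $\bar p \bar q (1-F)/2$ (half, because the
within-individual variance is averaged into the individual values) and
among-population component $F \bar p \bar q$, hence an expectation
$$\Phi_{ST} = \frac{2F}{1+F},$$
while the gamete-level Weir–Cockerham $\theta$ estimates $F$ itself. The
default `sim_config()` uses $N_e = 50$, $t = 17$, so $F \approx 0.157$ and
$\Phi_{ST} \approx 0.27$ — the differentiation regime of a European
landrace panel. Both expectations are stored in the truth record
(`expected_fst`, `expected_phi_st`) and each estimator is tested against
its own expectation. The default genome (5 chromosomes of 5 Mb, 400 SNPs
each, recombination $10^{-8}$/bp) yields within-population LD decaying
over hundreds of kb; 2% of calls are set missing.

What the generator does **not** emulate: real array ascertainment schemes
(ours is a single-threshold discovery panel), imputation artifacts,
within-landrace family structure or migration between landraces, variable
recombination along chromosomes, and new mutations after the split.
Passing tests therefore show correctness of the *statistics* under a
clean drift model, not robustness to every property of real data.

# Statistics

## Folded site frequency spectrum

For a sample of $g$ gametes the neutral expectation of the unfolded
spectrum is $E[f_i] \propto 1/i$, normalized by the harmonic number
$\sum_{j<g} 1/j$; folding adds classes $i$ and $g-i$ for $i < g/2$
(`expected_neutral_sfs()`). The empirical spectrum (`folded_sfs()`)
follows the resampling design of the study datasets: per SNP and repeat,
$g = \lfloor 2nc \rfloor$ gametes are drawn uniformly *without
replacement* among the gametes with non-missing calls ($c$ = the
dataset's minimum call rate), and the minor allele is counted within the
drawn sample (ties at $g/2$ go to the $g/2$ class). The alt-allele count
of such a draw is exactly hypergeometric, so the draw is realized with
`rhyper` — equivalent in distribution, and validated in the tests against
exhaustive enumeration of all $\binom{k}{g}$ subsets on toy data.
Because "averaging the number of minor alleles over repeats" is ambiguous,
both poolings are exposed: `method = "mass"` (default) accumulates each
draw's indicator mass; `method = "round"` rounds each SNP's mean minor
count to a class. They agree in expectation; mass accumulation avoids an
arbitrary rounding rule. Spectra are compared by total-variation distance
on the polymorphic classes after renormalization (`sfs_tv_distance()`).

## Diversity

* `proportion_polymorphic()`: share of markers with at least two alleles
  among non-missing calls.
* `nucleotide_diversity()`: per marker with $k$ callable gametes and
  alt frequency $p$, $\pi = \frac{k}{k-1} 2p(1-p)$ — the unbiased
  mean pairwise difference (equal to the average mismatch over all gamete
  pairs, which is the test oracle). Monomorphic markers contribute 0;
  markers with fewer than 2 callable gametes are excluded and counted.
* `haplotype_heterozygosity()`: windows of 100 kb (default) anchored at
  every SNP, half-open $[s, s + w)$, skipped below 5 SNPs; within a
  window the haplotype classes are the distinct allele strings among the
  $k$ gametes with *complete* calls, and
  $H = \frac{k}{k-1}(1 - \sum_c x_c^2)$. Complete calls are required
  because the statistic is defined on observed haplotypes; imputed panels
  satisfy this trivially.
* `fis()`: multi-locus Weir–Cockerham (1984) within-population $f$, the
  ratio of summed locus-wise between-individual components $b$ to
  $b + c$ ($c$ = half the heterozygote frequency). Significance comes
  from re-pairing the population's $2n$ gametes into $n$ genotypes
  uniformly at random (the natural Hardy–Weinberg null; the permuted unit
  is the gamete). For unphased panels each heterozygote's alleles are
  assigned to its two gamete slots at random under the seed — a fixed
  orientation would fabricate across-locus association among the
  constructed gametes and overdisperse the permutation distribution. The
  p-value is two-sided with +1 smoothing.
* `wc_fst()`: the standard multi-population Weir–Cockerham $\theta$
  (ratio of sums over loci), used for parameter recovery against the
  drift expectation.

## AMOVA and the variance-capture experiment

`amova()` implements the one-level decomposition on squared distances:
$SS_{total} = \frac1N \sum_{i<j} d_{ij}^2$, the within term with
per-population $\frac{1}{N_p}$ weights,
$\sigma_w^2 = SS_w/(N-P)$,
$\sigma_a^2 = (SS_a/(P-1) - \sigma_w^2)/n_0$ with
$n_0 = (N - \sum_p N_p^2/N)/(P-1)$, and
$\Phi_{ST} = \sigma_a^2/(\sigma_a^2 + \sigma_w^2)$. Distances are the
squared modified Rogers' distances used everywhere else in the package.
A negative among-component is clamped to 0 *for the percentages* (the raw
value is also reported). The permutation test shuffles individuals among
populations with sizes fixed and counts $\Phi \ge \Phi_{obs}$ with +1
smoothing.

The capture experiment (`variance_captured()`) formalizes "proportion of
the total molecular variance captured by $l$ populations" as a
mean-squared-deviation ratio: per random group of $l$ populations,
$\frac{SS_{total}(\text{group})/(N_g-1)}{SS_{total}(\text{all})/(N-1)}$.
Populations are shuffled and chunked into $\lceil P/l \rceil$ groups; the
last group keeps the remainder, and all group values are pooled. The MSD
ratio is one defensible reading of an unstated quantity; an alternative
(1 minus the among-groups component) would differ mainly by the group's
internal differentiation. Note that with remainder groups much smaller
than $l$ the pooled mean need not increase monotonically in $l$; the
analysis therefore evaluates $l$ values that divide the number of
populations.

## Population structure

* `mrd()`: modified Rogers' distance,
  $\sqrt{\frac{1}{2m}\sum_m \sum_a (p_{xa} - p_{ya})^2}$ with
  within-individual allele frequencies in {0, 1/2, 1}, restricted per
  pair to markers non-missing in both; a pair with no shared markers is
  an error.
* `neighbor_joining()`: classical Saitou–Nei agglomeration written
  in-package so its tie-break (lowest node-creation index) and
  negative-branch handling (clamp to 0, deficit transferred to the sister
  branch, preserving the joined pair's path length) are deterministic and
  documented; reference implementations differ subtly in both. Output is
  an `ape` tree; the additive-tree tests check exact topology recovery.
* `pcoa()`: Gower double-centering of $-\tfrac12 d^2$, symmetric
  eigendecomposition, axes scaled by $\sqrt{\lambda}$; negative
  eigenvalues are reported and their axes omitted; axis signs are fixed by
  making the largest-magnitude loading positive.
* `mantel_test()`: Pearson correlation of the upper triangles; one-sided
  permutation p with simultaneous row/column shuffles and +1 smoothing.
* `procrustes_fit()`: the correlation-like statistic
  $\sqrt{1 - ss}$ with $ss = 1 - (\sum_i \lambda_i)^2 /
  (\mathrm{tr}X'X\ \mathrm{tr}Y'Y)$, $\lambda_i$ the singular values of
  $X'Y$ after centering. Reflections are allowed (full orthogonal
  group): the compared configurations are PCoA solutions whose axis signs
  are arbitrary.
* `ld_prune()`: sliding 50-SNP windows advanced by 5 SNPs; pairs scanned
  greedily in position order, and at $r^2$ above 0.8 the lower-MAF member
  is removed (tie: the later position). This is one concrete reading of
  the widely used windowed pruning approach; removal is global (a marker
  removed in one window stays removed). The pruned set is the intended
  input for external model-based structure software, which is out of
  scope here.

## Linkage disequilibrium

`pairwise_ld()` computes, per same-chromosome pair within 1 Mb (default),
the signed gametic correlation
$r = (p_{AB} - p_A p_B)/\sqrt{p_A(1-p_A)p_B(1-p_B)}$ over gametes
complete at both markers, with orientation fixed by the alt allele at both
markers — identical to the Pearson correlation of the two 0/1 gamete
columns, which is how it is computed; a brute-force haplotype-counting
oracle pins this in the tests. Pairs monomorphic in the sample are
skipped and counted (including them as zeros would be the alternative
reading; exclusion is used because $r$ is undefined there).

The decay of $r^2$ with physical distance $d$ is fitted by least squares
to the drift–recombination expectation
$$E[r^2](C) = \frac{10+C}{(2+C)(11+C)}
\left(1 + \frac{(3+C)(12+12C+C^2)}{n(2+C)(11+C)}\right),\quad C = \rho d,$$
with $n$ the number of sampled gametes and $\rho \ge 0$ per bp the single
free parameter (`hill_weir_fit()`). The curve decreases from
$\frac{10}{22}(1+\frac{36}{22n})$ at $C=0$ to the sampling floor $1/n$.
The SSE profile is scanned on a dense grid in $\log_{10}\rho \in
[-12, -2]$ (which covers the multi-start range) and refined by
golden-section search in the bracketing interval; a profile that stays
flat to the lower grid edge means no decay is detectable at these
distances. Fewer than 50 informative pairs, or pairs at a single
distance, are errors. `decay_distance()` solves $E[r^2](\rho d) = 0.2$
(default threshold) by root bisection on $(0, 10\ \mathrm{Mb}]$;
uniqueness follows from monotonicity. Two flags cover the edges: curve at
the origin already below the threshold (distance 0, `below_threshold`),
and asymptote $1/n \ge$ threshold or no crossing by 10 Mb
(`reached = FALSE`).

Sampling designs: `sampling_scheme_ld()` draws $l$ populations and $g$
gametes per population (cells with $gl < 12$ skipped), fits with
$n = gl$, and averages decay distances over repeats;
`sample_size_ld()` varies the number of individuals within one
population; `interchromosomal_ld()` samples 24 individuals from $l$
populations, bins SNPs by sample MAF in steps of 0.05 (drawing a fixed
number per bin per chromosome so the allele-frequency profile is matched
across designs; underfilled bins are skipped), records the fraction of
cross-chromosome pairs with $r^2 > 0.2$, and the experiment wrapper
compares every $l > 1$ against $l = 1$ with a two-sided Wilcoxon
rank-sum test, Bonferroni-corrected. The number of individuals must be a
multiple of $l$ (the studied designs use divisors of 24).

## Persistence of linkage phase

`phase_persistence()` takes two gamete sets over an *identical* marker
list (intersect the panels first; allele orientation is anchored to the
shared alt allele). Same-chromosome pairs within 1 Mb that are
polymorphic in both populations are binned by distance in 10-kb half-open
bins; each bin reports the Pearson correlation of the signed $r$ values
and PEP, the proportion of pairs with equal sign of $r$. Pairs with
$r = 0$ in either population are excluded from PEP (their count is
reported) — counting them as half-agreements would be the arbitrary
alternative. Pooled whole-range summaries are also returned since both
per-bin and pooled views are in use. `split_half_persistence()` is the
within-population control: individuals are split uniformly into two
halves (sizes differ by at most 1), the two halves are compared, and
per-bin statistics are averaged over repeats.

# Pipeline, seeds and determinism

Every stochastic operation takes an explicit integer seed and runs under
`withr::with_seed`, leaving the session RNG untouched. `run_pipeline()`
executes stages from a single config (R list or YAML), validates analysis
parameters against stage preconditions before any computation, derives
per-stage seeds by a stable string hash of the stage name combined with
the master seed (`derive_seed()`; adding a stage never perturbs the
others), writes per-stage TSV/JSON plus a manifest (package version,
config hash, seeds), and a JSON-lines log of filter counts and stage
events. Reruns under the same config are bit-identical; the tests verify
this by hashing every output file.

# Problem sizes

The suite and `scripts/acceptance.R` use panels of 10 populations x 24-48
individuals x 2000-2400 simulated SNPs, 200-1000 resampling repeats for
spectra and capture curves, 10-20 repeats for LD sampling designs, and
99-199 permutations inside the tests (999 in the analysis scripts). These
sizes give stable estimates of every pattern of interest on a single CPU
in minutes; they are the package's chosen study scale, scaled down from
the original panels (35 landraces, 5 x 10^5 SNPs) whose download is out of
scope.

# Known limitations

* The generator's truth holds for its drift model; the AMOVA calibration
  $\Phi_{ST} = 2F/(1+F)$ assumes individual-level genotype distances and
  random mating within populations.
* The capture-curve statistic exceeds 1 slightly in degenerate cases
  (identical populations) because group and panel mean-squared deviations
  use different degrees of freedom.
* Strand conflicts between datasets are resolved only as ref/alt swaps in
  `intersect_panels()`; A/T and C/G markers are intersected like any
  other, as no strand-reconciliation procedure is defined for these
  panels — real array/GBS merges should pre-filter ambiguous markers.
* `hill_weir_fit()` fits a single equilibrium curve; non-equilibrium LD
  (recent admixture, bottlenecks) is absorbed into $\rho$, which is then
  a descriptive, not a demographic, parameter.
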