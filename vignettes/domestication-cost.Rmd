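---
title: "Measuring the genomic cost of domestication: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the genomic cost of domestication: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`domcost` implements the computational chain used to study the "cost of
domestication" in a wild/domestic species pair such as red jungle fowl and
domestic chicken: forward simulation of the two populations under a
domestication-bottleneck demography with deleterious coding mutations;
codon-aware variant annotation with an alignment-based deleteriousness
score; per-individual genetic-load accounting; windowed selective-sweep
scans; and two-population joint-SFS demographic inference with AIC model
selection and block-bootstrap confidence intervals.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and the limits of what the synthetic
experiments can demonstrate.

# The forward simulator

`simulate_two_population()` runs a discrete-generation Wright–Fisher model:

* **Mutation.** Infinite sites over an annotated contig: every position
  carries at most one segregating mutation; positions of lost mutations are
  freed for reuse, positions of fixed mutations stay blocked (a few hundred
  sites per run, a negligible fraction of the contig). A new mutation's
  class is determined by the genome layout: translating the affected codon
  on the annotated strand classifies it as synonymous, missense or
  nonsense; everything outside CDS is noncoding.
* **Selection.** Non-synonymous mutations draw a fitness cost `s` from a
  gamma distribution (shape 0.2, mean 0.01 by default) and act with
  dominance `h = 0.25`; genotype fitnesses are `1`, `1 - h s`, `1 - s`,
  multiplicative across loci. Synonymous and noncoding mutations are
  neutral. These DFE values are stand-ins chosen from typical vertebrate
  estimates — the study system provides no measured DFE — and are exposed
  as configuration knobs, not presented as claims.
* **Demography.** A burn-in of `burnin_factor * N_anc` generations
  (default 10 ancestral population sizes) precedes the split; afterwards
  each population follows piecewise-linear size epochs with constant
  asymmetric migration (an individual is replaced by a migrant with
  probability `m` per generation). Viability selection, migration and
  multinomial resampling complete each generation.
* **Recombination** is uniform crossover with probability `rec_rate` per
  adjacent-base boundary (no gene conversion, single contig).
* **Outgroup.** Polarization only needs a divergent outgroup's alleles, so
  the outgroup is simulated as Poisson(`outgroup_divergence * L`) fixed
  substitutions on an independent branch and emitted as identical
  homozygous diploids; shared ancestral polymorphism is deliberately
  ignored. Outgroup substitutions that hit a focal segregating site
  produce realistic mispolarization or unpolarizable (third-allele) sites.

## The `fig1d_model3` demography preset

The default demography encodes the published two-population history of
chicken domestication (1 generation = 1 year): split 12,300 generations
ago; the wild population expanding slightly to 257,000 until 10,300
generations ago, then contracting to 154,000; the domestic population
declining from 138,000 at the split to 52,000 until 6,990 generations ago
(the domestication bottleneck), then recovering to 152,000. Two values are
not pinned down by the published point estimates and were fixed once here:
the pre-split ancestral size (200,000 diploids, between the two post-split
starting sizes) and migration (symmetric, `2*N_anc*m = 1`; admixture
between domestic flocks and sympatric jungle fowl is pervasive but weak on
this timescale).

## Rescaling

`rescale(config, Q)` divides population sizes and epoch times by `Q` and
multiplies mutation, recombination, selection and migration rates by `Q`,
preserving the population-scaled compounds `4*N*mu`, `N*s`, `N*m` and
`t/N` exactly; selection coefficients that exceed 1 after rescaling are
clipped (an effectively lethal mutation stays lethal). Clipping distorts
only the strongly deleterious tail that never segregates, but it is the
reason strong positive selection cannot be rescaled aggressively: a sweep
with natural `s = 0.05` cannot be represented at `Q = 1000`. Desk-scale
experiments therefore run the bottleneck preset at `Q = 1000` (where all
analysed dynamics are weak-selection) and use separate small-population
configurations for sweep experiments.

## What the simulator does not emulate

Sequencing error and missing genotypes (the generator emits full calls;
the readers and statistics handle missingness for real data), X/Z
chromosomes, gene conversion, epistasis, balancing selection, and —
important for interpreting the load results below — population
substructure and recent admixture within the domestic pool.

# Variant annotation

`classify_coding_effect()` translates the affected codon on the annotated
strand with the standard genetic code (stop gains are `nonsense`,
stop-loss changes are grouped with `missense`). The deleteriousness score
(`delta_score()`) follows the alignment-delta construction of
conservation-based predictors: for each supporting homolog, the semi-global
affine alignment score (BLOSUM62, gap open 10, extend 1, free end gaps on
the homolog side) of the variant protein minus that of the reference
protein, averaged over the homolog set. Homolog sets here are synthetic
(`make_homologs()`: the reference protein mutated at a configurable
per-residue rate), a documented stand-in for a database search: the score's
alignment mechanics and its conservation logic are preserved — a slowly
diverged homolog set penalises substitutions more — but absolute score
distributions are not comparable to scores computed against real protein
databases. A variant is a high-impact SNP (hSNP) when its score is at or
below the threshold, default -2.5 with the boundary included.

Polarization uses the outgroup genotypes only: fixed-reference outgroup
means the reference allele is ancestral, fixed-alternate means the
alternate is; polymorphic, missing or third-allele outgroups leave the
site unpolarized, and unpolarized sites are excluded from all
derived-allele statistics.

# Load statistics

`individual_load()` counts derived deleterious and synonymous alleles per
individual with het/hom partitions; the additive convention (het + 2*hom)
operationalises "more hSNPs per genome" (the per-site count of carried
hSNP sites is also reported). Population summaries use means of
per-individual values; the heterozygous-deleterious fraction is reported
both as the mean of per-individual fractions (primary) and pooled.
`compare_groups()` is a two-sided Mann–Whitney rank-sum test — exact by
enumeration when the pooled sample is at most 12 and tie-free, otherwise
the normal approximation with tie and continuity corrections. The source
analyses label this unpaired comparison a "Wilcoxon signed-rank test"; the
unpaired rank-sum test is what the design supports, and that is what is
computed.

# Sweep scan

Per-site diversity is `2a(n-a)/(n(n-1))`; windows (default 50 kb sliding
by 25 kb) divide the summed site values by the full window length, which
matches the behaviour of the common windowed-pi tools (a callable-sites
denominator is available by flag but is only meaningful when callability
is tracked). Differentiation uses Hudson's FST estimator as the ratio of
summed numerators to summed denominators per window, clamped to [0, 1];
Hudson was chosen (over Weir–Cockerham) because it is least sensitive to
unequal sample sizes, the source publication does not name its estimator.
The locus-specific branch length is `(d_AB + d_AC - d_BC)/2` clamped at 0.
Sweeps are the top empirical-quantile windows (default 0.99 — the source
study defers its threshold to earlier work, so this is a knob), merged
when adjacent. The hSNP-in-sweep contrast relocates sweep regions
uniformly (lengths preserved) for its permutation null.

# Demographic inference

## Expected spectra

The default engine integrates the neutral two-population Wright–Fisher
diffusion forward from the ancestral mutation–drift equilibrium
(`phi = theta/x`), splits the density onto the plane as a diagonal ridge,
and evolves it under drift (`x(1-x)/(2 nu)` in time units of `2*N_anc`
generations), migration advection `m_ij (x_j - x_i)` with
`m` scaled as `2*N_anc*m`, and a constant low-frequency mutation source.
Numerics: finite volumes on a tanh-crowded frequency grid;
Scharfetter–Gummel exponential-fitted interface fluxes (positivity-
preserving at any migration strength, exactly central — and equilibrium-
exact — at `m = 0`); explicit advective escape terms at the loss and
fixation boundaries so alleles absent in one population re-enter by
migration at the physical velocity; implicit Euler with
alternating-direction splitting. Sampling onto `(n1+1) x (n2+1)` entries
uses binomial kernels with trapezoid quadrature, with the first and last
grid cells integrated analytically under a local `1/x` (resp. `1/(1-x)`)
density model; the monomorphic corners are masked. Spectra are exactly
linear in theta.

The engine was validated against closed forms (the `theta/i` equilibrium
marginal at any divergence time; the combined `theta/k` spectrum in the
no-divergence limit; the two-deme island model at high migration) and
against an independent event-driven structured-coalescent Monte-Carlo
engine (`engine = "coalescent"`), which remains available for
cross-checks.

## Models

Four nested parameterisations are fitted (sizes relative to `N_anc`,
times in `2*N_anc` generations, migration scaled by `2*N_anc`):
constant-size without (A) and with (B) asymmetric gene flow, and
growth/reduction with asymmetric flow where the sizes change linearly
from `nu` to `nuF` over the whole post-split epoch (C) or only over the
final fraction `rT2` of it (D). The published wording for its two
growth/reduction models is identical, so the C/D distinction here — one
extra epoch boundary — is this package's own resolution and is not
claimed to reproduce the original pair exactly. Linear (not exponential)
trajectories match the trapezoid-shaped histories of the simulator's
demography preset.

## Fitting

The composite likelihood treats sites as independent; theta is profiled
out analytically (`theta_hat = sum(data)/sum(model)`) and the multinomial
log-likelihood over unmasked cells is maximised (a Poisson mode is
available). Optimisation runs in log/logit-transformed space in three
rounds: log-uniform random multi-starts (a canonical mid-range start is
always included), perturbed restarts around the round-1 best, then a
polish that alternates a tight Nelder-Mead restart with a BFGS step using
numerical gradients — the fit engine uses a fixed number of time steps so
the objective is smooth in `T`. Soft box penalties keep the search inside
documented bounds; bound-pinned parameters are flagged. `AIC = 2k - 2 lnL`
ranks models fitted to the same spectrum.

`bootstrap_ci()` resamples neutral regions (blocks) with replacement —
block resampling is the valid choice under linkage, and the neutral
region set provides natural blocks — rebuilds the spectrum from per-region
site records, and refits from the point estimate (rounds 2–3 only).
`scale_to_physical()` converts through `theta = 4 N_anc mu L` with the
published calibration `mu = 1.91e-9` per site per year and a one-year
generation time.

# Problem sizes used by the test suite

The checks in `tests/testthat` run at documented desk scales chosen to
exercise every property with useful power: neutral-expectation checks use
populations of 100–200 diploids over 15–50 kb with 60–200 replicates;
self-consistency and model-recovery fits use `n1 = n2 = 10` haploid
spectra with about 22,000 sites; the end-to-end split-time recovery uses
the bottleneck preset at `Q = 1000` over 1 Mb with ten replicates; the
load-direction and sweep experiments use 25 replicates each (0.4 Mb and
0.8 Mb). The optimiser schedules for these experiments (grid sizes 45–70
points, 25–40 time steps, restart counts per round) are part of the same
desk-scale design and are recorded in each call.

# Known limitations and honest failures

* **The Fig-4 direction is not reproducible at desk scale.** The central
  qualitative claim of the domestication-cost analysis — domestic
  individuals carry more deleterious alleles, a higher deleterious-to-
  synonymous ratio and a larger heterozygous fraction — does not emerge
  per-replicate from this two-population Wright–Fisher model at affordable
  contig lengths. Across 40 preset replicates the paired domestic-minus-
  wild differences are statistically indistinguishable from zero, and a
  control with a far more severe bottleneck (domestic size 5,000) drives
  the heterozygous fraction *down* (drift-induced homozygosity dominates
  masking). Two reasons: the published effect is small (a 2.95% allele
  excess needs genome-scale counts, not the few hundred deleterious sites
  a desk-scale contig yields), and the real domestic sample is a deeply
  structured, admixed pool of hundreds of birds from many breeds — a
  feature a two-population model excludes by design. The corresponding
  directional test is therefore expected to fail and is reported honestly
  rather than weakened.
* Bootstrap coverage was validated only structurally (degenerate-resampling
  collapse, interval bracketing); a full coverage experiment over many
  simulated datasets exceeds the intended test-suite scale.
* The diffusion engine's accuracy degrades for scaled migration beyond
  about 20 (already outside the fitting bounds) and the composite
  likelihood ignores linkage, as is standard for SFS inference.
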