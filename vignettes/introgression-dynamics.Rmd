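---
title: "Simulating the genomic landscape of introgression under deleterious variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the genomic landscape of introgression under deleterious variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`introgsim` simulates a diploid Wright–Fisher population that splits into a
donor and a recipient subpopulation, diverges for `t_s` generations, and
then experiences a single one-generation admixture pulse in which a
fraction *f* (default 5%) of the recipient's parents are drawn from the
donor. The quantity of interest is *p~I~*, the fraction of recipient
ancestry that is introgression-derived, tracked exactly through
recombination as ancestry segments and, optionally, through neutral marker
mutations placed every 500 bp on donor haplotypes one generation before
the pulse.

Selection acts only on new nonsynonymous mutations, whose selection
coefficients are drawn from a gamma distribution of fitness effects (human
preset: shape 0.186, E[*s*] = −0.01314833; Arabidopsis preset: shape
0.185, E[*s*] = −0.00048655). Mutations land uniformly along the
chromosome at rate *μ* per bp per gamete; within exons they are
nonsynonymous with odds 2.31 : 1 over synonymous, outside exons they are
neutral. Dominance is additive (*h* = 0.5), recessive (*h* = 0), or the
hyperbolic *h*(*s*) relationship `h0 / (1 − k s)`; the human preset
`0.5 / (1 − 7071.07 s)` and the Arabidopsis preset
`1 / ((1/0.987) − 39547 s)` are the same functional form with
(h0, k) = (0.5, 7071.07) and (0.987, 0.987 × 39547).

### Fitness: multiplicative within and across loci

Computing fitness as additive within a locus but multiplicative across
loci creates spurious heterosis: two heterozygous copies of an allele with
effect *s* give `(1 − 0.5 s)² = 1 − s + 0.25 s²`, exceeding the single
homozygote `1 − s` by exactly `0.25 s²`, and admixed individuals —
which carry more heterozygous sites — would gain a fitness advantage that
is an artefact of the bookkeeping. The engine therefore uses a
within-locus multiplicative scheme: heterozygotes contribute `1 − h|s|`
and homozygotes `(1 − 0.5|s|)²` (fully recessive homozygotes the standard
`1 − |s|`), with per-locus factors multiplied across loci and clipped at
zero. Under additive dominance an individual's fitness then depends only
on its total count of deleterious allele copies, whatever their zygosity;
`locus_fitness_factor(..., scheme = "textbook")` retains the naive scheme
so the site-frequency-spectrum equivalence of the two formulations can be
(and is) checked in the test suite.

Selection coefficients are stored signed (≤ 0): the fitness formulas
consume |s|, the *h*(*s*) relationship consumes signed *s*.

### The X chromosome

In X mode males are hemizygous. Sons receive a recombined maternal X;
daughters receive a recombined maternal X plus the paternal X copied
without recombination; sexes alternate so the ratio is exactly 1 : 1.
Fitness is dosage-compensated: a hemizygous male carrier receives the
female *homozygote* factor, so male carriers and female homozygotes are
equally fit and, under additive dominance, heterozygous females are
intermediate. The X fitness table of the source framework is not printed
in the text this package follows; the implementation follows the verbal
description and should be treated as a reconstruction at the table level.

## Demographic presets

`model_preset(0..4, N_A)` builds the five scenarios on the shared
schedule: burn-in 10 N~A~ generations from a mutation-free founding
population, split, pulse after `t_s = 2 N_A` generations, and N~A~
further generations. The reduced size is N~A~/10 throughout:

* **Model 0** — both subpopulations at N~A~ (control).
* **Model 1** — recipient bottleneck to N~A~/10 for the last 0.1 N~A~
  generations before the pulse, recovering at the pulse.
* **Model 2** — donor at N~A~/10 from the split onward: the donor
  accumulates load and introgressed ancestry is deleterious.
* **Model 3** — recipient at N~A~/10 from the split onward.
* **Model 4** — recipient at N~A~/10 from the split, restored to N~A~ at
  the pulse: the donor is fitter and the recipient expands at admixture.

Only the reduced size of the split-time experiments (1,000 diploids at
N~A~ = 10,000) is printed in the source text; the remaining schedule
details of Models 1–3 are reconstructions and deliberately sit in plain
schedule tables that can be edited via `demographic_model()`.

## Rescaling and its distortions

`rescale()` applies the standard compute-saving transformation with
constant *c*: `N → N/c`, `t → t/c`, `s → s·c`, `μ → μ·c`, and each map
rate `r → 0.5 (1 − (1 − 2r)^c)` (≈ `r·c` for small `r`). Sequence length
is unchanged, and the *h*(*s*) relationship keeps operating on the
*unscaled* coefficient (its slope is divided by *c*), since dominance is a
property of the mutation, not of the rescaled clock.

The package's desk-scale profile is the N~A~ = 10,000 design rescaled
with c = 20, i.e. 500 diploids per population and 6,500 scaled
generations. This preserves every compound parameter (N s, N μ, N r,
times in units of N) but introduces two knowable distortions:

* **Clipping.** A fraction `pgamma(1, 0.186, scale = 0.01314833/0.186 * 20,
  lower.tail = FALSE)` ≈ 7.7% of scaled |s| draws exceeds 1; such
  mutations act as expressed lethals (factor clipped at 0). At the c = 5
  used for cluster-scale work this fraction is ≈ 0.4%.
* **Scaled fitness units.** Recorded fitnesses use the scaled
  coefficients, so a log-fitness difference is c times its unscaled
  counterpart. Ratios such as w~R~/w~D~ are therefore comparable only
  between runs with the same *c*.

The c = 1 versus c = 2 agreement of *p~I~* trajectories is verified on a
miniature model in the test suite. The clipping distortion matters most on
the X chromosome, where hemizygous males expose every scaled coefficient:
donor X haplotypes carrying many drifted-up partially-recessive variants
become nearly inviable in males at c = 20, which inflates the
autosome-over-X introgression fold well beyond what milder scaling
produces. The X–autosome *direction* (less introgression on the X under
recessive fitness) is robust; the fold magnitude at this scaling is not,
and the acceptance results should be read with that caveat.

## The synthetic genome structure

`generate_random_structure()` emulates the randomly generated genic
structure of the study design: alternating intergenic regions
(Uniform(100, 5000) bp) and genes built as an exon followed, with
continuation probability 0.8, by (intron, exon) pairs; exon lengths are
Lognormal(meanlog = log 50, sdlog = log 2) and intron lengths
Lognormal(meanlog = log 100, sdlog = log 1.5). Two interpretation choices
are worth recording. First, the second lognormal parameter is read as
`sdlog` (the convention of the recipe the design follows); the medians —
exp(meanlog) = 50 bp and 100 bp — are unaffected by this choice. Second,
the exons-per-gene distribution is not printed in the source text; the
geometric continuation at 0.8 is the recipe default and is exposed as a
parameter.

What the generator does *not* emulate: the long-range clustering of genes
in real genomes (gene deserts, gene-dense clusters), recombination-rate
variation along the chromosome (the attached map is uniform unless one is
supplied), and any correlation between exon density and recombination
rate. Window-level correlation analyses on generated structure therefore
probe the machinery, not realistic genomic heterogeneity; for the latter,
`read_annotation()` (BED) and `read_recomb_map()` accept real exon
annotations and piecewise-constant maps. Coordinates are 0-based and
half-open everywhere, and loaded annotations collapse intron/intergenic
into a single neutral non-exonic class, which is the only distinction the
mutation model uses.

## Ancestry accounting

Segment tracking is exact: every haplotype carries a run-length list of
(end, origin) covering the chromosome, labels are assigned at the split
generation, and crossovers split and re-merge runs. The marker method
estimates the same quantity from the mean frequency of the 500-bp-spaced
neutral markers; the two differ only through tract-boundary effects at
the marker spacing, which the test suite bounds explicitly. Markers are
exempt from fitness, the SFS, F~ST~, and fixation pruning (a marker fixed
in the recipient is information, not noise). Windows that contain no
marker report `NA` rather than 0.

Introgression deserts are maximal intervals in which *no* sampled
recipient haplotype carries donor ancestry (population-wide, the reading
consistent with "devoid of introgressed ancestry"); a per-haplotype
variant is available via `per_haplotype = TRUE`.

## Statistics

* **Load**: mean fitness per population over *segregating* selected
  sites. Mutations fixed in every extant haplotype are pruned on a
  100-generation cadence (and before every recorded generation) and
  logged as substitutions; they multiply every individual in both
  populations by the same factor, so relative quantities are invariant to
  the cadence.
* **F~ST~**: Hudson per-site components combined across sites as a ratio
  of averages; negative per-site numerators are retained; sites
  monomorphic in both samples are excluded; markers never enter.
* **SFS**: derived-allele counts (polarity is exact in simulation), with
  all sites at count ≥ 25 pooled into the last bin.
* **Private/shared**: a three-way partition of segregating variants that
  always sums to the total.
* **Window correlations**: Spearman's rho with ties broken by a random
  permutation, p-value from the large-sample t approximation — the
  appropriate choice at hundreds-to-thousands of windows.

## Numerical choices

* Positions are integers in `[0, L)`. Mutation positions are redrawn
  against currently occupied positions (occupancy refreshed at each prune
  pass) — an infinite-sites approximation that is exact at low mutation
  density and degrades gracefully at scaled densities where true
  infinite-sites is impossible; after 100 failed redraws a collision is
  allowed.
* Crossover counts are Poisson with mean equal to the map length in
  Morgans; positions are drawn by inverting the cumulative map.
  Duplicate breakpoints collapse.
* Parent sampling is fitness-proportional with replacement (soft
  selection at fixed N); an all-zero-fitness pool is an error, not a
  silent resample. Under selfing, one parent supplies both gametes with
  the configured probability.
* The compiled engine draws from an internal xoshiro256++ generator
  seeded from R's RNG, so `set.seed()` (or the `seed` arguments) fully
  determines a run; gamma deviates use R's sampler.
* Fitness factors are cached per mutation in single precision; the
  recorded means agree with a double-precision recomputation to ~1e-4,
  which is far below every biological signal of interest here.
* With `track_neutral = FALSE` the engine thins the mutation process to
  the retained (exonic nonsynonymous) rate. Neutral and synonymous
  mutations never influence fitness or ancestry, so this changes no
  dynamics; it only removes bookkeeping weight from large runs.

## Problem sizes used by the checks

The packaged checks run, by the package's own choice of scale: ancestry
controls at 500 kb (100 kb neutral, 200 kb for the highest-recombination
control, where the scaled map already exceeds 4 Morgans and the expected
value is length-insensitive); load-differential experiments (the Model 4
fitness gap and ancestry rise) at the full 5 Mb mutational target of the
randomly-generated-structure design, since the per-chromosome load
differential scales with the selected target, and the X–autosome
contrast at 2.5 Mb, where it is equally decisive; the
SFS-equivalence and scaling-consistency checks on miniature equilibrium
and Model 4 populations. Replicate counts are 50 in the acceptance
script and smaller in the routine test suite.

## Known limitations

* One chromosome, two extant populations, a single pulse; no continuous
  migration, overlapping generations, positive selection, or epistasis.
* The desk-scale c = 20 distortions described above, most visible in
  X-linked magnitudes and in any absolute fitness value.
* Model 1–3 schedule details and the X fitness table are reconstructions
  from verbal descriptions.
* Loaded annotations discard the intron/intergenic distinction.
* Marker phase starts at coordinate 0; the original phase convention is
  not documented in the source text.
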