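# sweepconv

Two-locus forward-in-time Wright–Fisher simulation of selective sweeps
that are "softened" by allelic gene conversion.

## The problem

When a beneficial mutation arises once and sweeps to fixation (a *hard*
sweep), every post-sweep chromosome traces back to the single founding
haplotype, erasing linked diversity. *Soft* sweeps — from standing
variation or recurrent mutation — leave several distinct haplotypes and a
subtler footprint, and their apparent prevalence is often read as
evidence of rapid, non-mutation-limited adaptation. Allelic gene
conversion complicates this reading: a conversion tract covering the
selected site can copy the beneficial allele onto another genetic
background *during* the sweep, so a single-origin mutation ends up on
multiple haplotypes. Such a **pseudo-soft sweep** is essentially
indistinguishable from a true soft sweep in sample data.

`sweepconv` quantifies how often this happens under realistic
demographies and conversion rates for humans, *Drosophila melanogaster*
and *Arabidopsis thaliana*. It is aimed at population geneticists who
want calibrated expectations for hard-vs-soft sweep classification.

## The model

Two completely linked loci in a diploid Wright–Fisher population:

* **B locus** (selected): alleles b/B with genotype fitnesses
  1, 1 + *hs'*, 1 + *s'*;
* **A locus** (neutral marker): alleles a/A.

The sweep starts `t_s × 4N_A` generations before the present from a
single `AB` haplotype among `2N − 1` `ab` haplotypes. Crossover and
recurrent mutation are disallowed; the only way an `aB` haplotype can
arise is a gene conversion event at the B locus, which occurs in a
transmitted gamete with composite probability `G = 500 · g · c · Q`
(tract initiation rate × mean tract length, expressed relative to the
species' mean per-bp crossover rate `c`, with relative rate `g` and
rescaling factor `Q`). If the beneficial allele is lost, the replicate
restarts from its origin, so every retained replicate conditions on
non-loss; a replicate ends at fixation of B or at the present. A sweep is
**pseudo-soft** if at least one `aB` haplotype is present at the end (in
the population, or in a random sample of 200 chromosomes).

Demographic histories are piecewise constant/exponential epochs
(constant-size models plus the Tennessen AFR/EUR, Sheehan–Song and
South-Middle-Atlas multi-epoch models, transcribed from the stdpopsim
catalog). For speed, sizes and epoch durations are divided by `Q` while
`s` and `G` are multiplied by `Q` (Q = 10 for human and *A. thaliana*,
100 for *D. melanogaster*).

The engine tracks the 10 unordered two-locus genotypes and advances each
generation with a single exact multinomial draw — equivalent in
distribution to individual-based simulation, which is also included
(`individual_based_replicate()`) as an independent validation oracle,
together with Kimura diffusion checks of fixation probabilities.

## Worked example

```r
library(sweepconv)

## human constant-size model (N = 10,000) rescaled by Q = 10
model  <- rescale_model(build_model("human_constant"), 10)
params <- sweep_params(s = 0.01, h = 1, t_s = 0.05, g = 1, Q = 10)
run_replicate(model, params, seed = 42)
#> replicate_result: reached present after 200 generations (0 restarts)
#>   p_f = 0.9705
#>   population: AB=1941 aB=0 Ab=0 ab=59
#>   sample:     AB=192 aB=0 Ab=0 ab=8

## 200 replicates of the same scenario
s <- run_scenario("human_constant", s = 0.01, h = 1, t_s = 0.05, g = 1,
                  reps = 200, base_seed = 1)
s[, c("n_reps", "n_fixed", "frac_pseudo_soft_sample", "mean_p_f")]
#>   n_reps n_fixed frac_pseudo_soft_sample  mean_p_f
#> 1    200       0                     0.1 0.9160175
```

Reading this: a dominant sweep with `s = 0.01` starting 200 (scaled)
generations ago has typically reached high frequency (mean final B
frequency 0.92) but not fixation; in 10% of replicates at least one
sampled chromosome carries the beneficial allele on the converted `a`
background — those sweeps would look soft despite the single mutational
origin. (The single replicate shown stayed hard: `aB = 0`.)

The full published parameter grid is available through
`grid_config()` / `run_grid()` and the `exec/sweepconv` command-line
tool (`simulate`, `grid`, `summarize`, `validate` subcommands);
`figure_tables()` exports the tidy tables behind the published figures.

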