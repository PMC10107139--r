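# poolHI

Hybrid-index genome scans and backcross simulation for pool-seq
introgression experiments between two *Drosophila* species.

## The problem

In a two-generation backcross experiment, F1 hybrid females are crossed to
pure males of a recipient species, and a pool of 82 second-backcross (BC2)
females is sequenced alongside pools of the two parental strains. The
**hybrid index (HI)** — the donor-species allele frequency at SNPs that are
differentially fixed between the parents — is expected to halve each
generation: 50% (F1) → 25% (BC1) → 12.5% (BC2). Deviations from 12.5% on a
chromosome point at either recombination suppression by species-specific
chromosomal inversions (which inflates the variance of mean HI without
moving its mean) or genetic incompatibilities that purge donor material
(which depress it). poolHI provides, for researchers analysing such
experimental-introgression designs:

- a **forward simulator** of the crossing design on ancestry tracts: one
  obligate crossover per female meiosis (50 cM map), transmitted-chromatid
  sampling, crossover suppression inside inversion unions of
  heterokaryotypic mothers (SIM2), and an all-or-none dominant
  incompatibility locus with fecundity compensation (SIM3), conditioned on
  the experiment's pedigree (`run_replicate()`, `simulate_mean_hi()`);
- **simulation envelopes**: Bonferroni-corrected 5%/95% quantile bands of
  chromosome-wise mean HI over 10,000 replicates, and classification of
  observed values against them (`build_envelope()`, `classify_hi()`);
- **exact expectations**: per-generation halving (`expected_hi()`) and the
  two-locus dominant–recessive incompatibility enumeration in exact
  rational arithmetic (`bdmi_expected_freqs()`), which gives donor-allele
  frequencies of 1/22 (4.5%) and 2/11 (18.2%) after two backcross
  generations;
- the **pool-seq scan**: coverage/minor-count site filters, diagnostic-SNP
  calling (allele frequency exactly 1 vs 0), per-SNP HI with orientation
  flipping (`1 − AF` for donor-is-reference sites) and the 0.5 cap,
  chromosome summaries including the zero-introgression fraction, 400-SNP
  HI windows and 200 kb SNP-density windows (`call_sites()`,
  `diagnostic_snps()`, `hi_per_snp()`, `chrom_summary()`);
- the accompanying **statistics**: one-sample t-tests of BC1 fertility,
  binomial GLM between cross directions, Poisson GLMs on window SNP
  counts (`one_sample_t()`, `binomial_glm_z()`, `poisson_glm_density()`);
- a **synthetic-data generator** with known truth — parental pools fixed at
  diagnostic SNPs, a simulated BC2 pool read-sampled at configurable
  coverage — so the whole pipeline runs and calibrates without any
  sequencing download (`generate_parental_pools()`,
  `generate_bc2_counts()`).

## Worked example

```r
library(poolHI)

# exact incompatibility expectations after two backcross generations
e <- bdmi_expected_freqs(2)
e$frac_A1; e$percent_A1   # "1/22"  4.5
e$frac_B1; e$percent_B1   # "2/11"  18.2

# neutral envelope for an X-sized chromosome, and a verdict
ped <- default_pedigree("to_fla")
g   <- genome_map("X", 30.6e6)
env <- build_envelope(ped, g, scenario("SIM1"),
                      n_replicates = 2000, n_tests = 6, seed = 20260926)
env$lower; env$upper      # 0.0665  0.1868
classify_hi(c(X = 0.046), env)$classification   # "below"

# scan a synthetic experiment end to end
syn   <- synthetic_genome()
pools <- generate_parental_pools(syn$genome, inversions = syn$inversions,
                                 seed = 20260926)
bc    <- generate_bc2_counts(pools$truth, ped, scenario("SIM1"),
                             mean_cov = 100, seed = 20260926)
d  <- diagnostic_snps(pools$counts_donor, pools$counts_recipient)
hi <- hi_per_snp(bc$counts, d, pool = "bc")
chrom_summary(hi)
#>   chrom mean_hi  sd_hi n_snps zero_fraction
#>   chrA  0.0897  0.0326   3574      0.00028
#>   chrB  0.1081  0.0344   2544      0
```

The chromosome means land inside the neutral envelope (the true replicate
happened to draw a low-HI pool: mean HI per replicate varies widely, which
is exactly why the envelope, not the 12.5% point value, is the test).

A worked sequence of analyses — expectations, envelopes under the three
scenarios, data synthesis, the genome scan, fertility and SNP-density
statistics, and the final classification report — lives in `analysis/`
(numbered scripts; run them in order from the repository root, outputs go
to `results/`).

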