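---
title: "Models and methods: backcross simulation and pool-seq hybrid-index scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: backcross simulation and pool-seq hybrid-index scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolHI)
```

## The problem

Two closely related *Drosophila* species are crossed once (F1 females
only — hybrid males are sterile and *Drosophila* males do not recombine),
and hybrid females are backcrossed to pure males of a recipient species
for two generations. A pool of 82 second-backcross (BC2) females is
sequenced together with pools of the two parental strains. The quantity of
interest is the **hybrid index (HI)**: the fraction of the genome (or, in
a pool, the allele frequency) derived from the donor species. Under
neutral Mendelian transmission the expected HI halves every generation —
50% in F1, 25% in BC1, 12.5% in the sequenced BC2 pool — but chromatid
sampling and crossover placement create substantial variance around that
mean. Chromosomal inversions that are alternately fixed between the
species suppress recombination in heterokaryotypic females and inflate
that variance further, while a strong genetic incompatibility removes
donor material around its locus. poolHI implements all three ingredients:
an exact analytic layer, a forward simulator that produces null
distributions, and the pool-seq scan that measures HI from read counts.

## Meiosis model

Each chromosome carries exactly one crossover per female meiosis,
corresponding to a genetic map of 50 cM. We model the full tetrad: one
crossover at a position uniform on `[0, L)` yields two parental and two
single-crossover recombinant chromatids, and the transmitted chromatid is
drawn uniformly — so a gamete is recombinant with probability 1/2. This is
the only interpretation that reconciles "one crossover per meiosis" with a
50 cM map, and it is what `meiosis()` implements on ancestry-tract
haplotypes (ordered `(start, end, ancestry)` runs tiling the chromosome).

Because every backcross uses a pure recipient father, donor ancestry only
ever segregates on the maternally transmitted haplotype; the simulator
asserts this invariant, and the per-individual HI on a chromosome is the
donor tract length on the maternal haplotype divided by `2L`.

**Inversions (SIM2).** When the mother is heterokaryotypic — her two
haplotypes differ in ancestry anywhere inside the chromosome's inversion
union — a crossover falling inside that union produces no transmissible
recombinant: the gamete is an intact parental chromatid drawn at random.
This mirrors the fate of single-crossover products in *Drosophila*
paracentric-inversion heterozygotes, which segregate into the polar
nuclei. The default therefore *suppresses* the crossover rather than
moving it; `scenario(..., suppression = "resample")` instead redraws the
position uniformly from the colinear part, for users who prefer to
conserve map length. Overlapping inversions (the X carries several) are
merged into a single inverted region, since suppression and locus
placement operate on the inverted part as a whole. Homokaryotypic mothers
recombine freely everywhere.

**Incompatibility locus (SIM3).** A single dominant-acting donor locus,
placed uniformly at random within the inversion union (fresh per
replicate) or at a fixed position, cannot pass beyond F1: any BC1/BC2
daughter whose maternal haplotype carries donor ancestry there is never
produced. Rejected daughters are redrawn until the pedigree counts are
met ("fecundity compensation"), because the experiment conditions on the
realised pool size of 82; a redraw budget (default 10,000) guards
impossible configurations. This is an all-or-none model — it brackets the
strongest possible incompatibility rather than estimating selection
strength.

## Conditioning and the pedigree

All simulations are conditioned on the pedigree: 4 F1 mothers, 14 BC1 and
82 BC2 females towards *D. montana*; 3 F1 mothers, 22 BC1 and 82 BC2
females towards *D. flavomontana*. The BC1-per-F1 and BC2-per-BC1
contributions are split as evenly as possible by default — the realised
per-mother counts are experiment-specific metadata, and
`pedigree_config()` accepts any observed split. Conditioning matters
because a handful of BC1 mothers dominates the pool: replicate-to-
replicate variance in mean HI is driven mostly by which BC1 haplotypes
happened to be drawn.

## Envelopes and testing

For each chromosome the experiment is simulated 10,000 times, and the
empirical quantile band from `alpha/n_tests` to `1 - alpha/n_tests` of
the replicate mean HI forms the acceptance envelope (`build_envelope()`).
`n_tests` defaults to the number of chromosome units analysed (six: X,
2L, 2R, 3, 4, 5), a Bonferroni correction across per-chromosome tests.
The band is implemented literally as corrected 5% and 95% quantiles
(i.e. one-sided `alpha/m` in each tail) rather than `alpha/(2m)`; both
tails are reported, so users who prefer the two-sided convention can pass
`alpha = 0.025`. An observed mean HI outside the band (bounds inclusive,
`classify_hi()`) is declared inconsistent with the simulated model.
Quantiles are the default interpolated type of `stats::quantile()`;
at 10,000 replicates the choice of quantile type moves the bounds by less
than the Monte Carlo error.

Reproducibility: per-replicate seeds are derived from the master seed by
a fixed integer recurrence and set independently per replicate, so
replicate *r* can be reproduced in isolation and results are independent
of execution order.

## Exact incompatibility expectations

`bdmi_expected_freqs()` enumerates the two-locus dominant–recessive
incompatibility (donor allele A1 acting dominantly against the
homozygous-recipient genotype B2B2) with exact rational arithmetic.
Each generation, offspring classes of every mother class are enumerated
(unlinked loci; recipient father), incompatible classes are removed, and
mother classes are weighted by their *surviving-offspring fraction* — a
mother who loses a quarter of her daughters to the incompatibility
contributes proportionally less to the next generation. Under this
weighting two backcross generations give donor-allele frequencies of
exactly 1/22 (4.5%) at the dominant locus and 2/11 (18.2%) at the
recessively interacting locus, against the neutral 1/8 at both. The
alternative (equal-mother) weighting would presume selection also reduces
per-mother contributions, contradicting the pool-size conditioning above;
with selection disabled the enumeration collapses to neutral halving at
every generation, which is tested.

## The pool-seq scan

Site filters follow heuristic pool-seq SNP calling: per pool and
chromosome a site needs depth at least 80 and at most the 95th depth
percentile, and the minor-allele read count summed across pools must
reach 5 (a per-pool variant is available). Diagnostic SNPs are sites with
allele frequency exactly 1 in one parental pool and 0 in the other;
fixity is strict by default (`tol = 0`) because pool-level fixation is
the definition of "differentially fixed", with a tolerance knob for noisy
data. At each diagnostic SNP the BC-pool HI is the donor-allele
frequency, `AD/DP` or `1 - AD/DP` depending on whether the donor carries
the alternate or the reference allele; values strictly above 0.5 are
impossible for first-cross-derived backcross females and are discarded
(0.5 itself is retained), with discard and missing-site counts carried as
attributes so the bookkeeping identity
`n(diagnostics) = n(records) + n(discarded) + n(missing)` is checkable.
Missing BC-pool data is skipped, never imputed — imputation would bias
the zero-introgression fraction, one of the scan's headline statistics.
Windows never span chromosomes; 2L and 2R are separate units.

## Synthetic data: what it emulates and what it does not

`generate_parental_pools()` and `generate_bc2_counts()` produce the full
input set with known truth. Diagnostic SNP positions follow a
piecewise-constant Poisson process whose rate doubles inside inversions
and is 1.5× on the X — the qualitative enrichment seen in diverged
genomes — at a baseline of 1e-4 per bp on a two-chromosome, 2 × 25 Mb
genome (one chromosome with a 40%-span inversion, one colinear), giving
roughly 5,000 SNPs: large enough for stable chromosome summaries, small
enough that the whole pipeline runs in seconds. Depths are Poisson with
mean 100, matching the filters' assumptions; reads are binomial around
the true pool frequency, with an optional symmetric miscall rate
(default 0) whose main use is exercising the >0.5 discard rule.

The generator does **not** emulate mapping bias beyond randomising
ref/alt orientation, indels, base-quality error structure, or linked
sequencing error — so passing calibration here demonstrates the
statistical pipeline, not robustness to alignment artefacts. Real-data
chromosome-level results additionally reflect reference bias, which the
original analysis handled by running the scan against both parental
reference genomes; the corresponding check here is the orientation-flip
invariance test.

## Problem sizes and numerical choices

The acceptance checks use the design's 10,000 replicates where the claim
is about the null distribution itself, 1,000 + 1,000 replicates for the
stochastic-dominance comparison of SIM3 against SIM1 (rank test), and
100 seeds for calibration of the "within" verdict; the demonstration
scripts under `analysis/` use 2,000 replicates. The t-test and GLMs
delegate to `stats::t.test()` / `stats::glm()` (logistic fits tightened
to `epsilon = 1e-14` so the Wald z agrees with the closed-form 2×2
solution to ~1e-7); degenerate inputs — zero-variance scores, zero cells,
all-zero count groups — raise explicit errors or warnings rather than
returning infinities. Interval arithmetic is exact on bp coordinates;
BED input is 0-based half-open, SNP tables 1-based, converted on ingest.

## Known limitations

Interchromosomal effects of inversions on recombination elsewhere are not
modelled; gene conversion and double crossovers inside inversions are
ignored (both transfer material at rates far below the single-crossover
scale of this design); the incompatibility model is a single all-or-none
locus, not a pairwise epistatic network; and fitness is equated with
being produced — partial sterility of carriers is outside scope.
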