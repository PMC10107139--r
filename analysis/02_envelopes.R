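#!/usr/bin/env Rscript
# Simulation envelopes for chromosome-wise mean hybrid index under the three
# scenarios: SIM1 (neutral), SIM2 (neutral inversions), SIM3 (inversions
# plus a dominant incompatibility locus). Run from the repository root.
#
# The X chromosome with its inversion complement is the interesting case:
# inversions widen the neutral envelope (more replicate-to-replicate
# variance), and an incompatibility locus drags the whole distribution down.
# 2,000 replicates keep this demonstration quick; the package's acceptance
# checks use the full 10,000.

suppressPackageStartupMessages(library(poolHI))
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

seed <- 20260926
n_rep <- 2000
genome <- genome_map("X", 30.6e6)
inversions <- load_inversions(
  system.file("extdata", "synthetic_inversions.bed", package = "poolHI"),
  default_genome())
ped <- default_pedigree("to_fla")

scens <- list(
  SIM1 = scenario("SIM1"),
  SIM2 = scenario("SIM2", inversions = inversions),
  SIM3 = scenario("SIM3", inversions = inversions)
)

rows <- list()
reps <- list()
for (nm in names(scens)) {
  env <- build_envelope(ped, genome, scens[[nm]], n_replicates = n_rep,
                        alpha = 0.05, n_tests = 6, seed = seed)
  m <- attr(env, "replicates")
  reps[[nm]] <- data.frame(scenario = nm, replicate = seq_len(nrow(m)),
                           mean_hi = m[, "X"])
  rows[[nm]] <- data.frame(scenario = nm, chrom = "X",
                           mean = mean(m), lower = env$lower,
                           upper = env$upper, width = env$upper - env$lower)
  cat(sprintf("%s: mean %.4f, envelope [%.4f, %.4f] (width %.4f)\n",
              nm, mean(m), env$lower, env$upper, env$upper - env$lower))
}
envs <- do.call(rbind, rows)
write.table(envs, "results/sim/envelopes_X.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, reps), "results/sim/replicates_X.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(
  paste0("\nInversions leave the mean at the neutral 12.5%% but widen the\n",
         "envelope by %.0f%%; the incompatibility locus shifts the mean\n",
         "down to %.1f%%.\n"),
  100 * (envs$width[2] / envs$width[1] - 1), 100 * envs$mean[3]))
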