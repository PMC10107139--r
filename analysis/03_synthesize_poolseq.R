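#!/usr/bin/env Rscript
# Generates the synthetic pool-seq inputs with known truth: two parental
# pools differentially fixed at every diagnostic SNP, and a BC2 pool of 82
# females simulated under neutrality (SIM1), sequenced at 100x.

suppressPackageStartupMessages(library(poolHI))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

seed <- 20260926
syn <- synthetic_genome()
pools <- generate_parental_pools(syn$genome, inversions = syn$inversions,
                                 mean_cov = 100, seed = seed)
ped <- default_pedigree("to_fla")
bc <- generate_bc2_counts(pools$truth, ped, scenario("SIM1"),
                          mean_cov = 100, seed = seed)

write_counts_tsv(pools$counts_donor, "results/data/pool_donor.tsv")
write_counts_tsv(pools$counts_recipient, "results/data/pool_recipient.tsv")
write_counts_tsv(bc$counts, "results/data/pool_bc2.tsv")
readr::write_tsv(bc$truth_q, "results/data/truth_q.tsv")
jsonlite::write_json(
  list(seed = seed, scenario = "SIM1", direction = ped$direction,
       pool_size = ped$pool_size,
       true_mean_hi = as.list(bc$mean_hi)),
  "results/data/truth.json", auto_unbox = TRUE, digits = NA)

cat(sprintf(
  paste0("Synthesised %d diagnostic SNPs over %d chromosomes;\n",
         "true BC2 pool mean hybrid index: %s\n"),
  nrow(pools$truth$sites), nrow(syn$genome),
  paste(sprintf("%s = %.4f", names(bc$mean_hi), bc$mean_hi),
        collapse = ", ")))
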