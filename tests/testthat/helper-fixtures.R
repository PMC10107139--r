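# Shared builders for small in-code fixtures.

# single-chromosome genome of length L
toy_genome <- function(L = 1e6, name = "chr1") genome_map(name, L)

# individual with a pure maternal/paternal haplotype pair
pure_individual <- function(mat_anc, pat_anc, L = 1e6, chrom = "chr1") {
  individual(stats::setNames(list(list(
    maternal = haplotype(0, L, mat_anc, L),
    paternal = haplotype(0, L, pat_anc, L)
  )), chrom))
}

f1_individual <- function(donor = "mon", L = 1e6, chrom = "chr1") {
  recipient <- setdiff(c("mon", "fla"), donor)
  pure_individual(donor, recipient, L = L, chrom = chrom)
}

# inversion table covering fraction `f` of a length-L chromosome, centred
toy_inversions <- function(f, L = 1e6, chrom = "chr1") {
  if (f <= 0) return(NULL)
  half <- f * L / 2
  tibble::tibble(chrom = chrom, start = L / 2 - half, end = L / 2 + half,
                 species_label = "mon")
}

# count-table row constructor for one pool
counts_table <- function(chrom, pos, ad, dp, pool = "p", ref = "A",
                         alt = "T") {
  tb <- tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt)
  tb[[paste0("AD_", pool)]] <- ad
  tb[[paste0("DP_", pool)]] <- dp
  tb
}

# a tiny pedigree: 1 F1 mother, n_bc1 BC1, pool_size BC2
tiny_pedigree <- function(direction = "to_fla", n_bc1 = 2L,
                          pool_size = 8L) {
  pedigree_config(
    direction = direction,
    bc1_per_f1 = n_bc1,
    bc2_per_bc1 = even_split_test(pool_size, n_bc1),
    pool_size = pool_size
  )
}

even_split_test <- function(n, k) {
  base <- n %/% k; extra <- n %% k
  c(rep(base + 1L, extra), rep(base, k - extra))
}

# ancestry lookup computed directly from the tract table (independent of
# the package's findInterval-based accessor)
hap_ancestry_at_test <- function(h, x) {
  i <- max(which(h$s <= x))
  h$a[i]
}

# independent interval-merge oracle (brute force over unit steps is too
# slow for Mb scales; this is a from-scratch sweep independent of the
# package's internals)
merge_oracle <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out <- list()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me) me <- max(me, ends[i]) else {
      out[[length(out) + 1]] <- c(ms, me); ms <- starts[i]; me <- ends[i]
    }
  }
  out[[length(out) + 1]] <- c(ms, me)
  do.call(rbind, out)
}
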