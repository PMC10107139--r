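#' Default synthetic genome for pipeline tests
#'
#' Two chromosome-sized units: `chrA` (25 Mb) carrying one inversion that
#' spans 40% of its length, and `chrB` (25 Mb) fully colinear. At the
#' default SNP density of 1e-4 per bp this yields about 5,000 diagnostic
#' SNPs genome-wide — enough to exercise every pipeline stage in seconds.
#'
#' @return List with `genome` (a [genome_map()]) and `inversions` (tibble).
#' @export
synthetic_genome <- function() {
  g <- genome_map(c("chrA", "chrB"), c(25e6, 25e6))
  inv <- tibble::tibble(chrom = "chrA", start = 7.5e6, end = 17.5e6,
                        species_label = "mon")
  list(genome = g, inversions = inv)
}

#' Generate parental pool count tables with known truth
#'
#' Emulates the two parental-strain pools: diagnostic SNP positions are
#' drawn from a Poisson process whose rate is boosted inside inversions and
#' on the X chromosome (mirroring the observed enrichment of differentially
#' fixed SNPs there), each pool is fixed for opposite alleles with the
#' ref/alt orientation randomised per site, and depths are Poisson around
#' `mean_cov`. With no sequencing error the emitted tables are differentially
#' fixed by construction, so [diagnostic_snps()] recovers every truth
#' position.
#'
#' @param genome A [genome_map()].
#' @param inversions Optional inversion tibble (used for the density boost
#'   and carried into the truth set).
#' @param snp_density Baseline diagnostic-SNP rate per bp (default 1e-4).
#' @param density_multiplier_inverted Rate multiplier inside the inversion
#'   union (default 2, emulating higher divergence in inverted regions).
#' @param density_multiplier_X Rate multiplier on the chromosome named
#'   `"X"`, if present (default 1.5).
#' @param mean_cov Mean sequencing depth per pool (default 100).
#' @param seed Integer seed.
#' @return List with `counts_donor`, `counts_recipient` (count tables, pool
#'   names `"donor"` / `"recipient"`) and `truth` — a list holding the
#'   genome, inversions, per-site truth tibble (`chrom`, `pos`,
#'   `donor_is_ref`), and the seed.
#' @export
generate_parental_pools <- function(genome, inversions = NULL,
                                    snp_density = 1e-4,
                                    density_multiplier_inverted = 2,
                                    density_multiplier_X = 1.5,
                                    mean_cov = 100, seed = 1L) {
  stopifnot(snp_density > 0, mean_cov > 0)
  set.seed(seed)
  sites <- lapply(seq_len(nrow(genome)), function(ci) {
    ch <- genome$chrom[ci]
    L <- genome$length[ci]
    mult_x <- if (ch == "X") density_multiplier_X else 1
    union <- inversion_union(inversions, ch)
    # piecewise-constant Poisson process: simulate colinear and inverted
    # segments at their own rates, then pool positions
    inv_len <- iv_length(union)
    rate_col <- snp_density * mult_x
    rate_inv <- rate_col * density_multiplier_inverted
    n_col <- stats::rpois(1L, rate_col * (L - inv_len))
    n_inv <- stats::rpois(1L, rate_inv * inv_len)
    pos_col <- if (L - inv_len > 0) sample_outside(n_col, L, union) else
      numeric(0)
    pos_inv <- if (inv_len > 0) sample_inside(n_inv, union) else numeric(0)
    pos0 <- sort(unique(floor(c(pos_col, pos_inv))))
    tibble::tibble(chrom = ch, pos = pos0 + 1)  # 1-based table positions
  })
  sites <- dplyr::bind_rows(sites)
  n <- nrow(sites)
  donor_is_ref <- stats::runif(n) < 0.5
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")

  dp_d <- stats::rpois(n, mean_cov)
  dp_r <- stats::rpois(n, mean_cov)
  # donor pool fixed for the donor allele; recipient pool for the other
  counts_donor <- tibble::tibble(
    chrom = sites$chrom, pos = sites$pos, ref = ref, alt = alt,
    AD_donor = ifelse(donor_is_ref, 0, dp_d), DP_donor = dp_d
  )
  counts_recipient <- tibble::tibble(
    chrom = sites$chrom, pos = sites$pos, ref = ref, alt = alt,
    AD_recipient = ifelse(donor_is_ref, dp_r, 0), DP_recipient = dp_r
  )
  truth <- list(
    genome = genome, inversions = inversions,
    sites = tibble::tibble(chrom = sites$chrom, pos = sites$pos,
                           ref = ref, alt = alt,
                           donor_is_ref = donor_is_ref),
    snp_density = snp_density, mean_cov = mean_cov, seed = seed
  )
  list(counts_donor = counts_donor, counts_recipient = counts_recipient,
       truth = truth)
}

# n uniform positions on [0, L) excluding `region` (merged intervals)
sample_outside <- function(n, L, region) {
  if (n == 0L) return(numeric(0))
  if (nrow(region) == 0L) return(stats::runif(n, 0, L))
  # complement of region within [0, L)
  bounds <- c(0, t(region), L)
  comp <- matrix(bounds, ncol = 2L, byrow = TRUE)
  comp <- comp[comp[, 1L] < comp[, 2L], , drop = FALSE]
  sample_inside(n, comp)
}

# n uniform positions inside merged intervals, length-weighted
sample_inside <- function(n, region) {
  if (n == 0L) return(numeric(0))
  w <- region[, 2L] - region[, 1L]
  k <- sample.int(nrow(region), n, replace = TRUE, prob = w)
  stats::runif(n, region[k, 1L], region[k, 2L])
}

#' Generate backcross-pool allele counts from a simulated pool
#'
#' Runs one replicate of the crossing experiment to obtain the maternal
#' haplotypes of the pooled females, computes the true pool donor-allele
#' frequency `q` at every diagnostic site (number of females carrying donor
#' ancestry there, over `2 * pool size` alleles, since the paternal allele
#' is always recipient), and draws pooled read counts: depth Poisson around
#' `mean_cov` and alternate-supporting reads binomial given depth and the
#' site's alternate-allele frequency (optionally perturbed by a symmetric
#' per-read miscall rate).
#'
#' @param truth Truth set from [generate_parental_pools()].
#' @param pedigree A [pedigree_config()].
#' @param scen A [scenario()].
#' @param mean_cov Mean sequencing depth (default 100).
#' @param error_rate Symmetric per-read miscall rate toward the other allele
#'   (default 0; nonzero values can push observed frequencies past 0.5 and
#'   so exercise the discard rule).
#' @param seed Integer seed.
#' @param depth Generation pooled (3 = BC2, the default).
#' @return List with `counts` (count table, pool name `"bc"`) and
#'   `truth_q` — tibble `chrom`, `pos`, `q` of true pool donor frequencies,
#'   plus `mean_hi`, the realised per-chromosome pool mean hybrid index.
#' @export
generate_bc2_counts <- function(truth, pedigree, scen, mean_cov = 100,
                                error_rate = 0, seed = 1L, depth = 3L) {
  genome <- truth$genome
  miss <- setdiff(unique(truth$sites$chrom), genome$chrom)
  if (length(miss)) stop("truth sites reference unknown chromosome(s): ",
                         paste(miss, collapse = ", "))
  set.seed(seed)
  rep_hi <- run_replicate(pedigree, genome, scen, depth = depth,
                          keep_pool = TRUE)
  pool <- attr(rep_hi, "pool")
  donor <- direction_labels(pedigree$direction)$donor

  out <- lapply(seq_len(nrow(genome)), function(ci) {
    ch <- genome$chrom[ci]
    s <- truth$sites[truth$sites$chrom == ch, , drop = FALSE]
    if (nrow(s) == 0L) return(NULL)
    haps <- pool[[ch]]
    pos0 <- s$pos - 1  # sites are 1-based; haplotypes 0-based
    carrier <- vapply(haps, function(h) {
      # donor ancestry indicator at each site for this female
      h$a[findInterval(pos0, h$s)] == donor
    }, logical(nrow(s)))
    if (nrow(s) == 1L) carrier <- matrix(carrier, nrow = 1L)
    q <- rowSums(carrier) / (2 * length(haps))
    dp <- stats::rpois(nrow(s), mean_cov)
    q_seq <- q * (1 - error_rate) + (1 - q) * error_rate
    alt_freq <- ifelse(s$donor_is_ref, 1 - q_seq, q_seq)
    ad <- stats::rbinom(nrow(s), dp, alt_freq)
    list(
      counts = tibble::tibble(chrom = ch, pos = s$pos, ref = s$ref,
                              alt = s$alt, AD_bc = ad, DP_bc = dp),
      q = tibble::tibble(chrom = ch, pos = s$pos, q = q)
    )
  })
  out <- out[!vapply(out, is.null, TRUE)]
  counts <- dplyr::bind_rows(lapply(out, `[[`, "counts"))
  list(
    counts = counts,
    truth_q = dplyr::bind_rows(lapply(out, `[[`, "q")),
    mean_hi = rep_hi
  )
}
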