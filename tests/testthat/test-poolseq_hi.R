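# Brute-force site-filter oracle applying the three rules one by one, kept
# independent of call_sites' vectorised implementation.
call_sites_oracle <- function(counts, min_count, min_cov, q) {
  pools <- sub("^AD_", "", grep("^AD_", names(counts), value = TRUE))
  keep <- logical(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    ok <- TRUE
    for (p in pools) {
      dp_all <- counts[[paste0("DP_", p)]][counts$chrom == counts$chrom[i]]
      thr <- stats::quantile(dp_all, q, names = FALSE)
      dp <- counts[[paste0("DP_", p)]][i]
      if (dp < min_cov || dp > thr) ok <- FALSE
    }
    ad_sum <- sum(sapply(pools, function(p) counts[[paste0("AD_", p)]][i]))
    dp_sum <- sum(sapply(pools, function(p) counts[[paste0("DP_", p)]][i]))
    if (min(ad_sum, dp_sum - ad_sum) < min_count) ok <- FALSE
    keep[i] <- ok
  }
  counts[keep, ]
}

two_pool_table <- function(chrom, pos, ad1, dp1, ad2, dp2) {
  tb <- tibble::tibble(chrom = chrom, pos = pos, ref = "A", alt = "T",
                       AD_p1 = ad1, DP_p1 = dp1, AD_p2 = ad2, DP_p2 = dp2)
  tb
}

test_that("site filters match a rule-by-rule oracle on a crafted table", {
  set.seed(21)
  tb <- two_pool_table(
    chrom = rep(c("c1", "c2"), each = 10),
    pos = rep(1:10 * 100, 2),
    ad1 = sample(0:50, 20, TRUE), dp1 = sample(60:200, 20, TRUE),
    ad2 = sample(0:50, 20, TRUE), dp2 = sample(60:200, 20, TRUE)
  )
  got <- call_sites(tb, min_count = 5, min_cov = 80, max_cov_quantile = 0.95)
  oracle <- call_sites_oracle(tb, 5, 80, 0.95)
  expect_equal(got, oracle)
})

test_that("coverage bounds follow the stated thresholds", {
  tb <- two_pool_table("c1", c(100, 200, 300),
                       ad1 = c(10, 10, 10), dp1 = c(79, 100, 100),
                       ad2 = c(10, 10, 10), dp2 = c(100, 100, 100))
  out <- call_sites(tb)
  expect_false(100 %in% out$pos)  # DP 79 in one pool drops the site
  # all-identical depths: the maximum-coverage quantile drops nothing
  tb2 <- two_pool_table("c1", 1:20 * 10,
                        ad1 = rep(10, 20), dp1 = rep(100, 20),
                        ad2 = rep(10, 20), dp2 = rep(100, 20))
  expect_equal(nrow(call_sites(tb2)), 20)
  # empty input passes through
  expect_equal(nrow(call_sites(tb2[0, ])), 0)
})

test_that("only differentially fixed sites are diagnostic, with orientation", {
  donor <- counts_table("c1", c(100, 200, 300, 400),
                        ad = c(50, 0, 99, 0), dp = c(50, 60, 100, 0),
                        pool = "donor")
  recip <- counts_table("c1", c(100, 200, 300, 400),
                        ad = c(0, 55, 0, 10), dp = c(45, 55, 80, 40),
                        pool = "recipient")
  d <- diagnostic_snps(donor, recip)
  # pos 100: donor fixed alt, recipient fixed ref -> diagnostic, donor_is_ref FALSE
  # pos 200: donor fixed ref, recipient fixed alt -> diagnostic, donor_is_ref TRUE
  # pos 300: AF 0.99 in donor -> excluded (strict fixity)
  # pos 400: zero depth in donor -> skipped and counted
  expect_equal(d$pos, c(100, 200))
  expect_equal(d$donor_is_ref, c(FALSE, TRUE))
  expect_equal(attr(d, "n_zero_dp"), 1L)
  # identical pools share every allele: nothing is diagnostic
  same <- diagnostic_snps(
    counts_table("c1", 1:5 * 10, ad = rep(30, 5), dp = rep(60, 5),
                 pool = "donor"),
    counts_table("c1", 1:5 * 10, ad = rep(30, 5), dp = rep(60, 5),
                 pool = "recipient"))
  expect_equal(nrow(same), 0)
})

test_that("per-SNP hybrid index flips orientation and applies the 0.5 cap", {
  diags <- tibble::tibble(chrom = "c1", pos = c(100, 200, 300, 400, 500),
                          ref = "A", alt = "T",
                          donor_is_ref = c(TRUE, FALSE, TRUE, FALSE, TRUE))
  bc <- counts_table("c1", c(100, 200, 300, 400),
                     ad = c(175, 0, 37, 63), dp = c(200, 80, 100, 100),
                     pool = "bc")
  hi <- hi_per_snp(bc, diags)
  # pos 100: donor-is-ref, AF 0.875 -> HI 0.125 (the worked flipping example)
  expect_equal(hi$hi[hi$pos == 100], 0.125)
  # pos 200: donor-is-alt, AD 0 -> HI 0
  expect_equal(hi$hi[hi$pos == 200], 0)
  # pos 300: HI = 1 - 0.37 = 0.63 > 0.5 -> discarded
  expect_false(300 %in% hi$pos)
  # pos 400: HI = 0.63 by the alt orientation -> discarded too
  expect_false(400 %in% hi$pos)
  # pos 500 missing from the BC table -> skipped
  expect_equal(attr(hi, "n_discarded"), 2L)
  expect_equal(attr(hi, "n_missing"), 1L)
  # conservation: diagnostics = records + discarded + missing
  expect_equal(nrow(diags),
               nrow(hi) + attr(hi, "n_discarded") + attr(hi, "n_missing"))
  # HI exactly 0.5 is retained (strict 'over 0.5' rule)
  bc2 <- counts_table("c1", 100, ad = 100, dp = 200, pool = "bc")
  hi2 <- hi_per_snp(bc2, diags[1, ])
  expect_equal(hi2$hi, 0.5)
})

test_that("hybrid index is invariant to relabelling ref and alt", {
  set.seed(31)
  n <- 200
  diags <- tibble::tibble(chrom = "c1", pos = 1:n * 10, ref = "A", alt = "T",
                          donor_is_ref = sample(c(TRUE, FALSE), n, TRUE))
  dp <- sample(80:150, n, TRUE)
  ad <- rbinom(n, dp, 0.3)
  bc <- counts_table("c1", 1:n * 10, ad = ad, dp = dp, pool = "bc")
  hi1 <- hi_per_snp(bc, diags)
  # flip: alt counts become ref counts and the orientation flag toggles
  bc_flipped <- counts_table("c1", 1:n * 10, ad = dp - ad, dp = dp,
                             pool = "bc")
  diags_flipped <- diags
  diags_flipped$donor_is_ref <- !diags$donor_is_ref
  hi2 <- hi_per_snp(bc_flipped, diags_flipped)
  expect_equal(hi1$hi, hi2$hi)
})

test_that("chromosome summaries agree with a two-pass oracle", {
  rec <- tibble::tibble(chrom = "c1", pos = 1:4, hi = c(0, 0, 0.5, 0))
  s <- chrom_summary(rec)
  expect_equal(s$zero_fraction, 0.75)
  rec2 <- tibble::tibble(chrom = "c2", pos = 1:10, hi = rep(0.125, 10))
  s2 <- chrom_summary(rec2)
  expect_equal(s2$mean_hi, 0.125)
  expect_equal(s2$sd_hi, 0)
  set.seed(41)
  rec3 <- tibble::tibble(chrom = sample(c("a", "b"), 1000, TRUE),
                         pos = 1:1000, hi = runif(1000, 0, 0.5))
  s3 <- chrom_summary(rec3)
  for (ch in c("a", "b")) {
    x <- rec3$hi[rec3$chrom == ch]
    mu <- sum(x) / length(x)
    sd2 <- sqrt(sum((x - mu)^2) / (length(x) - 1))  # explicit two-pass
    expect_equal(s3$mean_hi[s3$chrom == ch], mu, tolerance = 1e-12)
    expect_equal(s3$sd_hi[s3$chrom == ch], sd2, tolerance = 1e-12)
  }
})

test_that("SNP windows block consecutive records and flag partial tails", {
  rec <- tibble::tibble(chrom = "c1", pos = 1:800, hi = runif(800, 0, 0.5))
  w <- window_hi(rec, window_snps = 400)
  expect_equal(nrow(w), 2)
  expect_false(any(w$partial))
  rec2 <- tibble::tibble(chrom = "c1", pos = 1:900, hi = runif(900, 0, 0.5))
  w2 <- window_hi(rec2, window_snps = 400)
  expect_equal(nrow(w2), 3)
  expect_equal(w2$n_snps, c(400, 400, 100))
  expect_equal(w2$partial, c(FALSE, FALSE, TRUE))
  # window means equal a slice-and-average oracle
  expect_equal(w2$mean_hi, c(mean(rec2$hi[1:400]), mean(rec2$hi[401:800]),
                             mean(rec2$hi[801:900])))
})

test_that("fixed-width SNP-density windows match a histogram oracle", {
  g <- genome_map("c1", 1.05e6)
  empty <- tibble::tibble(chrom = character(0), pos = numeric(0),
                          donor_is_ref = logical(0))
  w0 <- window_snp_density(empty, g, window_bp = 2e5)
  expect_equal(nrow(w0), ceiling(1.05e6 / 2e5))
  expect_true(all(w0$n_snps == 0))

  d1 <- tibble::tibble(chrom = "c1", pos = seq(5000, 150000, by = 15000),
                       donor_is_ref = TRUE)
  w1 <- window_snp_density(d1, g, window_bp = 2e5)
  expect_equal(w1$n_snps[1], 10)
  expect_true(all(w1$n_snps[-1] == 0))

  set.seed(51)
  pos <- sort(sample(1:1.05e6, 500))
  d2 <- tibble::tibble(chrom = "c1", pos = pos, donor_is_ref = TRUE)
  w2 <- window_snp_density(d2, g, window_bp = 2e5)
  oracle <- tabulate(floor((pos - 1) / 2e5) + 1, nbins = nrow(w2))
  expect_equal(w2$n_snps, oracle)

  # inverted/colinear labels follow the window midpoint
  inv <- tibble::tibble(chrom = "c1", start = 3e5, end = 8e5,
                        species_label = "mon")
  w3 <- window_snp_density(d2, g, window_bp = 2e5, inversions = inv)
  expect_equal(w3$partition,
               c("colinear", "inverted", "inverted", "inverted", "colinear",
                 "colinear"))
})

test_that("count tables round-trip through TSV", {
  tb <- two_pool_table("c1", c(100, 200), ad1 = c(5, 7), dp1 = c(90, 95),
                       ad2 = c(0, 3), dp2 = c(88, 92))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(tb, p)
  back <- read_counts_tsv(p)
  expect_equal(as.data.frame(back), as.data.frame(tb))
})
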