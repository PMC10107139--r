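#' Read and write per-site allele-count tables
#'
#' The pipeline's exchange format is a TSV with columns `chrom`, `pos`
#' (1-based), `ref`, `alt`, then one `AD_<pool>` (reads supporting the
#' alternate allele) and `DP_<pool>` (total read depth) pair per pool.
#'
#' @param path File path.
#' @return A tibble in the count-table layout.
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    chrom = readr::col_character(),
                    pos = readr::col_double(),
                    ref = readr::col_character(),
                    alt = readr::col_character(),
                    .default = readr::col_double()
                  ))
}

#' @rdname read_counts_tsv
#' @param counts Count-table tibble.
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read pool allele counts from a VCF
#'
#' Minimal VCF ingest: pulls the per-sample `AD` and `DP` FORMAT fields for
#' biallelic SNPs into the count-table layout used by the rest of the
#' pipeline. Requires the vcfR package.
#'
#' @param path Path to a VCF file.
#' @param pools Optional character vector of sample names to keep (default:
#'   all samples).
#' @return A count-table tibble (see [read_counts_tsv()]).
#' @export
read_counts_vcf <- function(path, pools = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  keep <- !grepl(",", fix[, "ALT"]) & nchar(fix[, "REF"]) == 1L &
    nchar(fix[, "ALT"]) == 1L
  ad <- vcfR::extract.gt(v, "AD")  # "ref,alt" per sample
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
  if (is.null(pools)) pools <- colnames(ad)
  out <- tibble::tibble(
    chrom = fix[keep, "CHROM"],
    pos = as.numeric(fix[keep, "POS"]),
    ref = fix[keep, "REF"],
    alt = fix[keep, "ALT"]
  )
  for (p in pools) {
    alt_counts <- vapply(strsplit(ad[keep, p], ","), function(x) {
      if (length(x) >= 2L) as.numeric(x[2L]) else NA_real_
    }, 0)
    out[[paste0("AD_", p)]] <- alt_counts
    out[[paste0("DP_", p)]] <- dp[keep, p]
  }
  out
}

pool_names <- function(counts) {
  sub("^AD_", "", grep("^AD_", names(counts), value = TRUE))
}

#' Filter sites by coverage and minor-allele count
#'
#' Heuristic pool-seq site filters: a site is kept iff, in every pool, its
#' depth is at least `min_cov` and at most that pool-and-chromosome's
#' `max_cov_quantile` depth quantile, and the minor-allele read count reaches
#' `min_count`. By default the minor count is summed across pools (the
#' global behaviour of heuristic pool-seq SNP callers); `per_pool = TRUE`
#' requires it in every pool instead.
#'
#' @param counts Count-table tibble (see [read_counts_tsv()]).
#' @param min_count Minimum minor-allele read count (default 5).
#' @param min_cov Minimum depth per pool (default 80).
#' @param max_cov_quantile Maximum-depth quantile per pool per chromosome
#'   (default 0.95); sites above it are dropped.
#' @param per_pool Apply the minor-count rule per pool rather than summed.
#' @return The filtered count table.
#' @export
call_sites <- function(counts, min_count = 5, min_cov = 80,
                       max_cov_quantile = 0.95, per_pool = FALSE) {
  pools <- pool_names(counts)
  if (length(pools) == 0L) stop("no AD_/DP_ pool columns found")
  if (nrow(counts) == 0L) return(counts)
  keep <- rep(TRUE, nrow(counts))
  for (p in pools) {
    dp <- counts[[paste0("DP_", p)]]
    # per-pool, per-chromosome maximum-coverage threshold
    thr <- stats::ave(dp, counts$chrom, FUN = function(x)
      stats::quantile(x, max_cov_quantile, names = FALSE))
    keep <- keep & dp >= min_cov & dp <= thr
  }
  ad_cols <- paste0("AD_", pools)
  dp_cols <- paste0("DP_", pools)
  if (per_pool) {
    for (p in pools) {
      ad <- counts[[paste0("AD_", p)]]
      dp <- counts[[paste0("DP_", p)]]
      keep <- keep & pmin(ad, dp - ad) >= min_count
    }
  } else {
    ad_sum <- Reduce(`+`, counts[ad_cols])
    dp_sum <- Reduce(`+`, counts[dp_cols])
    keep <- keep & pmin(ad_sum, dp_sum - ad_sum) >= min_count
  }
  counts[keep, , drop = FALSE]
}

#' Identify diagnostic (differentially fixed) SNPs between parental pools
#'
#' A site is diagnostic when its allele frequency (AD/DP) is exactly 1 in
#' one parental pool and exactly 0 in the other: all reads of one pool
#' support the alternate allele and all reads of the other support the
#' reference. The orientation flag `donor_is_ref` records whether the donor
#' pool is the one fixed for the reference allele.
#'
#' @param counts_donor,counts_recipient Count tables for the two parental
#'   pools, each with a single pool column pair (or `pool` naming which).
#' @param pool_donor,pool_recipient Pool names within each table (default:
#'   the single pool present).
#' @param tol Fixity tolerance on allele frequency (default 0: exact).
#' @return Tibble `chrom`, `pos`, `ref`, `alt`, `donor_is_ref`, with the
#'   number of depth-zero sites skipped attached as attribute
#'   `"n_zero_dp"`.
#' @export
diagnostic_snps <- function(counts_donor, counts_recipient,
                            pool_donor = pool_names(counts_donor)[1],
                            pool_recipient = pool_names(counts_recipient)[1],
                            tol = 0) {
  d <- counts_donor[, c("chrom", "pos", "ref", "alt",
                        paste0(c("AD_", "DP_"), pool_donor))]
  r <- counts_recipient[, c("chrom", "pos", "ref", "alt",
                            paste0(c("AD_", "DP_"), pool_recipient))]
  names(d)[5:6] <- c("ad_d", "dp_d")
  names(r)[5:6] <- c("ad_r", "dp_r")
  j <- dplyr::inner_join(d, r, by = c("chrom", "pos", "ref", "alt"))
  zero_dp <- j$dp_d == 0 | j$dp_r == 0
  n_zero <- sum(zero_dp)
  j <- j[!zero_dp, , drop = FALSE]
  af_d <- j$ad_d / j$dp_d
  af_r <- j$ad_r / j$dp_r
  fixed_alt_d <- af_d >= 1 - tol & af_r <= tol
  fixed_ref_d <- af_d <= tol & af_r >= 1 - tol
  keep <- fixed_alt_d | fixed_ref_d
  out <- tibble::tibble(
    chrom = j$chrom[keep], pos = j$pos[keep], ref = j$ref[keep],
    alt = j$alt[keep], donor_is_ref = fixed_ref_d[keep]
  )
  attr(out, "n_zero_dp") <- n_zero
  out
}

#' Per-SNP hybrid index of a backcross pool
#'
#' At each diagnostic SNP the hybrid index is the donor-allele frequency in
#' the backcross pool: `AD/DP` when the donor species carries the alternate
#' allele, and `1 - AD/DP` when the donor carries the reference allele (so
#' an alternate-allele frequency of 87.5% at a donor-is-reference site
#' becomes a hybrid index of 12.5%). Because backcross females inherit at
#' most one donor allele per locus, the true hybrid index is at most 0.5;
#' records with a computed value strictly above 0.5 are discarded (and
#' counted), as are diagnostic sites missing from the table or with zero
#' depth.
#'
#' @param bc_counts Count table of the backcross pool.
#' @param diagnostics Output of [diagnostic_snps()].
#' @param pool Pool name within `bc_counts`.
#' @return Tibble `chrom`, `pos`, `hi` with attributes `n_discarded`
#'   (HI > 0.5), `n_missing` (diagnostic site absent or zero depth).
#' @export
hi_per_snp <- function(bc_counts, diagnostics,
                       pool = pool_names(bc_counts)[1]) {
  if (nrow(diagnostics) == 0L) stop("no diagnostic SNPs supplied")
  b <- bc_counts[, c("chrom", "pos", paste0(c("AD_", "DP_"), pool))]
  names(b)[3:4] <- c("ad", "dp")
  j <- dplyr::left_join(diagnostics, b, by = c("chrom", "pos"))
  missing <- is.na(j$dp) | j$dp == 0
  n_missing <- sum(missing)
  j <- j[!missing, , drop = FALSE]
  af <- j$ad / j$dp
  hi <- ifelse(j$donor_is_ref, 1 - af, af)
  over <- hi > 0.5
  n_disc <- sum(over)
  out <- tibble::tibble(chrom = j$chrom[!over], pos = j$pos[!over],
                        hi = hi[!over])
  attr(out, "n_discarded") <- n_disc
  attr(out, "n_missing") <- n_missing
  out
}

#' Per-chromosome summaries of per-SNP hybrid index
#'
#' @param records Tibble from [hi_per_snp()].
#' @return Tibble `chrom`, `mean_hi`, `sd_hi` (sample SD), `n_snps`,
#'   `zero_fraction` (fraction of SNPs with hybrid index exactly 0, i.e.
#'   no introgressed material).
#' @export
chrom_summary <- function(records) {
  records |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(
      mean_hi = mean(.data$hi),
      sd_hi = stats::sd(.data$hi),
      n_snps = dplyr::n(),
      zero_fraction = mean(.data$hi == 0),
      .groups = "drop"
    )
}

#' Mean hybrid index in non-overlapping SNP windows
#'
#' Blocks of `window_snps` consecutive SNPs (in position order, per
#' chromosome); the trailing block, if smaller, is flagged partial.
#'
#' @param records Tibble from [hi_per_snp()].
#' @param window_snps SNPs per window (default 400).
#' @return Tibble `chrom`, `window`, `start`, `end` (positions of first and
#'   last SNP), `n_snps`, `mean_hi`, `partial`.
#' @export
window_hi <- function(records, window_snps = 400L) {
  records |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$pos, .by_group = TRUE) |>
    dplyr::mutate(window = (dplyr::row_number() - 1L) %/% window_snps + 1L) |>
    dplyr::group_by(.data$chrom, .data$window) |>
    dplyr::summarise(
      start = min(.data$pos), end = max(.data$pos),
      n_snps = dplyr::n(), mean_hi = mean(.data$hi),
      partial = dplyr::n() < window_snps,
      .groups = "drop"
    )
}

#' Diagnostic-SNP counts in fixed-width genomic windows
#'
#' Divides each chromosome into non-overlapping `window_bp` windows
#' (`[0, 200k)`, `[200k, 400k)`, ...) and counts the diagnostic SNPs in
#' each. When inversions are supplied, a window is labelled `"inverted"`
#' iff its midpoint lies inside the chromosome's inversion union, else
#' `"colinear"`.
#'
#' @param diagnostics Tibble from [diagnostic_snps()] (1-based positions).
#' @param genome A [genome_map()].
#' @param window_bp Window width in bp (default 200,000).
#' @param inversions Optional inversion tibble for partition labels.
#' @return Tibble `chrom`, `window`, `start`, `end` (0-based half-open),
#'   `n_snps`, `partition`.
#' @export
window_snp_density <- function(diagnostics, genome, window_bp = 200000,
                               inversions = NULL) {
  out <- lapply(seq_len(nrow(genome)), function(ci) {
    ch <- genome$chrom[ci]
    L <- genome$length[ci]
    n_win <- ceiling(L / window_bp)
    start <- (seq_len(n_win) - 1) * window_bp
    end <- pmin(start + window_bp, L)
    pos0 <- diagnostics$pos[diagnostics$chrom == ch] - 1  # to 0-based
    idx <- pmin(floor(pos0 / window_bp), n_win - 1) + 1
    cnt <- tabulate(idx, nbins = n_win)
    union <- inversion_union(inversions, ch)
    mid <- (start + end) / 2
    part <- vapply(mid, function(m) iv_contains(union, m), TRUE)
    tibble::tibble(
      chrom = ch, window = seq_len(n_win), start = start, end = end,
      n_snps = cnt,
      partition = ifelse(part, "inverted", "colinear")
    )
  })
  dplyr::bind_rows(out)
}
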