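#' Define a simulation scenario
#'
#' Three nested models of the backcross experiment are simulated per
#' chromosome:
#' \describe{
#'   \item{SIM1}{neutral introgression — free recombination, no selection;}
#'   \item{SIM2}{neutral inversions — crossovers landing inside the inversion
#'     union of a heterokaryotypic mother are suppressed;}
#'   \item{SIM3}{inversions plus a single dominant incompatibility locus
#'     inside the inverted region: females heterozygous for the donor allele
#'     at that locus are not produced beyond the F1 generation.}
#' }
#'
#' @param kind One of `"SIM1"`, `"SIM2"`, `"SIM3"`.
#' @param inversions Inversion tibble (required for SIM2/SIM3 to have any
#'   effect); see [load_inversions()].
#' @param bdmi_placement SIM3 only: `"random_in_inversion"` (position drawn
#'   uniformly from the chromosome's inversion union, independently per
#'   replicate) or a single numeric bp position.
#' @param suppression How a crossover inside the inversion union of a
#'   heterokaryotypic mother is handled: `"suppress"` (the gamete is a
#'   non-recombinant parental chromatid, mirroring the loss of
#'   single-crossover products in Drosophila inversion heterozygotes) or
#'   `"resample"` (the crossover position is redrawn uniformly from the
#'   colinear part).
#' @param max_redraws SIM3: redraw budget per required offspring before
#'   erroring (guards configurations where a required mother class is
#'   impossible).
#' @return A `scenario` object.
#' @export
scenario <- function(kind = c("SIM1", "SIM2", "SIM3"), inversions = NULL,
                     bdmi_placement = "random_in_inversion",
                     suppression = c("suppress", "resample"),
                     max_redraws = 10000L) {
  kind <- match.arg(kind)
  suppression <- match.arg(suppression)
  if (kind == "SIM3" && is.character(bdmi_placement) &&
      !identical(bdmi_placement, "random_in_inversion")) {
    stop("bdmi_placement must be 'random_in_inversion' or a bp position")
  }
  structure(
    list(kind = kind, inversions = inversions,
         bdmi_placement = bdmi_placement, suppression = suppression,
         max_redraws = as.integer(max_redraws)),
    class = "scenario"
  )
}

# Does the pair of haplotypes differ in ancestry anywhere inside `region`?
# (i.e. is the mother heterokaryotypic for the inversion union)
heterokaryotypic <- function(h_mat, h_pat, region) {
  if (nrow(region) == 0L) return(FALSE)
  a <- iv_intersect(hap_tracts_of(h_mat, "mon"), region)
  b <- iv_intersect(hap_tracts_of(h_pat, "mon"), region)
  iv_symdiff_length(a, b) > 0
}

# Recombinant chromatid: prefix of hA on [0, x) followed by suffix of hB on
# [x, L), merging the junction when both sides share ancestry.
splice_haplotypes <- function(hA, hB, x) {
  ia <- hA$s < x
  ib <- hB$e > x
  s <- c(hA$s[ia], pmax(hB$s[ib], x))
  e <- c(pmin(hA$e[ia], x), hB$e[ib])
  a <- c(hA$a[ia], hB$a[ib])
  na <- sum(ia)
  if (na > 0L && na < length(a) && a[na] == a[na + 1L]) {
    # same ancestry across the junction: fuse the two tracts
    e[na] <- e[na + 1L]
    s <- s[-(na + 1L)]; e <- e[-(na + 1L)]; a <- a[-(na + 1L)]
  }
  structure(list(s = s, e = e, a = a, L = hA$L), class = "haplotype")
}

#' Simulate one female meiosis and return the transmitted gamete
#'
#' The meiosis model is one obligate crossover per tetrad with the crossover
#' position uniform on the chromosome, consistent with a 50 cM map: of the
#' four chromatids, two are parental and two are single-crossover
#' recombinants, and the transmitted chromatid is drawn uniformly — so the
#' gamete is recombinant with probability 1/2. Under SIM2/SIM3, if the mother
#' is heterokaryotypic for the chromosome's inversion union and the crossover
#' position falls inside that union, the single-crossover products are lost
#' and an intact parental chromatid is transmitted instead (or, with
#' `suppression = "resample"`, the crossover is redrawn from the colinear
#' part).
#'
#' @param mother An [individual()] (only the named chromosome is used).
#' @param chrom Chromosome name.
#' @param scen A [scenario()].
#' @return A [haplotype()] — the transmitted gamete.
#' @export
meiosis <- function(mother, chrom, scen) {
  hp <- mother$chroms[[chrom]]
  if (is.null(hp)) stop("unknown chromosome: ", chrom)
  meiosis_hap(hp$maternal, hp$paternal, scen, chrom)
}

# low-level meiosis on a haplotype pair; `union` precomputable by callers
meiosis_hap <- function(h1, h2, scen, chrom,
                        union = inversion_union(scen$inversions, chrom)) {
  L <- h1$L
  x <- stats::runif(1L, 0, L)
  suppressed <- FALSE
  if (scen$kind != "SIM1" && nrow(union) > 0L && iv_contains(union, x) &&
      heterokaryotypic(h1, h2, union)) {
    if (scen$suppression == "suppress") {
      suppressed <- TRUE
    } else {
      # redraw uniformly from the colinear fraction of the chromosome
      repeat {
        x <- stats::runif(1L, 0, L)
        if (!iv_contains(union, x)) break
      }
    }
  }
  u <- stats::runif(1L)
  if (suppressed || u < 0.5) {
    # intact parental chromatid
    if (u %% 0.5 < 0.25) h1 else h2
  } else if (u < 0.75) {
    splice_haplotypes(h1, h2, x)
  } else {
    splice_haplotypes(h2, h1, x)
  }
}

#' Screen an offspring against the incompatibility locus
#'
#' Under SIM3 a single dominant-acting donor locus cannot be introgressed
#' beyond the F1 generation: backcross females heterozygous for it are not
#' produced. In the backcross design donor ancestry only ever occurs on the
#' maternal haplotype, so an offspring is rejected iff its maternal haplotype
#' carries donor ancestry at the locus.
#'
#' @param offspring An [individual()].
#' @param bdmi_position Locus position in bp.
#' @param chrom Chromosome name.
#' @param donor Donor ancestry label.
#' @return `TRUE` (accept) or `FALSE` (reject).
#' @export
apply_bdmi <- function(offspring, bdmi_position, chrom, donor) {
  hp <- offspring$chroms[[chrom]]
  if (is.null(hp)) stop("unknown chromosome: ", chrom)
  if (bdmi_position < 0 || bdmi_position >= hp$maternal$L) {
    stop("bdmi_position outside chromosome")
  }
  hap_ancestry_at(hp$maternal, bdmi_position) != donor
}

# gamete-level rejection used in the hot loop
gamete_rejected <- function(gamete, bdmi_position, donor) {
  hap_ancestry_at(gamete, bdmi_position) == donor
}

# draw a gamete, redrawing until it passes the SIM3 screen (fecundity
# compensation: selection does not shrink the conditioned offspring counts)
draw_accepted_gamete <- function(h1, h2, scen, chrom, union, bdmi_pos, donor) {
  for (i in seq_len(scen$max_redraws)) {
    g <- meiosis_hap(h1, h2, scen, chrom, union)
    if (is.null(bdmi_pos) || !gamete_rejected(g, bdmi_pos, donor)) return(g)
  }
  stop("max_redraws exceeded: required offspring class may be impossible")
}

#' Run one replicate of the crossing experiment
#'
#' Simulates F1 -> BC1 -> BC2 for every chromosome of the genome under the
#' given scenario, conditioned on the pedigree (which BC1 mother each BC2
#' female has, and which F1 mother each BC1 female has). F1 females are
#' donor/recipient heterozygotes over the whole genome; every backcross uses
#' a pure recipient father, so only the maternally transmitted haplotype
#' segregates. Under SIM3 rejected offspring are redrawn until the pedigree
#' counts are met.
#'
#' @param pedigree A [pedigree_config()].
#' @param genome A [genome_map()].
#' @param scen A [scenario()].
#' @param depth Generation of the pooled females: 1 = F1, 2 = BC1,
#'   3 = BC2 (default).
#' @param keep_pool If `TRUE`, attach the pooled females' maternal haplotypes
#'   (attribute `"pool"`, a list by chromosome) for downstream read
#'   simulation.
#' @param check_bdmi If `TRUE` (default), assert that no pooled female
#'   carries donor ancestry at the SIM3 locus.
#' @return Named numeric vector: mean hybrid index of the pool per
#'   chromosome. The drawn locus position per chromosome is attached as
#'   attribute `"bdmi_position"` under SIM3.
#' @export
run_replicate <- function(pedigree, genome, scen, depth = 3L,
                          keep_pool = FALSE, check_bdmi = TRUE) {
  stopifnot(depth %in% 1:3)
  donor <- direction_labels(pedigree$direction)$donor
  recipient <- direction_labels(pedigree$direction)$recipient
  out <- stats::setNames(numeric(nrow(genome)), genome$chrom)
  pool_haps <- if (keep_pool) stats::setNames(
    vector("list", nrow(genome)), genome$chrom) else NULL
  bdmi_positions <- stats::setNames(rep(NA_real_, nrow(genome)), genome$chrom)

  for (ci in seq_len(nrow(genome))) {
    ch <- genome$chrom[ci]
    L <- genome$length[ci]
    union <- inversion_union(scen$inversions, ch)
    bdmi_pos <- NULL
    if (scen$kind == "SIM3") {
      if (is.numeric(scen$bdmi_placement)) {
        bdmi_pos <- scen$bdmi_placement
        if (bdmi_pos < 0 || bdmi_pos >= L) stop("bdmi position outside ", ch)
      } else if (nrow(union) > 0L) {
        # uniform over the union, weighting intervals by length
        w <- union[, 2L] - union[, 1L]
        k <- sample.int(nrow(union), 1L, prob = w)
        bdmi_pos <- stats::runif(1L, union[k, 1L], union[k, 2L])
      } else {
        stop("SIM3 with random placement requires an inversion on ", ch)
      }
      bdmi_positions[ch] <- bdmi_pos
    }

    h_donor <- pure_haplotype(donor, L)
    h_recip <- pure_haplotype(recipient, L)

    if (depth == 1L) {
      # pool = F1 females: donor fraction is exactly 1/2
      out[ch] <- 0.5
      if (keep_pool) pool_haps[[ch]] <-
          rep(list(h_donor), pedigree$pool_size)
      next
    }

    # BC1 gametes from F1 mothers (F1 = pure donor / pure recipient pair)
    n_bc1 <- sum(pedigree$bc1_per_f1)
    bc1 <- vector("list", n_bc1)
    for (j in seq_len(n_bc1)) {
      bc1[[j]] <- draw_accepted_gamete(h_donor, h_recip, scen, ch, union,
                                       bdmi_pos, donor)
    }

    if (depth == 2L) {
      pool <- bc1
    } else {
      # BC2 gametes, conditioned on each BC1 mother's contribution
      mother_of <- rep.int(seq_len(n_bc1), pedigree$bc2_per_bc1)
      pool <- vector("list", length(mother_of))
      for (j in seq_along(mother_of)) {
        hm <- bc1[[mother_of[j]]]
        pool[[j]] <- draw_accepted_gamete(hm, h_recip, scen, ch, union,
                                          bdmi_pos, donor)
      }
    }

    if (!is.null(bdmi_pos) && check_bdmi) {
      ok <- !vapply(pool, gamete_rejected, TRUE, bdmi_pos, donor)
      if (!all(ok)) stop("internal error: pooled female carries donor ",
                         "ancestry at the incompatibility locus")
    }

    # pool HI: donor length on the maternal haplotype / 2L (father is pure)
    hi <- vapply(pool, hap_donor_length, 0, donor) / (2 * L)
    out[ch] <- mean(hi)
    if (keep_pool) pool_haps[[ch]] <- pool
  }

  if (scen$kind == "SIM3") attr(out, "bdmi_position") <- bdmi_positions
  if (keep_pool) attr(out, "pool") <- pool_haps
  out
}

# replicate-level seed stream: replicate r reproducible in isolation
replicate_seed <- function(master_seed, r) {
  (as.numeric(master_seed) + r * 10007) %% 2147483647
}

#' Simulate the replicate distribution of chromosome-wise mean hybrid index
#'
#' Runs [run_replicate()] `n_replicates` times with per-replicate seeds
#' derived from the master seed, so any single replicate can be reproduced
#' in isolation.
#'
#' @inheritParams run_replicate
#' @param n_replicates Number of replicates (the study design uses 10,000).
#' @param seed Master seed (integer).
#' @return Numeric matrix, `n_replicates` x chromosomes, of replicate mean
#'   hybrid index.
#' @export
simulate_mean_hi <- function(pedigree, genome, scen, n_replicates = 10000L,
                             seed = 1L, depth = 3L) {
  stopifnot(n_replicates >= 1L)
  m <- matrix(NA_real_, nrow = n_replicates, ncol = nrow(genome),
              dimnames = list(NULL, genome$chrom))
  for (r in seq_len(n_replicates)) {
    set.seed(replicate_seed(seed, r))
    m[r, ] <- run_replicate(pedigree, genome, scen, depth = depth,
                            check_bdmi = FALSE)
  }
  m
}

#' Build simulation envelopes for chromosome-wise mean hybrid index
#'
#' Per chromosome, the empirical 5% and 95% quantiles of the replicate mean
#' hybrid index, Bonferroni-corrected for the number of chromosome units
#' tested: the band runs from the `alpha/n_tests` to the `1 - alpha/n_tests`
#' quantile. An observed mean outside this band is considered statistically
#' different from the simulated model.
#'
#' @inheritParams simulate_mean_hi
#' @param alpha Nominal one-sided tail level (default 0.05).
#' @param n_tests Bonferroni correction factor; defaults to the number of
#'   chromosomes in `genome`.
#' @return A tibble of class `sim_envelope` with columns `chrom`, `lower`,
#'   `upper`, `n_replicates`, `alpha`, `n_tests`; the replicate matrix is
#'   attached as attribute `"replicates"`.
#' @export
build_envelope <- function(pedigree, genome, scen, n_replicates = 10000L,
                           alpha = 0.05, n_tests = nrow(genome), seed = 1L) {
  if (n_replicates < 2L) stop("n_replicates must be >= 2")
  if (n_tests < 1L) stop("n_tests must be >= 1")
  m <- simulate_mean_hi(pedigree, genome, scen, n_replicates, seed)
  envelope_from_replicates(m, alpha = alpha, n_tests = n_tests)
}

#' @rdname build_envelope
#' @param replicates Matrix of replicate mean hybrid index (replicates x
#'   chromosomes), e.g. from [simulate_mean_hi()].
#' @export
envelope_from_replicates <- function(replicates, alpha = 0.05,
                                     n_tests = ncol(replicates)) {
  if (n_tests < 1L) stop("n_tests must be >= 1")
  p_lo <- alpha / n_tests
  p_hi <- 1 - alpha / n_tests
  env <- tibble::tibble(
    chrom = colnames(replicates),
    lower = unname(apply(replicates, 2L, stats::quantile, probs = p_lo,
                         names = FALSE)),
    upper = unname(apply(replicates, 2L, stats::quantile, probs = p_hi,
                         names = FALSE)),
    n_replicates = nrow(replicates),
    alpha = alpha,
    n_tests = as.integer(n_tests)
  )
  attr(env, "replicates") <- replicates
  class(env) <- c("sim_envelope", class(env))
  env
}

#' Classify observed mean hybrid index against a simulation envelope
#'
#' @param observed Named numeric vector of observed per-chromosome mean
#'   hybrid index (names matched against the envelope's chromosomes).
#' @param envelope A `sim_envelope` from [build_envelope()].
#' @return Tibble with columns `chrom`, `observed`, `lower`, `upper`,
#'   `classification` (`"below"`, `"within"`, `"above"`; bounds inclusive).
#' @export
classify_hi <- function(observed, envelope) {
  chroms <- names(observed)
  if (is.null(chroms)) stop("`observed` must be a named vector")
  miss <- setdiff(chroms, envelope$chrom)
  if (length(miss)) stop("no envelope for chromosome(s): ",
                         paste(miss, collapse = ", "))
  i <- match(chroms, envelope$chrom)
  lo <- envelope$lower[i]; hi <- envelope$upper[i]
  cls <- unname(ifelse(observed < lo, "below",
                       ifelse(observed > hi, "above", "within")))
  tibble::tibble(chrom = chroms, observed = unname(as.numeric(observed)),
                 lower = lo, upper = hi, classification = cls)
}
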