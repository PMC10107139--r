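# Exact rationals as (num, den) integer pairs; all arithmetic stays integral
# until rendering. Magnitudes here stay tiny (denominators < 1e6), far below
# double-precision exact-integer range.

rat <- function(num, den = 1) {
  if (den == 0) stop("zero denominator")
  if (den < 0) { num <- -num; den <- -den }
  g <- rat_gcd(abs(num), den)
  if (g > 0) { num <- num / g; den <- den / g }
  list(num = num, den = den)
}

rat_gcd <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

rat_add <- function(a, b) rat(a$num * b$den + b$num * a$den, a$den * b$den)
rat_mul <- function(a, b) rat(a$num * b$num, a$den * b$den)
rat_div <- function(a, b) {
  if (b$num == 0) stop("division by zero")
  rat(a$num * b$den, a$den * b$num)
}
rat_num <- function(a) a$num / a$den
rat_str <- function(a) paste0(a$num, "/", a$den)

#' Expected hybrid index by generation
#'
#' The expected fraction of donor-species genetic material halves with every
#' generation of the crossing design: 50% in F1 females, 25% in BC1, 12.5%
#' in the sequenced BC2 pools.
#'
#' @param generation Integer >= 1: 1 = F1, 2 = BC1, 3 = BC2, and so on.
#' @return Expected hybrid index as a fraction (`0.5^generation`).
#' @examples
#' expected_hi(3)  # 0.125, the BC2 neutral expectation
#' @export
expected_hi <- function(generation) {
  if (any(generation < 1) || any(generation != round(generation))) {
    stop("generation must be an integer >= 1")
  }
  0.5^generation
}

# The four two-locus genotype classes a backcross female can carry when every
# individual inherits at most one donor allele per locus: A in {A1A2, A2A2},
# B in {B1B2, B2B2}. Class i is (het_A, het_B) flags.
bdmi_classes <- function() {
  expand.grid(het_A = c(TRUE, FALSE), het_B = c(TRUE, FALSE))
}

# Offspring class distribution of a mother class crossed to a recipient male
# (A2A2 B2B2), unlinked loci: each heterozygous locus transmits the donor
# allele with probability 1/2.
offspring_dist <- function(mother_het_A, mother_het_B) {
  half <- rat(1, 2); one <- rat(1, 1); zero <- rat(0, 1)
  pA <- if (mother_het_A) half else zero  # P(offspring het at A)
  pB <- if (mother_het_B) half else zero
  cls <- bdmi_classes()
  prob <- vector("list", nrow(cls))
  for (i in seq_len(nrow(cls))) {
    pa <- if (cls$het_A[i]) pA else rat_add(one, rat(-pA$num, pA$den))
    pb <- if (cls$het_B[i]) pB else rat_add(one, rat(-pB$num, pB$den))
    prob[[i]] <- rat_mul(pa, pb)
  }
  prob
}

#' Expected allele frequencies under a two-locus dominant-recessive
#' incompatibility
#'
#' Enumerates, with exact rational arithmetic, the genotype-class frequencies
#' over successive backcrosses of an F1 double heterozygote (A1A2 B1B2) to
#' recipient-species males, where the donor allele A1 acts dominantly and is
#' incompatible with the homozygous recipient genotype B2B2: carriers of A1
#' together with B2B2 are removed each generation. Mothers contribute to the
#' next generation in proportion to their surviving-offspring fraction
#' (fecundity is fixed; selection removes a fraction of each mother's
#' offspring), which is the weighting under which two backcross generations
#' give donor-allele frequencies of exactly 1/22 at the dominant locus and
#' 2/11 at the recessively-interacting locus.
#'
#' @param n_backcross_generations Number of backcross generations (2 = the
#'   sequenced BC2 pool).
#' @param selection If `FALSE`, the incompatible class is retained and both
#'   frequencies reduce to neutral halving, `0.5^(n+1)`.
#' @return A list with exact rationals and decimals:
#'   `freq_A1` / `freq_B1` (numeric), `frac_A1` / `frac_B1` (strings like
#'   `"1/22"`), `percent_A1` / `percent_B1` (percentages rounded to one
#'   decimal), and `classes` — a tibble of surviving genotype-class
#'   frequencies in the final generation.
#' @examples
#' bdmi_expected_freqs(2)$frac_A1  # "1/22"
#' @export
bdmi_expected_freqs <- function(n_backcross_generations = 2L,
                                selection = TRUE) {
  n <- n_backcross_generations
  if (n < 1 || n != round(n)) {
    stop("n_backcross_generations must be an integer >= 1")
  }
  cls <- bdmi_classes()
  incompatible <- cls$het_A & !cls$het_B  # A1 carrier with B2B2
  # generation 0 = F1 mothers: all double heterozygotes
  freq <- list(rat(0), rat(0), rat(0), rat(0))
  freq[[which(cls$het_A & cls$het_B)]] <- rat(1)

  for (g in seq_len(n)) {
    nxt <- list(rat(0), rat(0), rat(0), rat(0))
    total <- rat(0)
    for (i in seq_len(nrow(cls))) {
      if (freq[[i]]$num == 0) next
      off <- offspring_dist(cls$het_A[i], cls$het_B[i])
      for (j in seq_len(nrow(cls))) {
        if (selection && incompatible[j]) next
        # mother weight x offspring fraction: mothers are NOT renormalised
        # per class, so a mother class losing offspring to selection
        # contributes proportionally less (surviving-offspring weighting)
        w <- rat_mul(freq[[i]], off[[j]])
        nxt[[j]] <- rat_add(nxt[[j]], w)
        total <- rat_add(total, w)
      }
    }
    if (total$num == 0) stop("all offspring classes removed by selection")
    freq <- lapply(nxt, rat_div, total)
  }

  half <- rat(1, 2)
  fA <- rat(0); fB <- rat(0)
  for (i in seq_len(nrow(cls))) {
    if (cls$het_A[i]) fA <- rat_add(fA, rat_mul(freq[[i]], half))
    if (cls$het_B[i]) fB <- rat_add(fB, rat_mul(freq[[i]], half))
  }

  classes <- tibble::tibble(
    genotype_A = ifelse(cls$het_A, "A1A2", "A2A2"),
    genotype_B = ifelse(cls$het_B, "B1B2", "B2B2"),
    frequency = vapply(freq, rat_num, 0),
    fraction = vapply(freq, rat_str, "")
  )
  list(
    freq_A1 = rat_num(fA), freq_B1 = rat_num(fB),
    frac_A1 = rat_str(fA), frac_B1 = rat_str(fB),
    percent_A1 = round(100 * rat_num(fA), 1),
    percent_B1 = round(100 * rat_num(fB), 1),
    classes = classes
  )
}

#' Genotype-class enumeration table across generations
#'
#' Convenience wrapper returning the surviving genotype-class frequencies for
#' each backcross generation up to `n`, as one long tibble (generation x
#' class x frequency) — the full enumeration behind
#' [bdmi_expected_freqs()].
#'
#' @inheritParams bdmi_expected_freqs
#' @return A tibble with columns `generation`, `genotype_A`, `genotype_B`,
#'   `frequency`, `fraction`.
#' @export
bdmi_enumeration_table <- function(n_backcross_generations = 2L,
                                   selection = TRUE) {
  out <- lapply(seq_len(n_backcross_generations), function(g) {
    tab <- bdmi_expected_freqs(g, selection = selection)$classes
    tab$generation <- g
    tab[, c("generation", "genotype_A", "genotype_B", "frequency",
            "fraction")]
  })
  dplyr::bind_rows(out)
}
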