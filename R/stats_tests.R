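#' One-sample t-test of fertility scores against an expected value
#'
#' Tests whether binary fertility scores (1 = fertile, 0 = sterile) deviate
#' from an expected fertility, by a one-sample Student's t-test.
#'
#' @param scores Numeric vector of 0/1 fertility scores (n >= 2).
#' @param mu0 Expected value under the null (default 1, full fertility).
#' @return List with `t`, `df`, `p` (two-sided), `mean`.
#' @examples
#' one_sample_t(c(rep(1, 15), rep(0, 5)))  # t ~ -2.52, df 19
#' @export
one_sample_t <- function(scores, mu0 = 1) {
  scores <- as.numeric(scores)
  if (length(scores) < 2L) stop("need at least 2 scores")
  if (stats::sd(scores) == 0) {
    stop("degenerate input: all scores equal; t statistic undefined")
  }
  tt <- stats::t.test(scores, mu = mu0)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = mean(scores))
}

#' Binomial GLM comparing fertility between two groups
#'
#' Fits a logistic regression of the binary fertility outcome on group
#' membership and returns the Wald test for the group effect — the log-odds
#' difference of group B relative to group A. For a saturated 2x2 table
#' this equals `log(OR) / sqrt(sum of reciprocal cell counts)`.
#'
#' @param group_a,group_b Length-2 vectors `c(n, k)`: total and fertile
#'   counts per group.
#' @return List with `log_odds_diff`, `z`, `p` (two-sided Wald).
#' @examples
#' binomial_glm_z(c(20, 15), c(55, 23))  # z ~ -2.45
#' @export
binomial_glm_z <- function(group_a, group_b) {
  na <- group_a[1]; ka <- group_a[2]
  nb <- group_b[1]; kb <- group_b[2]
  cells <- c(ka, na - ka, kb, nb - kb)
  if (any(cells < 0) || ka > na || kb > nb) stop("invalid counts")
  if (any(cells == 0)) {
    stop("separation: a zero cell in the 2x2 table; the Wald z is not ",
         "defined (consider an exact test)")
  }
  y <- c(rep(1, ka), rep(0, na - ka), rep(1, kb), rep(0, nb - kb))
  g <- factor(c(rep("a", na), rep("b", nb)), levels = c("a", "b"))
  fit <- stats::glm(y ~ g, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-14,
                                                 maxit = 100))
  s <- summary(fit)$coefficients["gb", ]
  list(log_odds_diff = unname(s["Estimate"]),
       z = unname(s["z value"]),
       p = unname(s["Pr(>|z|)"]))
}

#' Poisson GLM on window-wise SNP counts
#'
#' Log-linear model of diagnostic-SNP counts per genomic window on a window
#' label — chromosomes, or the colinear/inverted partition. Returns the Wald
#' test for every non-reference level; for a two-group comparison the fitted
#' rate ratio equals the ratio of group mean counts.
#'
#' @param window_counts Integer vector of per-window SNP counts.
#' @param labels Factor or character vector of window labels (same length);
#'   the first level is the reference.
#' @return Tibble with one row per non-reference level: `level`,
#'   `rate_ratio`, `z`, `p`. Levels whose group is all-zero are skipped with
#'   a warning (separation).
#' @export
poisson_glm_density <- function(window_counts, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("need >= 2 label levels")
  if (length(window_counts) != length(labels)) stop("length mismatch")
  zero_groups <- tapply(window_counts, labels, function(x) all(x == 0))
  bad <- names(zero_groups)[zero_groups]
  if (length(bad)) {
    warning("separation: all-zero count group(s) skipped: ",
            paste(bad, collapse = ", "))
    keep <- !labels %in% bad
    window_counts <- window_counts[keep]
    labels <- droplevels(labels[keep])
    if (nlevels(labels) < 2L) stop("fewer than 2 usable groups remain")
  }
  fit <- stats::glm(window_counts ~ labels, family = stats::poisson())
  cf <- summary(fit)$coefficients
  rows <- grep("^labels", rownames(cf), value = TRUE)
  tibble::tibble(
    level = sub("^labels", "", rows),
    rate_ratio = exp(cf[rows, "Estimate"]),
    z = cf[rows, "z value"],
    p = cf[rows, "Pr(>|z|)"]
  )
}
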