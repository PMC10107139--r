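test_that("a homokaryotypic pure-recipient mother transmits pure gametes", {
  mom <- pure_individual("fla", "fla")
  set.seed(1)
  for (i in 1:20) {
    g <- meiosis(mom, "chr1", scenario("SIM1"))
    expect_equal(g$a, "fla")
    expect_equal(length(g$s), 1L)
  }
})

test_that("F1 meiosis transmits a recombinant chromatid half the time", {
  mom <- f1_individual("mon")
  set.seed(42)
  n <- 10000
  rec <- vapply(seq_len(n), function(i) {
    length(meiosis(mom, "chr1", scenario("SIM1"))$s) > 1L
  }, TRUE)
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(mean(rec) - 0.5), 3 * se)
})

test_that("inversion suppression removes the inverted fraction of recombinants", {
  f <- 0.4
  inv <- toy_inversions(f)
  mom <- f1_individual("mon")
  scen <- scenario("SIM2", inversions = inv)
  set.seed(7)
  n <- 10000
  rec <- vapply(seq_len(n), function(i) {
    length(meiosis(mom, "chr1", scen)$s) > 1L
  }, TRUE)
  expected <- 0.5 * (1 - f)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(mean(rec) - expected), 3 * se)
})

test_that("resampling mode keeps the map length but moves junctions out", {
  f <- 0.4
  inv <- toy_inversions(f)
  u <- inversion_union(inv, "chr1")
  mom <- f1_individual("mon")
  scen <- scenario("SIM2", inversions = inv, suppression = "resample")
  set.seed(11)
  n <- 8000
  junctions <- c()
  rec <- logical(n)
  for (i in seq_len(n)) {
    g <- meiosis(mom, "chr1", scen)
    rec[i] <- length(g$s) > 1L
    if (rec[i]) junctions <- c(junctions, g$s[2])
  }
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(rec) - 0.5), 3 * se)          # no recombinant loss
  expect_false(any(junctions >= u[1, 1] & junctions < u[1, 2]))
})

test_that("the incompatibility screen rejects donor carriers at the locus", {
  L <- 1e6
  ok <- individual(list(chr1 = list(
    maternal = haplotype(0, L, "fla", L),
    paternal = haplotype(0, L, "fla", L)
  )))
  expect_true(apply_bdmi(ok, 5e5, "chr1", donor = "mon"))
  carrier <- individual(list(chr1 = list(
    maternal = haplotype(c(0, 4e5, 6e5), c(4e5, 6e5, L),
                         c("fla", "mon", "fla"), L),
    paternal = haplotype(0, L, "fla", L)
  )))
  expect_false(apply_bdmi(carrier, 5e5, "chr1", donor = "mon"))
  expect_true(apply_bdmi(carrier, 9e5, "chr1", donor = "mon"))
  expect_error(apply_bdmi(carrier, 2e6, "chr1", donor = "mon"),
               "outside chromosome")
})

test_that("BC1 offspring of an F1 mother are rejected at the Mendelian rate", {
  mom <- f1_individual("mon")
  set.seed(3)
  n <- 10000
  rej <- vapply(seq_len(n), function(i) {
    g <- meiosis(mom, "chr1", scenario("SIM1"))
    hap_ancestry_at_test(g, 5e5) == "mon"
  }, TRUE)
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(rej) - 0.5), 3 * se)
})

test_that("pool at generation depth 1 has hybrid index exactly one half", {
  ped <- tiny_pedigree()
  g <- toy_genome()
  hi <- run_replicate(ped, g, scenario("SIM1"), depth = 1L)
  expect_identical(unname(hi), 0.5)
})

test_that("replicate gametes tile the chromosome and keep donor ancestry
           off the paternal side", {
  ped <- tiny_pedigree(pool_size = 12L, n_bc1 = 3L)
  g <- toy_genome()
  set.seed(5)
  hi <- run_replicate(ped, g, scenario("SIM2", inversions =
                                         toy_inversions(0.3)),
                      keep_pool = TRUE)
  pool <- attr(hi, "pool")$chr1
  expect_length(pool, 12L)
  for (h in pool) {
    expect_silent(poolHI:::validate_haplotype(h))
  }
})

test_that("SIM1 replicate means converge to the neutral expectation 0.125", {
  ped <- default_pedigree("to_fla")
  g <- toy_genome(30.6e6, "X")
  m <- simulate_mean_hi(ped, g, scenario("SIM1"), n_replicates = 2000,
                        seed = 123)
  se <- sd(m) / sqrt(length(m))
  expect_lt(abs(mean(m) - 0.125), 4 * se)
})

test_that("identical master seeds give bit-identical replicate vectors and
           different seeds do not", {
  ped <- tiny_pedigree()
  g <- toy_genome()
  a <- simulate_mean_hi(ped, g, scenario("SIM1"), n_replicates = 50,
                        seed = 9)
  b <- simulate_mean_hi(ped, g, scenario("SIM1"), n_replicates = 50,
                        seed = 9)
  c <- simulate_mean_hi(ped, g, scenario("SIM1"), n_replicates = 50,
                        seed = 10)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("donor tract counts fall monotonically with inversion span", {
  ped <- default_pedigree("to_fla")
  g <- toy_genome()
  mean_tracts <- vapply(c(0, 0.25, 0.5, 0.75), function(f) {
    scen <- scenario("SIM2", inversions = toy_inversions(f))
    tot <- 0; n <- 0
    for (r in 1:40) {
      set.seed(1000 + r)
      hi <- run_replicate(ped, g, scen, keep_pool = TRUE)
      pool <- attr(hi, "pool")$chr1
      tot <- tot + sum(vapply(pool, function(h) sum(h$a == "mon"), 0))
      n <- n + length(pool)
    }
    tot / n
  }, 0)
  expect_true(all(diff(mean_tracts) < 0))
})

test_that("no pooled female carries donor ancestry at the SIM3 locus", {
  inv <- toy_inversions(0.5)
  ped <- tiny_pedigree(pool_size = 20L, n_bc1 = 4L)
  g <- toy_genome()
  scen <- scenario("SIM3", inversions = inv, bdmi_placement = 5e5)
  for (r in 1:25) {
    set.seed(2000 + r)
    hi <- run_replicate(ped, g, scen, keep_pool = TRUE)  # check_bdmi on
    pool <- attr(hi, "pool")$chr1
    carries <- vapply(pool, function(h) hap_ancestry_at_test(h, 5e5) ==
                        "mon", TRUE)
    expect_false(any(carries))
  }
})

test_that("SIM3 without an inversion on the chromosome is rejected", {
  ped <- tiny_pedigree()
  g <- toy_genome()
  expect_error(
    run_replicate(ped, g, scenario("SIM3", inversions = NULL)),
    "requires an inversion"
  )
})

test_that("envelopes match an independent order-statistic computation", {
  set.seed(77)
  m <- matrix(rnorm(4000), ncol = 2,
              dimnames = list(NULL, c("c1", "c2")))
  env <- envelope_from_replicates(m, alpha = 0.05, n_tests = 6)
  # independent type-7 quantile: h = (n - 1) p + 1, linear interpolation
  q7 <- function(x, p) {
    x <- sort(x); n <- length(x)
    h <- (n - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[pmin(lo + 1, n)] - x[lo])
  }
  for (j in 1:2) {
    expect_equal(env$lower[j], q7(m[, j], 0.05 / 6))
    expect_equal(env$upper[j], q7(m[, j], 1 - 0.05 / 6))
  }
  expect_true(all(env$lower <= env$upper))
  expect_error(envelope_from_replicates(m, n_tests = 0), "n_tests")
})

test_that("a degenerate constant pool yields a zero-width envelope", {
  ped <- tiny_pedigree()
  g <- toy_genome()
  env <- build_envelope(ped, g, scenario("SIM1"), n_replicates = 20,
                        seed = 1, n_tests = 1)
  # depth-3 is stochastic; use depth-1 (F1 pool) via simulate + envelope
  m <- simulate_mean_hi(ped, g, scenario("SIM1"), n_replicates = 20,
                        seed = 1, depth = 1L)
  env1 <- envelope_from_replicates(m, n_tests = 1)
  expect_equal(env1$lower, 0.5)
  expect_equal(env1$upper, 0.5)
  expect_true(env$lower < env$upper)
})

test_that("classification is inclusive at the bounds and orders correctly", {
  m <- matrix(seq(0.05, 0.25, length.out = 100), ncol = 1,
              dimnames = list(NULL, "X"))
  env <- envelope_from_replicates(m, alpha = 0.05, n_tests = 1)
  at_lower <- stats::setNames(env$lower, "X")
  expect_equal(classify_hi(at_lower, env)$classification, "within")
  expect_equal(classify_hi(c(X = 0), env)$classification, "below")
  expect_equal(classify_hi(c(X = 0.5), env)$classification, "above")
  expect_error(classify_hi(c(Z = 0.1), env), "no envelope")
})
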