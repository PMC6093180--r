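test_that("unpairable or too-short sequences have Z = 1 and PU = 1", {
  m <- fast_model()
  pf <- partition_function("AAAAAAAAAA", m)
  expect_equal(pf$Z, 1)
  expect_equal(pf$logZ, 0)
  expect_equal(unname(pf$unpaired_prob), rep(1, 10))
  expect_equal(unpaired_probability("AAAAAAAAAA", c(3, 7), m), 1)

  # shorter than min_hairpin_loop + 2: no structure possible
  pf2 <- partition_function("GCGC", m)
  expect_equal(pf2$Z, 1)
  expect_equal(partition_function("G", m)$Z, 1)
  expect_error(partition_function("GXG", m), "invalid")
})

test_that("partition function and PU match exhaustive enumeration", {
  m <- fast_model()
  set.seed(71)
  for (rep in 1:40) {
    seq <- random_rna(sample(6:13, 1))
    o <- oracle_partition(seq, m)
    pf <- partition_function(seq, m)
    expect_lt(abs(pf$Z - o$Z) / o$Z, 1e-9)
    expect_lt(max(abs(pf$pair_prob - o$bpp)), 1e-9)
    expect_lt(max(abs(pf$unpaired_prob - o$unpaired)), 1e-9)
    n <- nchar(seq)
    i <- sample(seq_len(n - 1), 1); j <- sample(i:n, 1)
    expect_lt(abs(unpaired_probability(seq, c(i, j), m) - o$pu_span(i, j)),
              1e-9)
  }
})

test_that("per-base normalisation holds for longer random sequences", {
  m <- fast_model()
  set.seed(72)
  for (rep in 1:10) {
    seq <- random_rna(sample(30:80, 1))
    pf <- partition_function(seq, m)
    tot <- pf$unpaired_prob + rowSums(pf$pair_prob)
    expect_lt(max(abs(tot - 1)), 1e-9)
    expect_true(all(pf$pair_prob >= 0 & pf$pair_prob <= 1))
    expect_gte(pf$Z, 1)
  }
})

test_that("PU is monotone under span inclusion", {
  m <- fast_model()
  set.seed(73)
  for (rep in 1:60) {
    n <- sample(12:35, 1)
    seq <- random_rna(n)
    i <- sample1(1:(n - 3)); j <- sample1((i + 2):n)
    i2 <- sample1(i:j); j2 <- sample1(i2:j)
    pu_big <- unpaired_probability(seq, c(i, j), m)
    pu_small <- unpaired_probability(seq, c(i2, j2), m)
    expect_lte(pu_big, pu_small + 1e-12)
  }
})

test_that("low kT concentrates PU on the minimum-free-energy pattern", {
  cold <- energy_model(kT = 0.01)
  # perfect 5-bp hairpin: stem pairs, loop unpaired
  hp <- "GGGGGAAAACCCCC"
  pf <- partition_function(hp, cold)
  expect_lt(max(pf$unpaired_prob[c(1:5, 10:14)]), 1e-6)
  expect_gt(min(pf$unpaired_prob[6:9]), 1 - 1e-6)
})

test_that("pentamer PU averages its three context values, truncating at ends", {
  m <- fast_model()
  set.seed(74)
  seq <- random_rna(50)
  pp <- pentamer_pu(seq, 25, m)
  expect_equal(pp$pu_mean, mean(pp$pu_by_context))
  # direct recomputation on the truncated substrings
  for (L in c(10, 20, 30)) {
    lo <- max(1, 25 - 2 - L); hi <- min(50, 25 + 2 + L)
    sub <- substr(seq, lo, hi)
    want <- unpaired_probability(sub, c(25 - 2 - lo + 1, 25 + 2 - lo + 1), m)
    expect_equal(unname(pp$pu_by_context[paste0("L", L)]), want,
                 tolerance = 1e-12)
  }
  # boundary pentamer: all three contexts truncate on the left
  pb <- pentamer_pu(seq, 3, m)
  for (L in c(10, 20, 30)) {
    hi <- min(50, 3 + 2 + L)
    want <- unpaired_probability(substr(seq, 1, hi), c(1, 5), m)
    expect_equal(unname(pb$pu_by_context[paste0("L", L)]), want,
                 tolerance = 1e-12)
  }
  expect_error(pentamer_pu(seq, 2, m), "inside")
})

test_that("positional profiles average per exon and pool linearly", {
  m <- fast_model()
# an all-A context (boundary validation off) has no pairable partners
  ctx_a <- spliced_context("a", strrep("A", 28), strrep("A", 12),
                           strrep("A", 12), validate_boundaries = FALSE)
  prof <- positional_pu_profile(list(ctx_a), "acceptor", m,
                                positions = signed_positions(-20, 5))
  expect_equal(unname(prof$mean_pu), rep(1, 25))

  set.seed(75)
  mk <- function(id) spliced_context(id, random_flank_ag(40),
                                     random_rna(20),
                                     paste0("GU", random_rna(30)))
  s1 <- lapply(1:3, function(i) mk(paste0("x", i)))
  s2 <- lapply(1:2, function(i) mk(paste0("y", i)))
  pos <- signed_positions(-15, 5)
  p1 <- positional_pu_profile(s1, "acceptor", m, positions = pos)
  p2 <- positional_pu_profile(s2, "acceptor", m, positions = pos)
  pall <- positional_pu_profile(c(s1, s2), "acceptor", m, positions = pos)
  pooled <- (3 * p1$mean_pu + 2 * p2$mean_pu) / 5
  expect_equal(pall$mean_pu, pooled, tolerance = 1e-12)
  expect_error(positional_pu_profile(list(), "acceptor", m), "empty")
})

test_that("mean_flank_pu reduces to the positional value for width-1 ranges", {
  m <- fast_model()
  set.seed(76)
  ctx <- spliced_context("w", random_flank_ag(60), random_rna(30),
                         paste0("GU", random_rna(38)))
  one <- mean_flank_pu(ctx, "acceptor", c(-12, -12), m)
  prof <- positional_pu_profile(list(ctx), "acceptor", m,
                                positions = -12L)
  expect_equal(one, unname(prof$mean_pu), tolerance = 1e-12)
  # poly-A stays 1 over the branch-point window
  pa <- spliced_context("pa", paste0(strrep("A", 58), "AG"),
                        strrep("A", 30), paste0("GU", strrep("A", 28)))
  expect_equal(mean_flank_pu(pa, "acceptor", c(-40, -18), m), 1)
  expect_error(mean_flank_pu(ctx, "acceptor", c(-300, -200), m), "range")
})
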