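.mk_ctx <- function(id, up, group = "other") {
  spliced_context(id, up, "GAAGAAGAAGAA", "GUCCCCCCCC", group = group)
}

test_that("positional composition counts, CIs and information content", {
  # 40 identical all-U columns upstream of the AG
  ctxs <- lapply(1:40, function(i)
    .mk_ctx(paste0("u", i), paste0(strrep("U", 30), "AG")))
  comp <- positional_composition(ctxs, "acceptor", range = c(-10, -3))
  expect_true(all(comp$freqs[, "U"] == 1))
  expect_equal(unname(comp$info_bits), rep(2, 8))
  expect_true(all(comp$ci_high[, "U"] >= comp$ci_low[, "U"]))
  expect_true(all(comp$counts[, "U"] == 40))

  # an exactly uniform column has zero information
  ups <- paste0(c("A", "C", "G", "U"), "UUUUAG")
  ctx4 <- lapply(seq_along(ups), function(i) .mk_ctx(paste0("m", i), ups[i]))
  comp4 <- positional_composition(ctx4, "acceptor", range = c(-7, -7))
  expect_equal(unname(comp4$info_bits), 0)
  expect_error(positional_composition(list(), "acceptor"), "empty")
})

test_that("enrichment windows flag planted positions only", {
  set.seed(91)
  mk_set <- function(n, u_positions = integer()) {
    lapply(seq_len(n), function(i) {
      up <- sample(c("A", "C", "G", "U"), 42, TRUE)
      for (p in u_positions)
        if (runif(1) < 0.6) up[42 + p + 1] <- "U"
      up[41:42] <- c("A", "G")
      .mk_ctx(paste0("s", i), paste(up, collapse = ""))
    })
  }
  bg <- mk_set(300)
  fg_same <- mk_set(300)
  cb <- positional_composition(bg, "acceptor", range = c(-40, -3))
  cs <- positional_composition(fg_same, "acceptor", range = c(-40, -3))
  none <- enrichment_window(cs, cb, "U")
  expect_length(none$significant, 0)
  expect_length(none$run, 0)

  fg_one <- mk_set(300, u_positions = -25)
  co <- positional_composition(fg_one, "acceptor", range = c(-40, -3))
  one <- enrichment_window(co, cb, "U")
  expect_identical(one$run, -25L)
  expect_true(all(one$significant == -25))
  expect_error(enrichment_window(co,
    positional_composition(bg, "acceptor", range = c(-30, -3)), "U"),
    "positions")
})

test_that("k-mer scans find planted motifs and cover the full k-mer space", {
  set.seed(92)
  mk <- function(n, plant = FALSE) {
    lapply(seq_len(n), function(i) {
      up <- sample(c("A", "C", "G"), 60, TRUE)   # U-free background
      if (plant && i <= 0.6 * n) up[20:26] <- c("U", "G", "U", "G", "U",
                                                "G", "U")
      up[59:60] <- c("A", "G")
      .mk_ctx(paste0("k", i), paste(up, collapse = ""))
    })
  }
  fg <- mk(50, plant = TRUE)
  bg <- mk(200)
  tab <- kmer_enrichment(fg, bg, k = 7, frame = "acceptor",
                         range = c(-58, -3))
  expect_equal(nrow(tab), 4^7)
  expect_equal(tab$kmer[1], "UGUGUGU")
  expect_lt(tab$q_value[1], 1e-6)

  same <- kmer_enrichment(fg, fg, k = 3, frame = "acceptor",
                          range = c(-58, -3))
  expect_gt(min(same$q_value), 0.99)
  expect_error(kmer_enrichment(fg, bg, k = 50, range = c(-40, -4)),
               "width")
})

test_that("Mann-Whitney U matches hand and enumeration results", {
  r <- mann_whitney_u(c(1, 2), c(3, 4), alternative = "less")
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 1 / 6)
  expect_equal(r$method, "exact")

  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(same$statistic), 4.5)   # n1 n2 / 2
  expect_equal(same$p_value, 1)

  set.seed(93)
  for (rep in 1:10) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- round(runif(n1), 6); y <- round(runif(n2), 6)
    got <- mann_whitney_u(x, y)
    expect_equal(got$p_value, wmw_enum_p(x, y), tolerance = 1e-12)
    expect_equal(mann_whitney_u(x, y, "greater")$p_value,
                 wmw_enum_p(x, y, "greater"), tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(), 1:3), "empty")
})

test_that("correlation matches a hand-computed covariance ratio", {
  x <- c(1, 2, 4, 5, 9)
  y <- c(2, 1, 5, 4, 8)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- correlation(x, y)
  expect_equal(unname(r$statistic), hand, tolerance = 1e-12)
  expect_equal(unname(correlation(x, x)$statistic), 1)
  expect_equal(unname(correlation(x, -x)$statistic), -1)
  expect_lt(correlation(x, x)$p_value, 1e-3)
  expect_error(correlation(rep(1, 5), x), "constant")
  sp <- correlation(x, y, method = "spearman")
  expect_equal(unname(sp$statistic), cor(x, y, method = "spearman"))
})

test_that("chi-squared handles hand-computed and degenerate tables", {
  r <- chi_square_contingency(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
  expect_equal(unname(r$statistic), 20 / 3, tolerance = 1e-12)
  expect_equal(r$df, 1)

  prop <- chi_square_contingency(matrix(c(10, 20, 20, 40), 2,
                                        byrow = TRUE))
  expect_equal(unname(prop$statistic), 0)
  expect_equal(prop$p_value, 1)

  r32 <- chi_square_contingency(matrix(c(5, 10, 9, 4, 7, 12), 3, 2))
  expect_equal(r32$df, 2)
  expect_error(chi_square_contingency(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("BH adjustment is step-up with order preservation", {
  expect_equal(bh_fdr(0.02), 0.02)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.04, 0.001, 0.9, 0.02)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_lte(max(q), 1)
  expect_equal(order(q), order(p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("chi-squared and Fisher agree in direction on 2x2 tables", {
  set.seed(94)
  for (rep in 1:20) {
    tab <- matrix(rpois(4, 30) + 5, 2)
    pc <- chi_square_contingency(tab)$p_value
    pf <- fisher.test(tab)$p.value
    expect_true((pc < 0.05) == (pf < 0.05) || abs(pc - pf) < 0.05)
  }
})
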