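.ctx_up <- function(up) {
  spliced_context("t", up, "GAAGAAGAAGAA", "GUCCCCCCCC")
}

test_that("AGEZ length matches hand-derived cases", {
  r <- agez_length(.ctx_up("UAGCUUUUUUUUUUUCAG"))
  expect_equal(r$agez_len, 13)
  expect_equal(r$upstream_ag_pos, -16)
  expect_false(r$censored)

  r2 <- agez_length(.ctx_up("GACUAACUUUUUUUUUUCAG"))
  expect_true(r2$censored)
  expect_equal(r2$agez_len, 18)      # flank_len - 2
  expect_true(is.na(r2$upstream_ag_pos))

  r3 <- agez_length(.ctx_up("AGAG"))
  expect_equal(r3$agez_len, 0)       # adjacent AG

  expect_error(agez_length(.ctx_up("CAG")), "shorter")
})

test_that("AGEZ scanner agrees with a naive substring oracle", {
  set.seed(31)
  naive_agez <- function(up) {
    L <- nchar(up)
    hits <- gregexpr("AG", up, fixed = TRUE)[[1]]
    hits <- hits[hits > 0]
    g_pos <- hits + 1L                       # index of the G
    g_pos <- g_pos[g_pos <= L - 2L]          # signed <= -3
    if (!length(g_pos)) list(len = L - 2L, cens = TRUE)
    else list(len = L - 2L - max(g_pos), cens = FALSE)
  }
  for (i in 1:500) {
    up <- random_flank_ag(sample(10:120, 1))
    got <- agez_length(.ctx_up(up))
    want <- naive_agez(up)
    expect_equal(got$agez_len, want$len)
    expect_equal(got$censored, want$cens)
  }
})

test_that("PPT metrics count composition and runs by hand", {
  ctx <- .ctx_up(paste0(strrep("A", 10), strrep("U", 20), "CAG"))
  m <- ppt_metrics(ctx, window = c(-23, -4))
  expect_equal(m$frac_U, 1.0)
  expect_equal(m$longest_U_run, 20)

  ctx2 <- .ctx_up(paste0(strrep("A", 10), "UCUCUCUCUC", "CAG"))
  m2 <- ppt_metrics(ctx2, window = c(-13, -4))
  expect_equal(m2$frac_pyrimidine, 1.0)
  expect_equal(m2$frac_U, 0.5)
  expect_equal(m2$longest_U_run, 1)
  expect_equal(m2$frac_C_among_nonU, 1.0)

  # split windows expose G-rich distal vs C-rich proximal backgrounds
  ctx3 <- .ctx_up(paste0("UGUGUGUGUG", "UCUCUCUCUC", "CAG"))
  sp <- ppt_metrics(ctx3, window = c(-23, -4), split_at = -14)
  expect_gt(sp$distal$frac_G_among_nonU, sp$distal$frac_C_among_nonU)
  expect_gt(sp$proximal$frac_C_among_nonU, sp$proximal$frac_G_among_nonU)
  expect_error(ppt_metrics(ctx3, window = c(4, 10)), "window")
})

test_that("PWM log-odds match closed forms and a hand recomputation", {
  uni <- pwm(matrix(0.25, 5, 4))
  expect_equal(pwm_log_odds("ACGUA", uni), 0)

  hard <- pwm(diag(4)[c(2, 4, 3, 1, 2), ])   # C U G A C with p = 1
  expect_equal(pwm_log_odds("CUGAC", hard), 5 * log2(4))

  set.seed(13)
  pr <- matrix(rgamma(28, 1), 7, 4)
  pr <- pr / rowSums(pr)
  p <- pwm(pr)
  s <- random_rna(7)
  hand <- sum(vapply(1:7, function(i) {
    l <- substr(s, i, i)
    log2(pr[i, match(l, c("A", "C", "G", "U"))] / 0.25)
  }, numeric(1)))
  expect_equal(pwm_log_odds(s, p), hand, tolerance = 1e-12)

  expect_error(pwm_log_odds("ACGU", p), "width")
  expect_error(pwm(matrix(0.3, 2, 4)), "sum to 1")
})

test_that("branch-point scanning is exhaustive, sorted, and tie-broken", {
  # uniform PWM: every A-anchored window scores 0; best = most proximal A
  uni <- pwm(matrix(0.25, 7, 4), branch_offset = 6L)
  up <- paste0(strrep("C", 60), "UACUAAC", strrep("C", 20), "UUUCAG")
  ctx <- .ctx_up(up)
  res <- score_bp_candidates(ctx, uni)
  expect_false(res$no_candidates)
  expect_true(all(res$candidates$score == 0))
  expect_equal(res$best$branch_a_pos,
               max(res$candidates$branch_a_pos))   # proximal tie-break

  # consensus PWM finds the planted heptamer (branch A 28 nt upstream)
  res2 <- score_bp_candidates(ctx, default_bp_pwm())
  expect_equal(res2$best$branch_a_pos, -28)
  expect_equal(res2$best$distance, 28)
  # exhaustive: one candidate per A in the search range with a full window
  n_a <- sum(strsplit(up, "")[[1]] == "A"[1])
  expect_true(nrow(res2$candidates) <= n_a)
  expect_equal(res2$candidates$score, sort(res2$candidates$score,
                                           decreasing = TRUE))

  # no A in the search window -> empty with warning flag
  ctx3 <- .ctx_up(paste0(strrep("C", 40), "AG"))
  res3 <- score_bp_candidates(ctx3, default_bp_pwm())
  expect_true(res3$no_candidates)
  expect_equal(nrow(res3$candidates), 0)
})

test_that("splice-site strength is deterministic PWM scoring", {
  ctx <- toy_context()
  uni_a <- pwm(matrix(0.25, 23, 4)); attr(uni_a, "span") <- c(20L, 3L)
  uni_d <- pwm(matrix(0.25, 9, 4)); attr(uni_d, "span") <- c(6L, 3L)
  s <- splice_site_strength(ctx, uni_a, uni_d)
  expect_equal(unname(s), c(0, 0))
  expect_identical(s, splice_site_strength(ctx, uni_a, uni_d))
})

test_that("PWMs estimated from contexts score the consensus highest", {
  set.seed(41)
  ctxs <- lapply(1:60, function(i)
    spliced_context(paste0("c", i), random_flank_ag(40), random_rna(30),
                    paste0("GU", random_rna(28)), group = "control"))
  pw <- splice_site_pwms(ctxs)
  scores <- vapply(ctxs, function(ctx)
    splice_site_strength(ctx, pw$acceptor, pw$donor)["acceptor_score"],
    numeric(1))
  # the AG columns are invariant, so every real acceptor outscores a
  # random window on those columns; scores must be finite and consistent
  expect_true(all(is.finite(scores)))
  # scoring the (near-)consensus sequence beats the average context
  cons <- paste(c("A", "C", "G", "U")[apply(pw$acceptor$probs, 1,
                                            which.max)], collapse = "")
  expect_gte(pwm_log_odds(cons, pw$acceptor), max(scores))
})
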