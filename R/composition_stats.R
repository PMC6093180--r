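#' Positional nucleotide composition with Bayesian confidence intervals
#'
#' Tallies A/C/G/U counts per signed position over a context set (N
#' excluded from counts and tracked separately), with per-letter 95%
#' credible intervals from the Beta marginal of a Jeffreys-style
#' symmetric Dirichlet posterior, `Beta(c + 1/2, n - c + 1/2)`, and
#' per-position information content `2 - H` in bits against an
#' equiprobable background.
#'
#' @param contexts list of `SplicedContext`.
#' @param frame `"acceptor"` or `"donor"`.
#' @param range signed length-2 interval (default -100..-1 for the
#'   acceptor frame, +1..+100 for the donor frame).
#' @param level credible level (default 0.95).
#' @return object of class `PositionalComposition`: list with
#'   `positions`, `counts` (position x letter), `n` (per position,
#'   excluding N), `n_N`, `freqs`, `ci_low`, `ci_high`, `info_bits`.
#' @export
positional_composition <- function(contexts, frame = c("acceptor", "donor"),
                                   range = NULL, level = 0.95) {
  frame <- match.arg(frame)
  if (!length(contexts)) stop("empty context set")
  if (is.null(range)) range <- if (frame == "acceptor") c(-100, -1)
                               else c(1, 100)
  positions <- signed_positions(range[1], range[2])
  if (!length(positions)) stop("empty range")
  np <- length(positions)
  counts <- matrix(0L, np, 4, dimnames = list(positions, RNA_LETTERS))
  n_N <- setNames(integer(np), positions)
  for (ctx in contexts) {
    ch <- .split_chars(.context_seq(ctx))
    idx <- .signed_to_index(ctx, frame, positions)
    ok <- !is.na(idx)
    if (!any(ok)) next
    lt <- ch[idx[ok]]
    isn <- lt == "N"
    n_N[which(ok)[isn]] <- n_N[which(ok)[isn]] + 1L
    use <- which(ok)[!isn]
    li <- match(lt[!isn], RNA_LETTERS)
    for (j in seq_along(use))
      counts[use[j], li[j]] <- counts[use[j], li[j]] + 1L
  }
  n <- rowSums(counts)
  freqs <- counts / ifelse(n > 0, n, 1)
  alpha <- (1 - level) / 2
  ci_low <- qbeta(alpha, counts + 0.5, n - counts + 0.5)
  ci_high <- qbeta(1 - alpha, counts + 0.5, n - counts + 0.5)
  dim(ci_low) <- dim(ci_high) <- dim(counts)
  dimnames(ci_low) <- dimnames(ci_high) <- dimnames(counts)
  h <- apply(freqs, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  info_bits <- ifelse(n > 0, 2 - h, NA_real_)
  structure(list(frame = frame, positions = positions, counts = counts,
                 n = n, n_N = n_N, freqs = freqs, ci_low = ci_low,
                 ci_high = ci_high,
                 info_bits = setNames(info_bits, positions)),
            class = "PositionalComposition")
}

#' Positions where one letter is enriched in a foreground set
#'
#' Per-position two-proportion comparison of one letter between matched
#' foreground and background compositions (Fisher's exact test when any
#' expected cell count is below 5, otherwise the normal two-proportion
#' test without continuity correction), Benjamini-Hochberg adjusted
#' across positions.  Reports the significant positions (q < `q_cut`)
#' and the longest contiguous significant run.
#'
#' @param fg,bg [positional_composition()]s over identical frames and
#'   positions.
#' @param letter one of A, C, G, U.
#' @param q_cut BH-adjusted significance cutoff (default 0.05).
#' @return list with `positions`, `p_values`, `q_values`,
#'   `significant` (signed positions with q < q_cut), `run` (signed
#'   positions of the longest contiguous significant run) and `window`
#'   (the span from the first to the last significant position - the
#'   detected enrichment region; planted or biological enrichment of
#'   alternating strength is significant at alternating positions, so
#'   the region extent, not the significant set, is the window
#'   estimate).  `run` and `window` are empty when nothing is
#'   significant.
#' @export
enrichment_window <- function(fg, bg, letter = "U", q_cut = 0.05) {
  if (!identical(fg$frame, bg$frame) ||
      !identical(fg$positions, bg$positions))
    stop("fg and bg must share frame and positions")
  letter <- match.arg(letter, RNA_LETTERS)
  p <- vapply(seq_along(fg$positions), function(i) {
    x1 <- fg$counts[i, letter]; n1 <- fg$n[i]
    x2 <- bg$counts[i, letter]; n2 <- bg$n[i]
    if (n1 == 0 || n2 == 0) return(NA_real_)
    tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), 2, byrow = TRUE)
    expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expct < 5)) {
      fisher.test(tab)$p.value
    } else {
      suppressWarnings(
        prop.test(c(x1, x2), c(n1, n2), correct = FALSE)$p.value)
    }
  }, numeric(1))
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- bh_fdr(p[!is.na(p)])
  sig <- !is.na(q) & q < q_cut
  run <- integer(); window <- integer()
  if (any(sig)) {
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    k <- which(r$values)
    best <- k[which.max(r$lengths[k])]
    run <- fg$positions[(ends[best] - r$lengths[best] + 1L):ends[best]]
    sp <- range(fg$positions[sig])
    window <- signed_positions(sp[1], sp[2])
  }
  list(positions = fg$positions, p_values = p, q_values = q,
       significant = fg$positions[sig], run = run, window = window)
}

.window_string <- function(context, frame, range) {
  positions <- signed_positions(range[1], range[2])
  idx <- .signed_to_index(context, frame, positions)
  idx <- idx[!is.na(idx)]
  paste(.split_chars(.context_seq(context))[idx], collapse = "")
}

#' k-mer enrichment between context sets
#'
#' Per-sequence presence/absence counts of every k-mer over `4^k`
#' possibilities within a signed window, compared between foreground and
#' background by Fisher's exact test with BH correction across all
#' k-mers.  Presence/absence (rather than occurrence) counting avoids
#' sequence-length bias; `occurrences = TRUE` switches to total
#' occurrence counts (Fisher on occurrence sums against the total
#' number of scanned windows).
#'
#' @param fg,bg lists of `SplicedContext`.
#' @param k k-mer size.
#' @param frame,range window to scan (see [positional_composition()]);
#'   default acceptor -100..-4.
#' @param occurrences count total occurrences instead of per-sequence
#'   presence.
#' @return data.frame (kmer, fg_count, bg_count, fg_n, bg_n, p_value,
#'   q_value, log2_enrichment), sorted by p then kmer; one row per
#'   possible k-mer.
#' @export
kmer_enrichment <- function(fg, bg, k = 5L, frame = "acceptor",
                            range = c(-100, -4), occurrences = FALSE) {
  frame <- .match_arg_frame(frame)
  width <- length(signed_positions(range[1], range[2]))
  if (k > width) stop("k exceeds the window width")
  if (k > 12) stop("k > 12 is not supported (4^k k-mers would be tested)")
  all_kmers <- .all_kmers(k)
  count_set <- function(ctxs) {
    tot <- setNames(integer(length(all_kmers)), all_kmers)
    for (ctx in ctxs) {
      s <- .window_string(ctx, frame, range)
      if (nchar(s) < k) next
      km <- substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
      km <- km[!grepl("N", km, fixed = TRUE)]
      if (!occurrences) km <- unique(km)
      t1 <- table(km)
      tot[names(t1)] <- tot[names(t1)] + as.integer(t1)
    }
    tot
  }
  fgc <- count_set(fg); bgc <- count_set(bg)
  fg_n <- length(fg); bg_n <- length(bg)
  denom_fg <- if (occurrences) sum(fgc) else fg_n
  denom_bg <- if (occurrences) sum(bgc) else bg_n
  p <- vapply(seq_along(all_kmers), function(i) {
    a <- fgc[i]; b <- bgc[i]
    if (a == 0 && b == 0) return(1)
    fisher.test(matrix(c(a, denom_fg - a, b, denom_bg - b), 2,
                       byrow = TRUE))$p.value
  }, numeric(1))
  q <- bh_fdr(p)
  l2 <- log2(((fgc + 0.5) / (denom_fg + 1)) / ((bgc + 0.5) / (denom_bg + 1)))
  out <- data.frame(kmer = all_kmers, fg_count = as.integer(fgc),
                    bg_count = as.integer(bgc), fg_n = fg_n, bg_n = bg_n,
                    p_value = p, q_value = q, log2_enrichment = l2,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.all_kmers <- function(k) {
  if (k == 1) return(RNA_LETTERS)
  grid <- do.call(expand.grid,
                  c(rep(list(RNA_LETTERS), k), stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; build lexicographic order
  km <- do.call(paste0, rev(grid))
  sort(km)
}

#' Wilcoxon-Mann-Whitney rank-sum comparison
#'
#' U statistic with mid-rank ties; the p-value is exact by enumeration
#' when `n1 * n2 <= 400` and there are no ties, otherwise a
#' tie-corrected normal approximation with continuity correction.  The
#' method actually used is tagged in the result.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   referring to x relative to y.
#' @return object of class `GroupComparison`: list with `statistic`
#'   (U), `p_value`, `medians`, `means`, `n1`, `n2`, `method`.
#' @export
mann_whitney_u <- function(x, y, alternative = c("two.sided", "less",
                                                 "greater")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("empty sample")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- (n1 * n2 <= 400) && !has_ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE))
  structure(list(statistic = c(U = U), p_value = wt$p.value,
                 means = c(mean(x), mean(y)),
                 medians = c(median(x), median(y)),
                 n1 = n1, n2 = n2,
                 method = if (exact) "exact" else "normal-approx",
                 alternative = alternative),
            class = "GroupComparison")
}

#' Correlation with significance test
#'
#' Pearson or Spearman correlation with its two-sided p-value (Student t
#' for Pearson; exact/normal per sample size for Spearman).  Constant
#' input is an explicit error, never a silent NaN.
#'
#' @param x,y equal-length numeric vectors (n >= 3 after removing
#'   incomplete pairs).
#' @param method `"pearson"` or `"spearman"`.
#' @return a `GroupComparison` with `statistic` = r.
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("correlation undefined for constant input")
  ct <- suppressWarnings(cor.test(x, y, method = method))
  structure(list(statistic = c(r = unname(ct$estimate)),
                 p_value = ct$p.value, n1 = length(x), n2 = length(y),
                 means = c(mean(x), mean(y)),
                 medians = c(median(x), median(y)),
                 method = method),
            class = "GroupComparison")
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson chi-squared without continuity correction by default (set
#' `yates = TRUE` for the corrected 2x2 variant); df = (r-1)(c-1).
#'
#' @param table r x c matrix of counts; all margins must be positive.
#' @param yates apply Yates continuity correction (2x2 only).
#' @return a `GroupComparison` with `statistic` = chi-squared and a
#'   `df` field.
#' @export
chi_square_contingency <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all table margins must be positive")
  ct <- suppressWarnings(chisq.test(table, correct = yates))
  structure(list(statistic = c(chi_squared = unname(ct$statistic)),
                 df = unname(ct$parameter), p_value = ct$p.value,
                 n1 = sum(table), n2 = NA_integer_,
                 means = NULL, medians = NULL,
                 method = "chi2"),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("GroupComparison [%s]: statistic %s = %.6g, p = %.4g\n",
              x$method, names(x$statistic)[1], x$statistic[1], x$p_value))
  invisible(x)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH with monotonicity enforcement; input order preserved.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return q-values in the same order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
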