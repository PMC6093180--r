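#' AG-exclusion-zone length of a spliced context
#'
#' Scans the upstream intron flank from the 3'ss towards the branch
#' point region for the nearest upstream AG dinucleotide (G at position
#' p <= -3).  The AGEZ length is the number of nucleotides strictly
#' between that G and the A of the 3'ss AG (positions p+1 .. -3).  If
#' no upstream AG lies within the flank the value is censored at
#' `flank_len - 2`.
#'
#' @param context a `SplicedContext` (upstream flank must end in AG and
#'   be at least 4 nt long).
#' @return object of class `AGEZResult`: list with `agez_len`,
#'   `upstream_ag_pos` (signed position of the G, `NA` when censored)
#'   and `censored`.
#' @export
agez_length <- function(context) {
  up <- .upstream_chars(context)
  L <- length(up)
  if (L < 4) stop("upstream flank shorter than 4 nt")
  if (paste(up[L - 1], up[L], sep = "") != "AG")
    stop("upstream flank must end in AG")
  # G candidates at index k (signed p = k - L - 1), p <= -3 => k <= L - 2
  g_at <- which(up[-1] == "G" & up[-L] == "A") + 1L  # index of the G
  g_at <- g_at[g_at <= L - 2L]
  if (!length(g_at)) {
    return(structure(list(agez_len = L - 2L, upstream_ag_pos = NA_integer_,
                          censored = TRUE), class = "AGEZResult"))
  }
  k <- max(g_at)
  structure(list(agez_len = L - 2L - k, upstream_ag_pos = k - L - 1L,
                 censored = FALSE), class = "AGEZResult")
}

#' Polypyrimidine-tract composition metrics
#'
#' Base-composition summaries of an upstream intron window: U and
#' pyrimidine fractions, the G and C fractions among non-U bases (these
#' expose the guanine-rich 5' versus cytosine-rich 3' backgrounds of
#' bipartite tracts), and the longest U and pyrimidine runs.  With
#' `split_at`, metrics are returned separately for the 3'ss-proximal
#' and 5'-distal subwindows.
#'
#' @param context a `SplicedContext`.
#' @param window signed acceptor-frame interval (default -100..-4).
#' @param split_at optional signed position; the proximal subwindow runs
#'   from `split_at` (exclusive) towards the 3'ss, the distal one from
#'   the window's far end up to `split_at` (inclusive).
#' @return object of class `PPTMetrics` (or a list with elements
#'   `proximal` and `distal` when split).
#' @export
ppt_metrics <- function(context, window = c(-100, -4), split_at = NULL) {
  if (!is.null(split_at)) {
    w <- sort(window)
    prox <- ppt_metrics(context, window = c(split_at + 1L, w[2]))
    dist <- ppt_metrics(context, window = c(w[1], split_at))
    return(list(proximal = prox, distal = dist))
  }
  positions <- signed_positions(window[1], window[2])
  positions <- positions[positions < 0]
  if (!length(positions)) stop("empty window")
  idx <- .signed_to_index(context, "acceptor", positions)
  idx <- idx[!is.na(idx) & idx <= nchar(context$upstream)]
  if (!length(idx)) stop("window outside the upstream flank")
  ch <- .split_chars(context$upstream)[idx]
  ch <- ch[ch != "N"]
  if (!length(ch)) stop("window contains only N")
  n <- length(ch)
  is_u <- ch == "U"; is_py <- ch %in% c("U", "C")
  non_u <- sum(!is_u)
  run_len <- function(flag) if (any(flag)) max(rle(flag)$lengths[rle(flag)$values]) else 0L
  structure(list(
    window = sort(window),
    n = n,
    frac_U = mean(is_u),
    frac_pyrimidine = mean(is_py),
    frac_G_among_nonU = if (non_u) sum(ch == "G") / non_u else NA_real_,
    frac_C_among_nonU = if (non_u) sum(ch == "C") / non_u else NA_real_,
    longest_U_run = run_len(is_u),
    longest_pyrimidine_run = run_len(is_py)),
    class = "PPTMetrics")
}

#' Position weight matrix
#'
#' A probability PWM with log-odds scoring in bits against a background
#' distribution (equiprobable by default).  An optional branch-A offset
#' designates which motif column must be the branch adenine when the
#' PWM is used for branch-point scoring.
#'
#' @param probs width x 4 matrix of letter probabilities (columns
#'   A, C, G, U); each row must sum to 1.
#' @param background length-4 background distribution.
#' @param branch_offset 1-based motif column of the branch adenine, or
#'   `NULL`.
#' @return object of class `PWM` with the log-odds matrix in bits.
#' @export
pwm <- function(probs, background = rep(0.25, 4), branch_offset = NULL) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4) stop("probs must have 4 columns (A, C, G, U)")
  if (nrow(probs) < 1) stop("PWM width must be >= 1")
  if (any(abs(rowSums(probs) - 1) > 1e-8))
    stop("each PWM row must sum to 1")
  if (any(probs < 0)) stop("probabilities must be non-negative")
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-8)
    stop("background must be a length-4 distribution")
  colnames(probs) <- RNA_LETTERS
  log_odds <- log2(sweep(probs, 2, background, "/"))
  if (!is.null(branch_offset) &&
      (branch_offset < 1 || branch_offset > nrow(probs)))
    stop("branch_offset outside PWM width")
  structure(list(width = nrow(probs), probs = probs, log_odds = log_odds,
                 background = background, branch_offset = branch_offset),
            class = "PWM")
}

#' Estimate a PWM from aligned sequences
#'
#' Columnwise letter frequencies with a pseudocount, e.g. for building
#' splice-site PWMs from a control set.
#'
#' @param seqs character vector of equal-length RNA strings.
#' @param pseudocount added per letter per column.
#' @param ... passed to [pwm()].
#' @return a [pwm()].
#' @export
estimate_pwm <- function(seqs, pseudocount = 0.5, ...) {
  if (!length(seqs)) stop("no sequences")
  w <- unique(nchar(seqs))
  if (length(w) != 1) stop("sequences must have equal length")
  mat <- matrix(pseudocount, w, 4, dimnames = list(NULL, RNA_LETTERS))
  for (s in seqs) {
    ch <- .split_chars(.to_rna(s))
    for (i in seq_len(w)) if (ch[i] %in% RNA_LETTERS)
      mat[i, ch[i]] <- mat[i, ch[i]] + 1
  }
  pwm(mat / rowSums(mat), ...)
}

#' Log-odds score of a sequence under a PWM
#'
#' `sum over positions of log2(p_letter / background_letter)`, in bits.
#'
#' @param seq RNA string of length `pwm$width`, no N.
#' @param pwm a [pwm()].
#' @return numeric score in bits.
#' @export
pwm_log_odds <- function(seq, pwm) {
  ch <- .split_chars(.to_rna(seq))
  if (length(ch) != pwm$width)
    stop("sequence length ", length(ch), " does not match PWM width ",
         pwm$width)
  if (any(!ch %in% RNA_LETTERS))
    stop("sequence contains non-ACGU letters")
  sum(pwm$log_odds[cbind(seq_along(ch), match(ch, RNA_LETTERS))])
}

#' Default branch-point PWM
#'
#' A heptamer branch-point matrix around the consensus UACUAAC with the
#' branch adenine at column 6, smoothed so that non-consensus letters
#' retain small probability.  It mirrors the planting distribution of
#' the synthetic generator and is a placeholder for published
#' branch-point models, which users can supply as any [pwm()] with a
#' `branch_offset`.
#'
#' @param consensus_prob probability mass on the consensus letter.
#' @return a [pwm()] with `branch_offset = 6`.
#' @export
default_bp_pwm <- function(consensus_prob = 0.91) {
  consensus <- c("U", "A", "C", "U", "A", "A", "C")
  off <- (1 - consensus_prob) / 3
  probs <- matrix(off, 7, 4, dimnames = list(NULL, RNA_LETTERS))
  for (i in seq_along(consensus)) probs[i, consensus[i]] <- consensus_prob
  pwm(probs, branch_offset = 6L)
}

#' Score branch-point candidates in an upstream flank
#'
#' Scores every window of the upstream intron whose branch-A column is
#' an adenine, over a signed search interval (default -9 down to
#' -min(100, flank length), covering the AGEZ span extended to at least
#' -100).  Candidates are sorted by score descending; ties are broken in
#' favour of the 3'ss-proximal adenine, the deterministic convention
#' under which proximal branch points dominate control exons.
#'
#' @param context a `SplicedContext`.
#' @param pwm a [pwm()] with a `branch_offset`; see [default_bp_pwm()].
#' @param search signed length-2 interval for the branch A position, or
#'   `"default"`.
#' @return object of class `BPCandidateSet`: list with `candidates`
#'   (data.frame branch_a_pos, motif_start, score, distance), `best`
#'   (first row or `NULL`) and `no_candidates` flag.  When no adenine is
#'   available in the search window the candidate list is empty and a
#'   warning flag is set.
#' @export
score_bp_candidates <- function(context, pwm = default_bp_pwm(),
                                search = "default") {
  if (is.null(pwm$branch_offset))
    stop("PWM must designate a branch-A offset")
  L <- nchar(context$upstream)
  if (identical(search, "default")) search <- c(-9, -min(100L, L))
  search <- sort(as.integer(search))
  up <- .upstream_chars(context)
  w <- pwm$width; off <- pwm$branch_offset
  rows <- list()
  for (p in seq(search[2], search[1])) {   # proximal to distal
    if (p > -3) next
    k <- L + p + 1L                         # index of candidate branch A
    if (k < 1 || k > L) next
    if (up[k] != "A") next
    s_idx <- k - off + 1L; e_idx <- k + (w - off)
    if (s_idx < 1 || e_idx > L) next
    win <- paste(up[s_idx:e_idx], collapse = "")
    if (grepl("N", win, fixed = TRUE)) next
    rows[[length(rows) + 1L]] <- data.frame(
      branch_a_pos = p, motif_start = s_idx - L - 1L,
      score = pwm_log_odds(win, pwm), distance = abs(p))
  }
  if (!length(rows)) {
    return(structure(list(candidates = data.frame(
      branch_a_pos = integer(), motif_start = integer(),
      score = numeric(), distance = integer()),
      best = NULL, no_candidates = TRUE), class = "BPCandidateSet"))
  }
  cand <- do.call(rbind, rows)
  cand <- cand[order(-cand$score, cand$distance), , drop = FALSE]
  rownames(cand) <- NULL
  structure(list(candidates = cand, best = cand[1, , drop = FALSE],
                 no_candidates = FALSE),
            class = "BPCandidateSet")
}

#' Intrinsic splice-site strength by PWM log-odds
#'
#' Scores the windows straddling the 3'ss AG and the 5'ss GU/GC with
#' acceptor and donor PWMs.  Each PWM carries a `span` attribute
#' `c(intronic, exonic)` giving how many intronic and exonic bases its
#' window covers (set by [splice_site_pwms()] or manually via
#' `attr(p, "span")`).
#'
#' @param context a `SplicedContext`.
#' @param acceptor_pwm,donor_pwm [pwm()]s with `span` attributes.
#' @return named numeric `c(acceptor_score, donor_score)` in bits.
#' @export
splice_site_strength <- function(context, acceptor_pwm, donor_pwm) {
  sa <- attr(acceptor_pwm, "span"); sd_ <- attr(donor_pwm, "span")
  if (is.null(sa) || is.null(sd_))
    stop("splice-site PWMs must carry a span attribute c(intronic, exonic)")
  acc_win <- .ss_window(context, "acceptor", sa)
  don_win <- .ss_window(context, "donor", sd_)
  c(acceptor_score = pwm_log_odds(acc_win, acceptor_pwm),
    donor_score = pwm_log_odds(don_win, donor_pwm))
}

# extract the window of `span = c(intronic, exonic)` bases straddling a
# splice site, 5'->3'
.ss_window <- function(context, frame, span) {
  pos <- if (frame == "acceptor") {
    c(seq(-span[1], -1), seq(1, span[2]))
  } else {
    c(seq(-span[2], -1), seq(1, span[1]))
  }
  idx <- .signed_to_index(context, frame, pos)
  if (anyNA(idx)) stop("context too short for the splice-site PWM span")
  paste(.split_chars(.context_seq(context))[idx], collapse = "")
}

#' Estimate acceptor and donor splice-site PWMs from contexts
#'
#' Builds PWMs over windows straddling the splice sites (acceptor:
#' `acceptor_span[1]` intronic + `acceptor_span[2]` exonic bases; donor
#' analogous), typically from a control set.
#'
#' @param contexts list of `SplicedContext`.
#' @param acceptor_span,donor_span `c(intronic, exonic)` window sizes.
#' @param pseudocount see [estimate_pwm()].
#' @return list with elements `acceptor` and `donor` ([pwm()]s with
#'   `span` attributes).
#' @export
splice_site_pwms <- function(contexts, acceptor_span = c(20L, 3L),
                             donor_span = c(6L, 3L), pseudocount = 0.5) {
  acc <- vapply(contexts, .ss_window, "", frame = "acceptor",
                span = acceptor_span)
  don <- vapply(contexts, .ss_window, "", frame = "donor",
                span = donor_span)
  a <- estimate_pwm(acc, pseudocount = pseudocount)
  d <- estimate_pwm(don, pseudocount = pseudocount)
  attr(a, "span") <- acceptor_span
  attr(d, "span") <- donor_span
  list(acceptor = a, donor = d)
}
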