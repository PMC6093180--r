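# Independent oracles used across the suite.  These deliberately share
# no code with the package internals: structures are enumerated by
# brute force, shuffles by exhaustive rearrangement search, and rank
# statistics by full permutation enumeration.

# size-safe single draw (sample(x, 1) misbehaves for length-1 x)
sample1 <- function(v) v[sample.int(length(v), 1)]

random_rna <- function(n, letters = c("A", "C", "G", "U")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# --- secondary-structure enumeration --------------------------------------

.orc_pairable <- function(a, b)
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")

# all nested pair sets over the index vector `avail` (sorted ascending)
enum_structures <- function(chars, avail = seq_along(chars), minloop = 3) {
  if (length(avail) < 2) return(list(matrix(numeric(0), 0, 2)))
  i <- avail[1]
  out <- enum_structures(chars, avail[-1], minloop)
  for (j in avail[-1]) {
    if (j - i - 1 < minloop) next
    if (!.orc_pairable(chars[i], chars[j])) next
    inner <- avail[avail > i & avail < j]
    outer <- avail[avail > j]
    for (si in enum_structures(chars, inner, minloop))
      for (so in enum_structures(chars, outer, minloop))
        out[[length(out) + 1L]] <- rbind(c(i, j), si, so)
  }
  out
}

.orc_energy <- function(pairs, chars, pe, sb) {
  if (!nrow(pairs)) return(0)
  key <- paste0(chars[pairs[, 1]], chars[pairs[, 2]])
  e <- sum(pe[key])
  pset <- paste(pairs[, 1], pairs[, 2])
  for (r in seq_len(nrow(pairs)))
    if (paste(pairs[r, 1] + 1, pairs[r, 2] - 1) %in% pset)
      e <- e + sb[key[r]]
  e
}

# Z, pair probabilities, unpaired probabilities and span-PU by
# exhaustive enumeration
oracle_partition <- function(seq, model) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pe <- model$pair_energies
  sb <- model$stack_bonus
  names(sb) <- names(pe)
  ss <- enum_structures(chars, minloop = model$min_hairpin_loop)
  w <- vapply(ss, function(p)
    exp(-.orc_energy(p, chars, pe, sb) / model$kT), numeric(1))
  Z <- sum(w)
  n <- length(chars)
  bpp <- matrix(0, n, n)
  for (k in seq_along(ss)) {
    p <- ss[[k]]
    if (nrow(p)) for (r in seq_len(nrow(p)))
      bpp[p[r, 1], p[r, 2]] <- bpp[p[r, 1], p[r, 2]] + w[k]
  }
  bpp <- (bpp + t(bpp)) / Z
  pu_span <- function(i, j) {
    keep <- vapply(ss, function(p) {
      !nrow(p) || !any((p[, 1] >= i & p[, 1] <= j) |
                       (p[, 2] >= i & p[, 2] <= j))
    }, logical(1))
    sum(w[keep]) / Z
  }
  list(Z = Z, bpp = bpp, unpaired = 1 - rowSums(bpp), pu_span = pu_span)
}

# --- dinucleotide-shuffle enumeration -------------------------------------

# every distinct string with the same dinucleotide multiset and the same
# endpoints as `seq` (exhaustive walk over the dinucleotide multigraph)
enum_dinuc_strings <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  edges <- table(paste0(chars[-n], chars[-1]))
  out <- new.env(parent = emptyenv())
  walk <- function(cur, remaining, acc) {
    if (sum(unlist(remaining)) == 0) {
      assign(acc, TRUE, envir = out)
      return(invisible())
    }
    for (e in names(remaining)) {
      if (remaining[[e]] == 0 || substr(e, 1, 1) != cur) next
      r2 <- remaining
      r2[[e]] <- r2[[e]] - 1L
      walk(substr(e, 2, 2), r2, paste0(acc, substr(e, 2, 2)))
    }
  }
  rem <- as.list(edges)
  walk(chars[1], rem, chars[1])
  ls(out)
}

dinuc_counts <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  table(factor(paste0(chars[-n], chars[-1]),
               levels = as.vector(outer(c("A", "C", "G", "U"),
                                        c("A", "C", "G", "U"), paste0))))
}

# --- exact Wilcoxon-Mann-Whitney by enumeration ---------------------------

wmw_enum_p <- function(x, y, alternative = "two.sided") {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  idx <- utils::combn(n1 + n2, n1)
  ustat <- function(sel) {
    r <- rank(pooled)
    sum(r[sel]) - n1 * (n1 + 1) / 2
  }
  obs <- ustat(seq_len(n1))
  us <- apply(idx, 2, ustat)
  p_le <- mean(us <= obs); p_ge <- mean(us >= obs)
  switch(alternative,
         less = p_le, greater = p_ge,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

# --- misc helpers ----------------------------------------------------------

# a hand-built context with valid boundaries
toy_context <- function(up = "CCCCCCCCCCCCUUUUUUUUUUUUCAG",
                        exon = "GAGGAAGAAGAAGAAGAAGA",
                        down = "GUAAGUCCCCCCCCCC", ...) {
  spliced_context("toy", up, exon, down, ...)
}

# random upstream flank that ends in AG and avoids N
random_flank_ag <- function(len) {
  paste0(random_rna(len - 2), "AG")
}

fast_model <- function() energy_model()
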