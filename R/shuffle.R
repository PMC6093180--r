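#' Dinucleotide-preserving shuffle of an RNA sequence
#'
#' Produces a uniformly chosen rearrangement of `seq` with exactly the
#' same mononucleotide counts, the same dinucleotide count multiset and
#' the same first and last residue, using the Euler-path construction on
#' the dinucleotide multigraph (a uniformly sampled arborescence fixes
#' the last exit edge of every vertex; the remaining out-edges are
#' randomly ordered and the Eulerian walk read off).  Draws come from
#' R's RNG, so results are reproducible under `set.seed()`.
#'
#' @param seq RNA string over A/C/G/U.  Sequences containing N are
#'   rejected; mask or drop such segments first.
#' @return a shuffled RNA string.  Sequences of length <= 3 are returned
#'   unchanged (both endpoints are fixed, so the interior is forced).
#' @export
dinucleotide_shuffle <- function(seq) {
  chars <- .split_chars(seq)
  n <- length(chars)
  if (n < 1) stop("sequence must have length >= 1")
  if (any(!chars %in% RNA_LETTERS)) {
    bad <- setdiff(unique(chars), RNA_LETTERS)
    stop("dinucleotide_shuffle requires a pure A/C/G/U sequence; found ",
         paste(bad, collapse = ","),
         " - mask or drop N-containing segments before shuffling")
  }
  if (n <= 3) return(seq)
  first <- chars[1]; last <- chars[n]
  verts <- unique(chars)
  if (length(verts) == 1) return(seq)
  # adjacency: out-edges of v are the successors of occurrences of v
  adj <- lapply(setNames(verts, verts), function(v) {
    idx <- which(chars[-n] == v)
    chars[idx + 1L]
  })
  need_last <- verts[vapply(adj, length, 1L) > 0 & verts != last]
  for (try in seq_len(100000L)) {
    pick <- lapply(adj[need_last], function(e) e[[sample.int(length(e), 1L)]])
    # arborescence check: following picked edges from every vertex must
    # reach `last` without revisiting
    ok <- TRUE
    for (v in need_last) {
      cur <- v; seen <- character()
      repeat {
        if (cur == last) break
        if (cur %in% seen || !cur %in% need_last) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- pick[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
    if (try == 100000L) stop("arborescence sampling failed (malformed graph?)")
  }
  ord <- adj
  for (v in verts) {
    e <- adj[[v]]
    if (!length(e)) { ord[[v]] <- e; next }
    if (v %in% need_last) {
      # remove one copy of the picked edge, permute the rest, append it
      i <- match(pick[[v]], e)
      rest <- e[-i]
      if (length(rest) > 1) rest <- rest[sample.int(length(rest))]
      ord[[v]] <- c(rest, pick[[v]])
    } else {
      ord[[v]] <- if (length(e) > 1) e[sample.int(length(e))] else e
    }
  }
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- first
  cur <- first
  for (i in 2:n) {
    nxt <- ord[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Shuffle mask
#'
#' Signed-coordinate intervals of the intron flanks that must remain
#' byte-identical under [masked_flank_shuffle()].  Upstream intervals
#' use acceptor-frame intron positions (negative, -1 = G of the 3'ss
#' AG); downstream intervals use donor-frame intron positions (positive,
#' +1 = G of the 5'ss GU/GC).  The exon body is always preserved.
#'
#' @param upstream,downstream lists of length-2 signed intervals.
#' @return object of class `ShuffleMask`.
#' @export
shuffle_mask <- function(upstream = list(), downstream = list()) {
  chk <- function(iv, sign) {
    for (x in iv) {
      if (length(x) != 2) stop("mask intervals must have length 2")
      if (sign < 0 && any(x >= 0)) stop("upstream mask must be negative")
      if (sign > 0 && any(x <= 0)) stop("downstream mask must be positive")
    }
  }
  chk(upstream, -1); chk(downstream, 1)
  structure(list(upstream = upstream, downstream = downstream),
            class = "ShuffleMask")
}

#' Default shuffle mask
#'
#' Preserves the splice sites and the last/first 10 nt of each intron:
#' upstream the 3'ss AG plus 10 intronic nt (positions -12..-1),
#' downstream the 5'ss dinucleotide plus 10 intronic nt (+1..+12).
#' @return a [shuffle_mask()].
#' @export
default_shuffle_mask <- function() {
  shuffle_mask(upstream = list(c(-12, -1)), downstream = list(c(1, 12)))
}

.mask_vector <- function(len, intervals, side) {
  m <- logical(len)
  for (iv in intervals) {
    iv <- sort(iv)
    if (side == "up") {
      # signed -len..-1 maps to index len + pos + 1
      lo <- max(1L, len + iv[1] + 1L); hi <- min(len, len + iv[2] + 1L)
    } else {
      lo <- max(1L, iv[1]); hi <- min(len, iv[2])
    }
    if (lo <= hi) m[lo:hi] <- TRUE
  }
  m
}

.shuffle_segments <- function(chars, mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  out <- chars
  for (k in seq_along(r$values)) {
    if (r$values[k]) next
    seg <- chars[starts[k]:ends[k]]
    out[starts[k]:ends[k]] <-
      .split_chars(dinucleotide_shuffle(paste(seg, collapse = "")))
  }
  out
}

#' Masked dinucleotide shuffles of the intron flanks
#'
#' Generates `n` shuffled versions of a spliced context in which each
#' maximal unmasked segment of each intron flank is independently
#' dinucleotide-shuffled (see [dinucleotide_shuffle()]) while masked
#' intervals and the exon body stay byte-identical.  These are the
#' composition-matched background controls for PU comparisons.
#'
#' @param context a `SplicedContext`.
#' @param mask a [shuffle_mask()]; default = [default_shuffle_mask()].
#' @param n number of shuffled copies (a replicate count of 100 matches
#'   common practice).
#' @return list of `n` `SplicedContext`s, exon ids suffixed
#'   `|shufK`.  If the mask covers both flanks entirely the copies are
#'   identical and a warning is emitted.
#' @export
masked_flank_shuffle <- function(context, mask = default_shuffle_mask(),
                                 n = 100L) {
  if (n < 1) stop("n must be >= 1")
  if (!inherits(mask, "ShuffleMask")) stop("mask must be a shuffle_mask()")
  up <- .split_chars(context$upstream)
  dn <- .split_chars(context$downstream)
  mu <- .mask_vector(length(up), mask$upstream, "up")
  md <- .mask_vector(length(dn), mask$downstream, "down")
  if (all(mu) && all(md))
    warning("mask covers both flanks entirely; returning identical copies")
  lapply(seq_len(n), function(k) {
    ctx <- context
    ctx$exon_id <- sprintf("%s|shuf%d", context$exon_id, k)
    ctx$upstream <- paste(.shuffle_segments(up, mu), collapse = "")
    ctx$downstream <- paste(.shuffle_segments(dn, md), collapse = "")
    ctx
  })
}
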