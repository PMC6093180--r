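# Internal helpers shared across modules: RNA alphabet handling and the
# signed splice-site coordinate frames.
#
# All analysis positions use a signed frame with NO position 0:
#   acceptor frame: -1 is the G of the 3'ss AG, +1 the first exon base;
#   donor frame:    -1 is the last exon base, +1 the G of the 5'ss GU/GC.

RNA_LETTERS <- c("A", "C", "G", "U")

# map characters to integer codes 1..4 (N -> 0)
.encode_rna <- function(seq, allow_n = TRUE) {
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  x[x == "T"] <- "U"
  code <- match(x, RNA_LETTERS)
  if (anyNA(code)) {
    bad <- unique(x[is.na(code)])
    if (!allow_n || any(bad != "N")) {
      stop("invalid RNA letters in sequence: ",
           paste(setdiff(bad, "N"), collapse = ", "),
           if (any(bad == "N") && !allow_n) " (and N not allowed here)")
    }
    code[is.na(code)] <- 0L
  }
  as.integer(code)
}

.to_rna <- function(seq) {
  chartr("Tt", "Uu", toupper(seq))
}

.revcomp_rna <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(seq)))
}

.split_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' Signed frame positions
#'
#' The inclusive sequence of signed splice-site frame positions between
#' `from` and `to` (either order), skipping the non-existent position 0.
#' @param from,to signed positions.
#' @return integer vector.
#' @export
signed_positions <- function(from, to) {
  rng <- sort(c(from, to))
  p <- seq.int(rng[1], rng[2])
  p[p != 0L]
}

# Map a signed frame position to a 1-based index into the concatenated
# context sequence upstream|exon|downstream.  Returns NA outside bounds.
.signed_to_index <- function(context, frame, pos) {
  u <- nchar(context$upstream)
  e <- nchar(context$exon)
  d <- nchar(context$downstream)
  idx <- if (frame == "acceptor") {
    ifelse(pos < 0, u + pos + 1L, u + pos)
  } else {
    ifelse(pos < 0, u + e + pos + 1L, u + e + pos)
  }
  idx[idx < 1L | idx > u + e + d] <- NA_integer_
  as.integer(idx)
}

.context_seq <- function(context) {
  paste0(context$upstream, context$exon, context$downstream)
}

# character at signed positions of the upstream flank (acceptor frame)
.upstream_chars <- function(context) {
  .split_chars(context$upstream)
}

.match_arg_frame <- function(frame) {
  match.arg(frame, c("acceptor", "donor"))
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}
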