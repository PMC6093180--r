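#' Construct a spliced context
#'
#' A `SplicedContext` is the unit of all analyses in this package: one
#' exon together with anchored stretches of its flanking introns, always
#' in transcript orientation and in the RNA alphabet.  Positions are
#' addressed in signed splice-site frames with no position 0: in the
#' acceptor (3'ss) frame, -1 is the G of the intron-terminal AG and +1
#' the first exon base; in the donor (5'ss) frame, -1 is the last exon
#' base and +1 the G of the intron-initial GU/GC.
#'
#' @param exon_id,gene_id identifiers (gene_id may be `NA`).
#' @param upstream,exon,downstream RNA sequences (5' to 3').  The
#'   upstream flank must end in `AG`; the downstream flank must begin
#'   with `GU` or `GC`.
#' @param group one of `"activated"`, `"repressed"`, `"control"`,
#'   `"other"`.
#' @param log2fold exon-usage change on the log2 scale, or `NA`.
#' @param validate_boundaries check the splice-site dinucleotides
#'   (disable only for deliberately malformed test inputs).
#' @return an object of class `SplicedContext` (a named list).
#' @export
spliced_context <- function(exon_id, upstream, exon, downstream,
                            group = "other", log2fold = NA_real_,
                            gene_id = NA_character_,
                            validate_boundaries = TRUE) {
  upstream <- .to_rna(upstream)
  exon <- .to_rna(exon)
  downstream <- .to_rna(downstream)
  for (s in c(upstream, exon, downstream)) {
    bad <- setdiff(unique(.split_chars(s)), c(RNA_LETTERS, "N"))
    if (length(bad))
      stop("invalid letters in spliced context: ", paste(bad, collapse = ","))
  }
  group <- match.arg(group, c("activated", "repressed", "control", "other"))
  if (!is.na(log2fold) && !is.finite(log2fold))
    stop("log2fold must be finite or NA")
  if (validate_boundaries) {
    acc <- substr(upstream, nchar(upstream) - 1L, nchar(upstream))
    if (acc != "AG")
      stop("upstream flank must end in the 3'ss AG, found '", acc, "'")
    don <- substr(downstream, 1L, 2L)
    if (!don %in% c("GU", "GC"))
      stop("downstream flank must begin with the 5'ss GU/GC, found '",
           don, "'")
  }
  structure(
    list(exon_id = as.character(exon_id), gene_id = as.character(gene_id),
         group = group, log2fold = as.numeric(log2fold),
         upstream = upstream, exon = exon, downstream = downstream),
    class = "SplicedContext")
}

#' @export
print.SplicedContext <- function(x, ...) {
  cat(sprintf("SplicedContext %s [%s] up=%dnt exon=%dnt down=%dnt log2fold=%s\n",
              x$exon_id, x$group, nchar(x$upstream), nchar(x$exon),
              nchar(x$downstream),
              ifelse(is.na(x$log2fold), "NA", format(x$log2fold))))
  invisible(x)
}

.VALID_GROUPS <- c("activated", "repressed", "control", "other")

#' Read an exon interval table
#'
#' Two dialects are supported. `"bed6+"`: BED6 columns
#' chrom/start/end/name/score/strand plus optional columns 7 (group) and
#' 8 (log2fold); the name column is the exon id (a `gene:exon` name is
#' split into gene and exon ids).  `"tsv"`: a header line with columns
#' `chrom, start, end, strand, exon_id, gene_id, group, log2fold`
#' (`gene_id`, `group`, `log2fold` optional).  Coordinates are 0-based
#' half-open in both dialects.  Missing log2fold may be `NA`, `.` or an
#' empty field.
#'
#' @param path file path.
#' @param dialect `"bed6+"` or `"tsv"`.
#' @return a data.frame with columns chrom, start, end, strand, exon_id,
#'   gene_id, group, log2fold, in file order.
#' @export
read_exon_table <- function(path, dialect = c("bed6+", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("exon table not found: ", path)
  if (dialect == "bed6+") {
    raw <- read.table(path, sep = "\t", header = FALSE,
                      colClasses = "character", quote = "",
                      comment.char = "#")
    if (ncol(raw) < 6) stop("bed6+ requires at least 6 columns")
    name <- raw[[4]]
    has_gene <- grepl(":", name, fixed = TRUE)
    gene_id <- ifelse(has_gene, sub(":.*$", "", name), NA_character_)
    exon_id <- ifelse(has_gene, sub("^[^:]*:", "", name), name)
    df <- data.frame(
      chrom = raw[[1]],
      start = suppressWarnings(as.integer(raw[[2]])),
      end = suppressWarnings(as.integer(raw[[3]])),
      strand = raw[[6]],
      exon_id = exon_id, gene_id = gene_id,
      group = if (ncol(raw) >= 7) raw[[7]] else "other",
      log2fold = if (ncol(raw) >= 8) .parse_log2fold(raw[[8]]) else NA_real_,
      stringsAsFactors = FALSE)
  } else {
    raw <- read.table(path, sep = "\t", header = TRUE,
                      colClasses = "character", quote = "",
                      comment.char = "#")
    need <- c("chrom", "start", "end", "strand", "exon_id")
    miss <- setdiff(need, names(raw))
    if (length(miss))
      stop("tsv exon table missing columns: ", paste(miss, collapse = ", "))
    df <- data.frame(
      chrom = raw$chrom,
      start = suppressWarnings(as.integer(raw$start)),
      end = suppressWarnings(as.integer(raw$end)),
      strand = raw$strand,
      exon_id = raw$exon_id,
      gene_id = if ("gene_id" %in% names(raw)) raw$gene_id else NA_character_,
      group = if ("group" %in% names(raw)) raw$group else "other",
      log2fold = if ("log2fold" %in% names(raw))
        .parse_log2fold(raw$log2fold) else NA_real_,
      stringsAsFactors = FALSE)
  }
  .validate_exon_table(df, path)
}

.parse_log2fold <- function(x) {
  x[x %in% c("", ".", "NA", "na")] <- NA
  out <- suppressWarnings(as.numeric(x))
  if (any(!is.na(x) & is.na(out)))
    stop("non-numeric log2fold value: ",
         paste(unique(x[!is.na(x) & is.na(out)]), collapse = ", "))
  out
}

.validate_exon_table <- function(df, path) {
  bad <- which(is.na(df$start) | is.na(df$end))
  if (length(bad))
    stop("malformed coordinates in ", path, " at line(s) ",
         paste(bad, collapse = ", "))
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop("end <= start in ", path, " at line(s) ",
         paste(bad, collapse = ", "))
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad))
    stop("strand must be + or - in ", path, " at line(s) ",
         paste(bad, collapse = ", "))
  badg <- setdiff(unique(df$group), .VALID_GROUPS)
  if (length(badg))
    stop("unknown group label(s) in ", path, ": ",
         paste(badg, collapse = ", "))
  if (any(!is.na(df$log2fold) & !is.finite(df$log2fold)))
    stop("log2fold must be finite when present")
  df
}

.genome_seq <- function(genome, chrom) {
  if (is.character(genome)) {
    if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
    return(toupper(genome[[chrom]]))
  }
  # assume Biostrings XStringSet
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  toupper(as.character(genome[[chrom]]))
}

#' Extract the spliced context of one exon from a genome
#'
#' Takes `up_len` nt of the upstream intron, the exon, and `down_len` nt
#' of the downstream intron, in transcript orientation (minus-strand
#' exons are reverse-complemented and the flanks swapped), converts DNA
#' T to RNA U, and validates the splice-site dinucleotides (upstream
#' flank ends `AG`; downstream flank begins `GU`/`GC`).
#'
#' @param genome named character vector or `Biostrings::DNAStringSet`
#'   keyed by chromosome.
#' @param exon one row of an exon table (see [read_exon_table()]) or a
#'   list with fields chrom, start, end, strand, exon_id, and optionally
#'   gene_id, group, log2fold.  Coordinates 0-based half-open.
#' @param up_len,down_len flank lengths in nt (>= 10).
#' @param on_violation `"error"` (default) or `"skip"`: what to do when
#'   a splice-site dinucleotide is not AG / GU / GC.  With `"skip"` the
#'   function returns `NULL` and emits a warning naming the offending
#'   dinucleotide, so annotation bugs stay visible.
#' @return a [spliced_context()] (or `NULL` when skipped).
#' @export
extract_spliced_context <- function(genome, exon, up_len = 150L,
                                    down_len = 150L,
                                    on_violation = c("error", "skip")) {
  on_violation <- match.arg(on_violation)
  if (up_len < 10L || down_len < 10L)
    stop("up_len and down_len must be >= 10")
  exon <- as.list(exon)
  chrom_seq <- .genome_seq(genome, exon$chrom)
  n <- nchar(chrom_seq)
  start <- as.integer(exon$start); end <- as.integer(exon$end)
  if (end <= start) stop("exon end must exceed start")
  # 1-based genomic windows
  if (exon$strand == "+") {
    up_rng <- c(start - up_len + 1L, start)
    dn_rng <- c(end + 1L, end + down_len)
  } else {
    up_rng <- c(end + 1L, end + up_len)
    dn_rng <- c(start - down_len + 1L, start)
  }
  if (min(up_rng[1], dn_rng[1]) < 1L || max(up_rng[2], dn_rng[2]) > n)
    stop("flank out of chromosome bounds for exon ", exon$exon_id)
  up <- substr(chrom_seq, up_rng[1], up_rng[2])
  ex <- substr(chrom_seq, start + 1L, end)
  dn <- substr(chrom_seq, dn_rng[1], dn_rng[2])
  up <- .to_rna(up); ex <- .to_rna(ex); dn <- .to_rna(dn)
  if (exon$strand == "-") {
    up <- .revcomp_rna(up); ex <- .revcomp_rna(ex); dn <- .revcomp_rna(dn)
  }
  res <- tryCatch(
    spliced_context(exon_id = exon$exon_id, upstream = up, exon = ex,
                    downstream = dn,
                    group = if (is.null(exon$group)) "other" else exon$group,
                    log2fold = if (is.null(exon$log2fold)) NA_real_
                               else exon$log2fold,
                    gene_id = if (is.null(exon$gene_id)) NA_character_
                              else exon$gene_id),
    error = function(e) e)
  if (inherits(res, "error")) {
    if (on_violation == "skip") {
      warning("skipping exon ", exon$exon_id, ": ", conditionMessage(res))
      return(NULL)
    }
    stop(conditionMessage(res))
  }
  res
}

#' Extract contexts for every row of an exon table
#'
#' @inheritParams extract_spliced_context
#' @param exons exon table data.frame.
#' @return list of `SplicedContext` (skipped exons dropped when
#'   `on_violation = "skip"`).
#' @export
extract_contexts <- function(genome, exons, up_len = 150L, down_len = 150L,
                             on_violation = c("error", "skip")) {
  on_violation <- match.arg(on_violation)
  out <- lapply(seq_len(nrow(exons)), function(i)
    extract_spliced_context(genome, exons[i, , drop = FALSE],
                            up_len, down_len, on_violation))
  out[!vapply(out, is.null, logical(1))]
}

#' Build an annotation set
#'
#' A minimal transcript model: one row per exon with transcript and gene
#' ids, a principal-isoform flag, and 0-based half-open coordinates.
#' Exons of a transcript must be non-overlapping; they are stored in
#' coordinate order.
#'
#' @param exons data.frame with columns transcript_id, gene_id, chrom,
#'   strand, start, end, principal (logical).
#' @return data.frame of class `AnnotationSet`.
#' @export
annotation_set <- function(exons) {
  need <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end",
            "principal")
  miss <- setdiff(need, names(exons))
  if (length(miss))
    stop("annotation missing columns: ", paste(miss, collapse = ", "))
  if (any(exons$end <= exons$start)) stop("annotation has end <= start")
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  for (tx in unique(exons$transcript_id)) {
    e <- exons[exons$transcript_id == tx, , drop = FALSE]
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
      stop("overlapping exons within transcript ", tx)
  }
  class(exons) <- c("AnnotationSet", "data.frame")
  exons
}

#' Select control exons from an annotation
#'
#' Applies the control-exon filters used for background sets in
#' splice-site architecture studies: one principal isoform per gene (the
#' longest by summed exon length if several are flagged principal;
#' deterministic id tie-break), internal exons only (first and last exon
#' of the transcript dropped), exon length strictly greater than 60 nt,
#' both flanking introns strictly greater than 400 nt, and
#' transcript-sense boundary dinucleotides AG..GU or AG..GC.
#'
#' @param annotation an [annotation_set()].
#' @param genome named character vector or `DNAStringSet`.
#' @param min_exon_len,min_intron_len strict lower bounds (nt) for exon
#'   length and both flanking introns.
#' @return exon table data.frame (see [read_exon_table()]) with all
#'   surviving exons labelled `control`, sorted by gene, transcript and
#'   coordinate; empty annotation gives an empty table.
#' @export
select_control_exons <- function(annotation, genome,
                                 min_exon_len = 60L, min_intron_len = 400L) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      exon_id = character(), gene_id = character(),
                      group = character(), log2fold = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(annotation) == 0) return(empty)
  ann <- as.data.frame(annotation)
  ann <- ann[order(ann$gene_id, ann$transcript_id, ann$start), , drop = FALSE]
  keep <- list()
  for (g in sort(unique(ann$gene_id))) {
    ga <- ann[ann$gene_id == g & ann$principal, , drop = FALSE]
    if (nrow(ga) == 0) next
    lens <- tapply(ga$end - ga$start, ga$transcript_id, sum)
    # longest principal isoform; ties broken by transcript id
    best_tx <- names(lens)[order(-lens, names(lens))][1]
    tx <- ga[ga$transcript_id == best_tx, , drop = FALSE]
    tx <- tx[order(tx$start), , drop = FALSE]
    if (nrow(tx) < 3) next
    for (i in 2:(nrow(tx) - 1)) {
      if (tx$end[i] - tx$start[i] <= min_exon_len) next
      intron_up_gen <- tx$start[i] - tx$end[i - 1]
      intron_dn_gen <- tx$start[i + 1] - tx$end[i]
      if (intron_up_gen <= min_intron_len || intron_dn_gen <= min_intron_len)
        next
      chrom_seq <- .genome_seq(genome, tx$chrom[i])
      s <- tx$start[i]; e <- tx$end[i]
      if (s - 1L < 1L || e + 2L > nchar(chrom_seq)) next
      left <- .to_rna(substr(chrom_seq, s - 1L, s))     # genomic before exon
      right <- .to_rna(substr(chrom_seq, e + 1L, e + 2L))
      ok <- if (tx$strand[i] == "+") {
        left == "AG" && right %in% c("GU", "GC")
      } else {
        # transcript sense on minus strand
        .revcomp_rna(right) == "AG" && .revcomp_rna(left) %in% c("GU", "GC")
      }
      if (!ok) next
      keep[[length(keep) + 1L]] <- data.frame(
        chrom = tx$chrom[i], start = tx$start[i], end = tx$end[i],
        strand = tx$strand[i],
        exon_id = sprintf("%s.e%d", best_tx, i),
        gene_id = g, group = "control", log2fold = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(keep)) return(empty)
  out <- do.call(rbind, keep)
  out <- out[order(out$gene_id, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- context FASTA dialect ------------------------------------------------
# header: >exon_id|group|log2fold|up_len|exon_len|down_len
# sequence: upstream + exon + downstream on one line (byte-deterministic)

.fmt_log2fold <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write spliced contexts to the structured-header FASTA dialect
#'
#' Header fields: `exon_id|group|log2fold|up_len|exon_len|down_len`;
#' the record sequence is the concatenation upstream+exon+downstream.
#' Output is byte-deterministic.
#'
#' @param contexts list of `SplicedContext`.
#' @param path output file.
#' @export
write_context_fasta <- function(contexts, path) {
  lines <- unlist(lapply(contexts, function(ctx) {
    c(sprintf(">%s|%s|%s|%d|%d|%d", ctx$exon_id, ctx$group,
              .fmt_log2fold(ctx$log2fold), nchar(ctx$upstream),
              nchar(ctx$exon), nchar(ctx$downstream)),
      .context_seq(ctx))
  }))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read spliced contexts from the structured-header FASTA dialect
#'
#' @param path file written by [write_context_fasta()] (or following the
#'   same header convention).
#' @return list of `SplicedContext`.
#' @export
read_context_fasta <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  lapply(seq_along(recs), function(i) {
    hdr <- strsplit(names(recs)[i], "|", fixed = TRUE)[[1]]
    if (length(hdr) != 6)
      stop("malformed context FASTA header: ", names(recs)[i])
    up_len <- as.integer(hdr[4]); ex_len <- as.integer(hdr[5])
    dn_len <- as.integer(hdr[6])
    seq <- as.character(recs[[i]])
    if (nchar(seq) != up_len + ex_len + dn_len)
      stop("context FASTA sequence length does not match header: ", hdr[1])
    spliced_context(
      exon_id = hdr[1], group = hdr[2],
      log2fold = if (hdr[3] == "NA") NA_real_ else as.numeric(hdr[3]),
      upstream = substr(seq, 1, up_len),
      exon = substr(seq, up_len + 1, up_len + ex_len),
      downstream = substr(seq, up_len + ex_len + 1, nchar(seq)))
  })
}
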