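test_that("exon tables parse in both dialects and validate coordinates", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t100\t200\tgeneA:ex1\t0\t+\tactivated\t-1.25",
    "chr1\t400\t520\tex2\t0\t-\tcontrol\tNA",
    "chr2\t10\t60\tgeneB:ex3\t0\t+\trepressed\t0.8"), bed)
  tab <- read_exon_table(bed, "bed6+")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$group, c("activated", "control", "repressed"))
  expect_equal(tab$exon_id, c("ex1", "ex2", "ex3"))
  expect_equal(tab$gene_id, c("geneA", NA, "geneB"))
  expect_equal(tab$log2fold, c(-1.25, NA, 0.8))

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tstrand\texon_id",
               "chr1\t5\t80\t+\tx1"), tsv)
  tab2 <- read_exon_table(tsv, "tsv")
  expect_true(is.na(tab2$log2fold))   # missing column -> missing values
  expect_equal(tab2$group, "other")

  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\ta\t0\t+",
               "chr1\t300\t250\tb\t0\t+"), bad)
  expect_error(read_exon_table(bad, "bed6+"), "line\\(s\\) 2")

  badg <- tempfile(fileext = ".bed")
  writeLines("chr1\t1\t50\ta\t0\t+\tupregulated", badg)
  expect_error(read_exon_table(badg, "bed6+"), "group")
})

test_that("plus-strand extraction anchors the splice-site dinucleotides", {
  # ...AAAG | exon | GUAAA...
  chrom <- paste0(strrep("C", 20), "AAAG", "TTTCATTTCA", "GTAAA",
                  strrep("C", 20))
  genome <- c(chr1 = chrom)
  exon <- list(chrom = "chr1", start = 24L, end = 34L, strand = "+",
               exon_id = "e1")
  ctx <- extract_spliced_context(genome, exon, up_len = 12, down_len = 12)
  expect_equal(substr(ctx$upstream, 11, 12), "AG")
  expect_equal(substr(ctx$downstream, 1, 2), "GU")
  expect_equal(ctx$exon, "UUUCAUUUCA")
})

test_that("minus-strand extraction equals the hand reverse-complement", {
  set.seed(11)
  plus_chrom <- paste0(strrep("T", 12), "AAAG", "CCGGTTAA", "GTCCC",
                       strrep("T", 11))
  # a minus-strand exon on the reverse complement of that chromosome
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  minus_chrom <- rc(plus_chrom)
  n <- nchar(plus_chrom)
  # plus coordinates of the exon: start=16, end=24 (0-based half-open)
  ctx_plus <- extract_spliced_context(c(chr = plus_chrom),
                                      list(chrom = "chr", start = 16L,
                                           end = 24L, strand = "+",
                                           exon_id = "e"),
                                      up_len = 10, down_len = 10)
  ctx_minus <- extract_spliced_context(c(chr = minus_chrom),
                                       list(chrom = "chr",
                                            start = n - 24L, end = n - 16L,
                                            strand = "-", exon_id = "e"),
                                       up_len = 10, down_len = 10)
  expect_identical(ctx_plus$upstream, ctx_minus$upstream)
  expect_identical(ctx_plus$exon, ctx_minus$exon)
  expect_identical(ctx_plus$downstream, ctx_minus$downstream)
})

test_that("boundary violations error by default and skip on request", {
  chrom <- paste0(strrep("A", 30), "AC", "TTTTT", "GT", strrep("A", 30))
  genome <- c(chr1 = chrom)
  exon <- list(chrom = "chr1", start = 32L, end = 37L, strand = "+",
               exon_id = "bad")
  expect_error(extract_spliced_context(genome, exon, 10, 10), "AC")
  expect_warning(
    res <- extract_spliced_context(genome, exon, 10, 10,
                                   on_violation = "skip"),
    "skipping")
  expect_null(res)
  expect_error(extract_spliced_context(genome,
                                       list(chrom = "chr1", start = 3L,
                                            end = 8L, strand = "+",
                                            exon_id = "oob"), 10, 10),
               "bounds")
})

# builds a genome holding one multi-exon gene with AG..GT boundaries on
# every internal exon; returns genome and annotation rows
.build_gene <- function(tx, gene, exon_starts, exon_len, principal,
                        chrom_len = 6000, strand = "+") {
  chrom <- strsplit(strrep("C", chrom_len), "")[[1]]
  for (s in exon_starts) {
    chrom[(s - 1):s] <- c("A", "G")
    chrom[(s + exon_len + 1):(s + exon_len + 2)] <- c("G", "T")
  }
  ann <- data.frame(transcript_id = tx, gene_id = gene, chrom = "chr",
                    strand = strand, start = exon_starts,
                    end = exon_starts + exon_len, principal = principal)
  list(chrom = paste(chrom, collapse = ""), ann = ann)
}

test_that("control selection applies the four filters and principal choice", {
  g <- .build_gene("tx1", "g1", c(500, 1500, 2500, 3500), 100, TRUE)
  ann <- annotation_set(g$ann)
  ctrl <- select_control_exons(ann, c(chr = g$chrom))
  # internal exons only: exons 2 and 3
  expect_equal(nrow(ctrl), 2)
  expect_true(all(ctrl$group == "control"))
  expect_equal(ctrl$start, c(1500, 2500))

  # exon of length exactly 60 is excluded (strict >)
  g60 <- .build_gene("tx1", "g1", c(500, 1500, 2500), 60, TRUE)
  expect_equal(nrow(select_control_exons(annotation_set(g60$ann),
                                         c(chr = g60$chrom))), 0)

  # introns of exactly 400 are excluded (strict >)
  gi <- .build_gene("tx1", "g1", c(500, 1000, 1500), 100, TRUE)
  expect_equal(nrow(select_control_exons(annotation_set(gi$ann),
                                         c(chr = gi$chrom))), 0)

  # two principal isoforms: only the longest is used
  glong <- .build_gene("txB", "g1", c(500, 1500, 2500, 3500), 100, TRUE)
  gshort <- data.frame(transcript_id = "txA", gene_id = "g1", chrom = "chr",
                       strand = "+", start = c(500, 1500, 2500),
                       end = c(600, 1600, 2600), principal = TRUE)
  ann2 <- annotation_set(rbind(glong$ann, gshort))
  ctrl2 <- select_control_exons(ann2, c(chr = glong$chrom))
  expect_true(all(grepl("^txB", ctrl2$exon_id)))

  # output invariant to row order
  ann3 <- annotation_set(rbind(gshort, glong$ann)[sample(7), ])
  expect_identical(select_control_exons(ann3, c(chr = glong$chrom)), ctrl2)

  expect_equal(nrow(select_control_exons(
    annotation_set(g$ann[0, ]), c(chr = g$chrom))), 0)
})

test_that("context FASTA round-trips byte-identically", {
  set.seed(3)
  ctxs <- lapply(1:5, function(i)
    spliced_context(paste0("ex", i),
                    upstream = random_flank_ag(40),
                    exon = random_rna(30),
                    downstream = paste0("GU", random_rna(38)),
                    group = sample(c("activated", "control"), 1),
                    log2fold = if (i %% 2) rnorm(1) else NA))
  f1 <- tempfile(fileext = ".fa")
  write_context_fasta(ctxs, f1)
  back <- read_context_fasta(f1)
  expect_equal(back, ctxs, ignore_attr = FALSE)
  f2 <- tempfile(fileext = ".fa")
  write_context_fasta(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
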