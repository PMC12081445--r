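test_that("validate_transcripts accepts the toy models and enforces invariants", {
  tx <- toy_transcripts()
  expect_silent(validate_transcripts(tx))
  expect_silent(validate_transcripts(tx, require_cds_multiple = TRUE))

  broken <- tx
  broken$exon_number[broken$gene == "TOYA"] <- c(1L, 2L, 2L, 4L)
  expect_error(validate_transcripts(broken), "consecutive")

  broken <- tx
  broken$cds_start[1] <- broken$start[1] - 10L
  expect_error(validate_transcripts(broken), "CDS not contained")

  # minus-strand numbering must follow transcription order (right to left)
  broken <- tx
  broken$exon_number[broken$gene == "TOYB"] <- c(3L, 2L, 1L)
  expect_error(validate_transcripts(broken), "transcription order")
})

test_that("exon_phase implements cumulative CDS mod 3 with strand awareness", {
  tx <- toy_transcripts()
  expect_equal(exon_phase(tx, "TOYA", 1:4), c(0L, 2L, 0L, 1L))
  expect_equal(exon_phase(tx, "TOYB", 1:3), c(NA_integer_, 0L, 1L))
  expect_error(exon_phase(tx, "TOYA", 5), "no exon")
  expect_error(exon_phase(tx, "NOPE", 1), "not found")
})

test_that("exon phases match a codon-walking oracle on simulated genes", {
  tx <- shared_tx()
  for (g in c("NTRK1", "NTRK3", "LMNA", "SIMPART02")) {
    ex <- tx[tx$gene == g, ]
    ex <- ex[order(ex$exon_number), ]
    lens <- ifelse(is.na(ex$cds_start), 0L, ex$cds_end - ex$cds_start + 1L)
    walked <- integer(0)
    consumed <- 0L
    for (k in seq_len(nrow(ex))) {
      walked[k] <- if (lens[k] == 0L && consumed == 0L) NA_integer_
                   else consumed %% 3L
      consumed <- consumed + lens[k]
    }
    expect_equal(exon_phase(tx, g, seq_len(nrow(ex))), walked, info = g)
  }
})

test_that("locate_breakpoint covers every base of a toy gene exactly once", {
  tx <- toy_transcripts()
  for (g in c("TOYA", "TOYB")) {
    ex <- tx[tx$gene == g, ]
    span <- seq(min(ex$start), max(ex$end))
    kinds <- vapply(span, function(p) locate_breakpoint(tx, g, p)$kind, "")
    n_exonic <- sum(kinds == "exon")
    expect_equal(n_exonic, sum(ex$end - ex$start + 1L))
    expect_equal(sum(kinds == "intron"), length(span) - n_exonic)
  }
  # strand-aware exon offsets: minus-strand offset 1 is the genomic right end
  d <- locate_breakpoint(tx, "TOYB", 2100)
  expect_equal(d$kind, "exon"); expect_equal(d$ordinal, 1L)
  expect_equal(d$exon_offset, 1L)
  d <- locate_breakpoint(tx, "TOYB", 2001)
  expect_equal(d$exon_offset, 100L)
  expect_error(locate_breakpoint(tx, "TOYB", 5), "outside the span")
})

test_that("breakpoint_genomic inverts locate_breakpoint on exonic positions", {
  tx <- toy_transcripts()
  withr::with_seed(3, {
    for (g in c("TOYA", "TOYB")) {
      ex <- tx[tx$gene == g, ]
      for (i in seq_len(20)) {
        k <- sample(ex$exon_number, 1)
        off <- sample.int(ex$end[ex$exon_number == k] -
                            ex$start[ex$exon_number == k] + 1L, 1)
        pos <- breakpoint_genomic(tx, g, "exon", k, off)
        d <- locate_breakpoint(tx, g, pos)
        expect_equal(d$kind, "exon")
        expect_equal(d$ordinal, k)
        expect_equal(d$exon_offset, off)
      }
      # intron midpoints map back to the same intron
      for (k in seq_len(max(ex$exon_number) - 1L)) {
        pos <- breakpoint_genomic(tx, g, "intron", k)
        d <- locate_breakpoint(tx, g, pos)
        expect_equal(d$kind, "intron")
        expect_equal(d$ordinal, k)
      }
    }
  })
})

test_that("TSV and GTF dialects round-trip identical content", {
  tx <- toy_transcripts()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_transcripts_tsv(tx, tsv)
  write_transcripts_gtf(tx, gtf)
  from_tsv <- read_transcripts(tsv)
  from_gtf <- read_transcripts(gtf)
  key <- c("gene", "chrom", "strand", "exon_number", "start", "end",
           "cds_start", "cds_end")
  norm <- function(x) {
    x <- tibble::as_tibble(x)[key]
    x[order(x$gene, x$exon_number), ]
  }
  expect_equal(norm(from_tsv), norm(tx))
  expect_equal(norm(from_gtf), norm(tx))
  expect_equal(dplyr::arrange(transcript_domains(from_tsv), .data$gene),
               dplyr::arrange(transcript_domains(tx), .data$gene))
  expect_equal(dplyr::arrange(transcript_domains(from_gtf), .data$gene),
               dplyr::arrange(transcript_domains(tx), .data$gene))
})

test_that("GTF reader keeps the longest-CDS transcript and reports it", {
  tx <- toy_transcripts()
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_transcripts_gtf(tx[tx$gene == "TOYA", ], gtf)
  # add a second, shorter transcript of the same gene
  extra <- c(
    paste("chr1", "x", "exon", 101, 200, ".", "+", ".",
          'gene_id "TOYA"; transcript_id "TOYA.t2"; exon_number "1";',
          sep = "\t"),
    paste("chr1", "x", "CDS", 151, 180, ".", "+", "0",
          'gene_id "TOYA"; transcript_id "TOYA.t2"; exon_number "1";',
          sep = "\t"))
  writeLines(c(readLines(gtf), extra), gtf)
  expect_message(got <- read_transcripts(gtf), "longest CDS")
  expect_equal(nrow(got), 4)
  expect_equal(sum(got$cds_end - got$cds_start + 1, na.rm = TRUE), 300)
})

test_that("malformed transcript TSV fails with a line-numbered error", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tchrom\tstrand\texon_number\tstart\tend\tcds_start\tcds_end",
               "G1\tchr1\t+\tone\t10\t20\tNA\tNA"), tsv)
  expect_error(read_transcripts(tsv), "line 2")
})
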