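# hand-built toy transcript models with fully known geometry
#
# TOYA (+ strand): 4 exons of length 100; CDS lengths 50/100/100/50 (total
# 300), so exon phases are 0, 2, 0, 1. Domain "DOM" spans exons 3-4.
# TOYB (- strand): 3 exons of length 100; exon 1 fully non-coding, CDS
# lengths 0/100/71 (total 171), so exon phases are NA, 0, 1.
toy_transcripts <- function() {
  exons <- tibble::tribble(
    ~gene,  ~chrom, ~strand, ~exon_number, ~start, ~end, ~cds_start, ~cds_end,
    "TOYA", "chr1", "+",     1L,           101L,   200L, 151L,       200L,
    "TOYA", "chr1", "+",     2L,           301L,   400L, 301L,       400L,
    "TOYA", "chr1", "+",     3L,           501L,   600L, 501L,       600L,
    "TOYA", "chr1", "+",     4L,           701L,   800L, 701L,       750L,
    "TOYB", "chr2", "-",     1L,           2001L,  2100L, NA,        NA,
    "TOYB", "chr2", "-",     2L,           1501L,  1600L, 1501L,     1600L,
    "TOYB", "chr2", "-",     3L,           1001L,  1100L, 1030L,     1100L)
  domains <- tibble::tibble(gene = "TOYA", domain = "DOM",
                            first_exon = 3L, last_exon = 4L)
  trkfusions:::new_transcripts(exons, domains)
}

# one shared simulated transcriptome for tests that need NTRK geometry
shared_tx <- local({
  tx <- NULL
  function() {
    if (is.null(tx)) tx <<- simulate_transcriptome(n_novel_partners = 6,
                                                   seed = 101)
    tx
  }
})

# phase at the junction made by cutting in intron k: 5' side contributes the
# phase entering exon k+1; the 3' side resumes at the same quantity
junction_phase <- function(tx, gene, intron) exon_phase(tx, gene, intron + 1L)

# find a 5' intron of `g5` whose phase matches `phase3` (in-frame junction);
# introns retaining no CDS at all are skipped (their frame is indeterminate)
pick_inframe_intron <- function(tx, g5, phase3) {
  ex <- trkfusions:::gene_exons(tx, g5)
  for (k in seq_len(nrow(ex) - 1L)) {
    retained <- ex$cum_cds_before[k] + ex$cds_len[k]
    if (retained > 0 && retained %% 3L == phase3) return(k)
  }
  stop("no frame-matched intron found in ", g5)
}

# worked-example fusion calls from the classification rules; the novel-partner
# in-frame example picks a phase-matched intron from the actual geometry
worked_calls <- function(tx = worked_tx()) {
  erbb2_o5 <- pick_inframe_intron(tx, "ERBB2", junction_phase(tx, "NTRK3", 14L))
  tibble::tibble(
    specimen_id = sprintf("WK%02d", 1:5),
    gene_5p = c("LMNA", "GNAQ", "ERBB2", "NTRK1", "LMNA"),
    bp_5p   = c("intron3", "intron1", paste0("intron", erbb2_o5), "intron11",
                "intron3"),
    gene_3p = c("NTRK1", "NTRK2", "NTRK3", "SIMPART02", "NTRK1"),
    bp_3p   = c("intron11", "intron15", "intron14", "intron2", "intron11"),
    unique_reads = c(12L, 9L, 8L, 20L, 4L))
}

# transcriptome for the worked examples: a novel gene renamed ERBB2 so the
# published ERBB2-NTRK3 example is expressible
worked_tx <- local({
  tx <- NULL
  function() {
    if (is.null(tx)) {
      t0 <- shared_tx()
      t0$gene[t0$gene == "SIMPART01"] <- "ERBB2"
      tx <<- t0
    }
    tx
  }
})
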