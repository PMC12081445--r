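# Brute-force translate-and-scan ORF oracle, independent of the package's
# phase arithmetic. Each gene gets a random CDS nucleotide sequence with no
# internal stop codons; a junction is judged in frame when the translated
# chimeric CDS still contains the 3' gene's native C-terminal peptide with
# no stop codon upstream of it.

# Codons drawn from {A, C, G} only: no codon is a stop, and because stops all
# begin with T, even the chimeric codon straddling the fusion junction can
# never be a stop. This keeps the oracle's verdict a pure function of the
# reading frame rather than of sequence luck at the junction.
non_stop_codons <- local({
  bases <- c("A", "C", "G")
  apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
})

# one random stop-free CDS per gene, as a named character vector
oracle_sequences <- function(tx, seed = 7) {
  withr::with_seed(seed, {
    genes <- unique(tx$gene)
    out <- vapply(genes, function(g) {
      total <- cds_total_len(tx, g)
      stopifnot(total %% 3 == 0, total > 0)
      paste(sample(non_stop_codons, total / 3, replace = TRUE), collapse = "")
    }, character(1))
    out
  })
}

# independent CDS bookkeeping straight off the exon table
cds_total_len <- function(tx, gene) {
  ex <- tx[tx$gene == gene, ]
  sum(ifelse(is.na(ex$cds_start), 0L, ex$cds_end - ex$cds_start + 1L))
}

# CDS bases retained upstream of a cut in intron k (transcript order)
cds_len_through_exon <- function(tx, gene, k) {
  ex <- tx[tx$gene == gene, ]
  ex <- ex[order(ex$exon_number), ]
  lens <- ifelse(is.na(ex$cds_start), 0L, ex$cds_end - ex$cds_start + 1L)
  sum(lens[seq_len(k)])
}

# TRUE (in frame), FALSE (out of frame), or NA (indeterminate: no coding
# sequence retained on one side) for a fusion cut in intron o5 / intron o3
oracle_in_frame <- function(tx, seqs, g5, o5, g3, o3) {
  l5 <- cds_len_through_exon(tx, g5, o5)
  total3 <- cds_total_len(tx, g3)
  upstream3 <- cds_len_through_exon(tx, g3, o3)
  l3 <- total3 - upstream3
  if (l5 == 0 || l3 == 0) return(NA)
  prefix <- substr(seqs[[g5]], 1, l5)
  suffix <- substr(seqs[[g3]], upstream3 + 1, total3)
  fused <- paste0(prefix, suffix)
  fused <- substr(fused, 1, (nchar(fused) %/% 3) * 3)
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(fused),
                                             no.init.codon = TRUE))
  native3 <- as.character(Biostrings::translate(
    Biostrings::DNAString(seqs[[g3]]), no.init.codon = TRUE))
  marker <- substr(native3, nchar(native3) - 9, nchar(native3))
  hit <- regexpr(marker, prot, fixed = TRUE)[1]
  if (hit < 0) return(FALSE)
  upstream_prot <- substr(prot, 1, hit - 1)
  !grepl("*", upstream_prot, fixed = TRUE)
}
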