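#' Tyrosine-kinase-domain retention regions
#'
#' The TRK tyrosine kinase domain (TKD) is annotated on exons 9-17 of NTRK1,
#' 16-20 of NTRK2, and 15-19 of NTRK3. Retention of the kinase fold by the 3'
#' fusion segment is, however, judged against a per-gene *breakpoint-compatible
#' region*: the most 3' breakpoints observed in functional fusions fall inside
#' the annotated TKD span, so the catalytic fold that must survive begins a few
#' exons into it. The shipped defaults (`required_first_exon` 12/18/16) encode
#' the region compatible with the breakpoints of fusions judged oncogenic or
#' likely oncogenic (e.g. an NTRK1 intron-11 breakpoint retains the fold).
#' The table is data, not code, and can be replaced to adopt a stricter
#' convention such as requiring the full annotated span.
#'
#' @param path Optional path to a TSV with columns `ntrk_gene`,
#'   `tkd_first_exon`, `tkd_last_exon`, `required_first_exon`. Defaults to the
#'   table bundled with the package.
#' @return Tibble with one row per NTRK gene.
#' @export
default_tkd_regions <- function(path = NULL) {
  path <- path %||% system.file("extdata", "tkd_regions.tsv",
                                package = "trkfusions", mustWork = TRUE)
  readr::read_tsv(path, col_types = "ciii", comment = "#", progress = FALSE)
}

#' Is the kinase domain retained by a 3' breakpoint?
#'
#' A 3' fusion segment retains the kinase domain when every exon of the
#' required region lies fully downstream of the breakpoint: an intronic
#' breakpoint with ordinal below `required_first_exon`, or an exonic
#' breakpoint in an exon strictly upstream of `required_first_exon`. An
#' exonic breakpoint inside the required span itself counts as *not*
#' retained (partial domain loss is not assumed functional).
#'
#' Moving a 3' breakpoint further 5' can therefore never lose a domain that
#' was retained (monotonicity).
#'
#' @param transcripts A transcript tibble.
#' @param gene An NTRK gene symbol.
#' @param kind "intron" or "exon".
#' @param ordinal Breakpoint ordinal (transcript order).
#' @param tkd_regions Retention region table, see [default_tkd_regions()].
#' @return Logical scalar.
#' @examples
#' tx <- simulate_transcriptome(n_novel_partners = 2, seed = 1)
#' tkd_retained(tx, "NTRK1", "intron", 11)  # TRUE
#' tkd_retained(tx, "NTRK1", "intron", 14)  # FALSE: required region truncated
#' @export
tkd_retained <- function(transcripts, gene, kind, ordinal,
                         tkd_regions = default_tkd_regions()) {
  row <- tkd_regions[tkd_regions$ntrk_gene == gene, ]
  if (nrow(row) != 1) {
    stop(sprintf("%s is not an NTRK gene with a kinase-domain region", gene),
         call. = FALSE)
  }
  ex <- gene_exons(transcripts, gene)
  n <- nrow(ex)
  if (kind == "intron" && (ordinal < 1 || ordinal > n - 1)) {
    stop(sprintf("%s has no intron %d", gene, ordinal), call. = FALSE)
  }
  if (kind == "exon" && (ordinal < 1 || ordinal > n)) {
    stop(sprintf("%s has no exon %d", gene, ordinal), call. = FALSE)
  }
  # intron k retains exons k+1..n; exon j retains only part of exon j
  ordinal < row$required_first_exon
}
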