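#' Reading-frame preservation at a fusion junction
#'
#' Frame preservation is decided by exon phase arithmetic. For the 5' gene,
#' the phase at the end of the retained segment is the retained CDS length
#' modulo 3 (for exonic breakpoints, counted to the exact coding offset of
#' the breakpoint base). For the 3' gene, the phase at the start of the
#' retained segment is the CDS length native to the transcript upstream of
#' the first retained base, modulo 3. The junction is in frame exactly when
#' the two phases are defined and equal; when the retained 5' portion
#' contains no CDS, or the retained 3' portion contains no CDS, the status
#' is `indeterminate`.
#'
#' Breakpoint convention: a 5' breakpoint retains its exon up to and
#' including the offset base; a 3' breakpoint retains its exon from the
#' offset base onward.
#'
#' @param annotated Annotated fusion tibble from [annotate_fusions()].
#' @param transcripts Transcript tibble.
#' @return `annotated` with columns `end_phase_5p`, `start_phase_3p`
#'   (integer, `NA` when undefined) and `frame_status`
#'   (`in_frame` / `out_of_frame` / `indeterminate`).
#' @export
frame_preserved <- function(annotated, transcripts) {
  res <- purrr::pmap(
    list(annotated$gene_5p, annotated$bp5_kind, annotated$bp5_ordinal,
         annotated$bp5_offset, annotated$gene_3p, annotated$bp3_kind,
         annotated$bp3_ordinal, annotated$bp3_offset),
    function(g5, k5, o5, f5, g3, k3, o3, f3) {
      if (is.na(k5) || is.na(k3)) {
        return(tibble::tibble(end_phase_5p = NA_integer_,
                              start_phase_3p = NA_integer_,
                              frame_status = "indeterminate"))
      }
      p5 <- phase_end_5p(transcripts, g5, k5, o5, f5)
      p3 <- phase_start_3p(transcripts, g3, k3, o3, f3)
      status <- if (is.na(p5) || is.na(p3)) "indeterminate"
                else if (p5 == p3) "in_frame" else "out_of_frame"
      tibble::tibble(end_phase_5p = p5, start_phase_3p = p3,
                     frame_status = status)
    })
  dplyr::bind_cols(annotated, dplyr::bind_rows(res))
}

# CDS length retained by a 5' breakpoint, mod 3 (NA when no CDS retained)
phase_end_5p <- function(transcripts, gene, kind, ordinal, offset) {
  ex <- gene_exons(transcripts, gene)
  retained <- if (kind == "intron") {
    ex$cum_cds_before[ordinal] + ex$cds_len[ordinal]
  } else {
    within <- cds_overlap_len(ex, ordinal, 1L, offset)
    ex$cum_cds_before[ordinal] + within
  }
  if (retained == 0) NA_integer_ else as.integer(retained %% 3L)
}

# native CDS length upstream of the first retained 3' base, mod 3
# (NA when the retained portion contains no CDS)
phase_start_3p <- function(transcripts, gene, kind, ordinal, offset) {
  ex <- gene_exons(transcripts, gene)
  total <- sum(ex$cds_len)
  upstream <- if (kind == "intron") {
    ex$cum_cds_before[ordinal] + ex$cds_len[ordinal]
  } else {
    ex$cum_cds_before[ordinal] + cds_overlap_len(ex, ordinal, 1L, offset - 1L)
  }
  if (total - upstream <= 0) NA_integer_ else as.integer(upstream %% 3L)
}

# bases of exon `ordinal`'s CDS falling in transcript-orientation offsets [a, b]
cds_overlap_len <- function(ex, ordinal, a, b) {
  if (is.na(ex$cds_off_start[ordinal]) || b < a) return(0L)
  lo <- max(a, ex$cds_off_start[ordinal])
  hi <- min(b, ex$cds_off_end[ordinal])
  max(0L, hi - lo + 1L)
}

#' Classify one table of annotated fusions
#'
#' Applies the rule-based oncogenicity decision procedure, in order:
#' \enumerate{
#'   \item the NTRK gene must be the 3' component, else VUS;
#'   \item the 3' breakpoint must retain the kinase domain, else VUS;
#'   \item a known (canonical or clinical-validity) partner makes the fusion
#'     ONCOGENIC — the frame condition applies only to novel partners, so
#'     known-partner fusions with indeterminate frame (e.g. promoter-swap
#'     style 5'-UTR breakpoints) still classify ONCOGENIC;
#'   \item a novel partner with a frame-preserving junction is
#'     LIKELY_ONCOGENIC;
#'   \item anything else — out-of-frame or frame-indeterminate novel-partner
#'     fusions — is VUS.
#' }
#' Each row records the outcome of every rule evaluated (`reasons`) and the
#' knowledge-base version used.
#'
#' @param annotated Annotated fusion tibble with no annotation errors.
#' @param transcripts Transcript tibble.
#' @param kb Knowledge base, see [default_kb()].
#' @param tkd_regions Kinase-domain retention table, see
#'   [default_tkd_regions()].
#' @return Classified tibble with `verdict`, `partner_status`,
#'   `frame_status`, `tkd_ok`, `reasons`, `kb_version` columns.
#' @export
classify_fusions <- function(annotated, transcripts, kb = default_kb(),
                             tkd_regions = default_tkd_regions()) {
  if (nrow(annotated) == 0) {
    return(dplyr::mutate(annotated, verdict = character(0),
                         partner_status = character(0),
                         frame_status = character(0), tkd_ok = logical(0),
                         reasons = character(0), kb_version = character(0)))
  }
  if ("annotation_error" %in% names(annotated) &&
      any(!is.na(annotated$annotation_error))) {
    stop("cannot classify fusions carrying annotation errors", call. = FALSE)
  }
  if (!"frame_status" %in% names(annotated)) {
    annotated <- frame_preserved(annotated, transcripts)
  }
  rows <- purrr::pmap(
    list(annotated$ntrk_role, annotated$ntrk_gene, annotated$gene_5p,
         annotated$bp3_kind, annotated$bp3_ordinal, annotated$frame_status),
    function(role, ng, g5, k3, o3, frame) {
      reasons <- character(0)
      verdict <- NULL
      tkd_ok <- NA
      status <- NA_character_
      if (role != "3prime") {
        reasons <- c(reasons, sprintf("orientation=%s", role))
        verdict <- "VUS"
      } else {
        reasons <- c(reasons, "orientation=3prime")
        tkd_ok <- tkd_retained(transcripts, ng, k3, o3, tkd_regions)
        reasons <- c(reasons, sprintf("tkd=%s",
                                      if (tkd_ok) "retained" else "lost"))
        if (!tkd_ok) {
          verdict <- "VUS"
        } else {
          status <- partner_status(kb, g5, ng)
          reasons <- c(reasons, sprintf("partner=%s", status))
          if (startsWith(status, "known")) {
            verdict <- "ONCOGENIC"
          } else {
            reasons <- c(reasons, sprintf("frame=%s", frame))
            verdict <- if (frame == "in_frame") "LIKELY_ONCOGENIC" else "VUS"
          }
        }
      }
      tibble::tibble(verdict = verdict, partner_status = status,
                     tkd_ok = tkd_ok,
                     reasons = paste(reasons, collapse = "|"))
    })
  out <- dplyr::bind_cols(annotated, dplyr::bind_rows(rows))
  out$fusion_name <- paste(out$gene_5p, out$gene_3p, sep = "-")
  out$kb_version <- kb_version(kb)
  out
}

#' Run the full fusion classification pipeline
#'
#' read -> filter by read support -> annotate -> classify, with a QC report
#' whose totals reconcile exactly: input rows = classified + removed by the
#' read filter + failed annotation. Output rows are ordered by specimen then
#' input row, for reproducible diffs.
#'
#' @param calls Fusion call tibble or path to a fusion TSV.
#' @param transcripts Transcript tibble.
#' @param kb Knowledge base.
#' @param min_reads Unique-read support threshold (default 5).
#' @param tkd_regions Kinase-domain retention table.
#' @return An object of class `ntrk_classification`: list with `classified`
#'   (tibble) and `qc` (named list). Use [tidy()] for the table and
#'   [glance()] for the QC one-liner.
#' @examples
#' tx <- simulate_transcriptome(n_novel_partners = 4, seed = 7)
#' sim <- simulate_cohort(sim_params(n_specimens = 400, seed = 7), tx)
#' res <- classify_batch(sim$fusions, tx, default_kb())
#' glance(res)
#' @export
classify_batch <- function(calls, transcripts, kb = default_kb(),
                           min_reads = 5, tkd_regions = default_tkd_regions()) {
  if (is.character(calls)) calls <- read_fusion_calls(calls)
  # accept previously annotated/classified tibbles: derived columns are
  # recomputed, not trusted
  derived <- c("bp5_kind", "bp5_ordinal", "bp5_offset", "bp3_kind",
               "bp3_ordinal", "bp3_offset", "annotation_error", "ntrk_role",
               "ntrk_gene", "end_phase_5p", "start_phase_3p", "frame_status",
               "verdict", "partner_status", "tkd_ok", "reasons",
               "fusion_name", "kb_version")
  calls <- calls[, setdiff(names(calls), derived), drop = FALSE]
  if (!".row" %in% names(calls)) calls$.row <- seq_len(nrow(calls))
  flt <- filter_read_support(calls, min_reads)
  if (nrow(flt$kept) > 0) {
    ann <- annotate_fusions(flt$kept, transcripts)
    failed <- ann[!is.na(ann$annotation_error), , drop = FALSE]
    clean <- ann[is.na(ann$annotation_error), , drop = FALSE]
    classified <- classify_fusions(clean, transcripts, kb, tkd_regions)
    classified <- dplyr::arrange(classified, .data$specimen_id, .data$.row)
  } else {
    failed <- flt$kept
    classified <- classify_fusions(
      annotate_fusions(flt$kept[0, ], transcripts), transcripts, kb, tkd_regions)
  }
  qc <- list(
    n_input = nrow(calls),
    n_removed_read_support = nrow(flt$removed),
    n_annotation_failed = nrow(failed),
    n_classified = nrow(classified),
    min_reads = min_reads,
    kb_version = kb_version(kb),
    verdicts = as.list(table(factor(classified$verdict,
                                    levels = verdict_levels()))))
  structure(list(classified = classified, failed = failed, qc = qc),
            class = "ntrk_classification")
}

#' @export
print.ntrk_classification <- function(x, ...) {
  q <- x$qc
  cat(sprintf(
    "<ntrk_classification> %d calls: %d classified (%s), %d below %d reads, %d failed annotation [KB %s]\n",
    q$n_input, q$n_classified,
    paste(sprintf("%s %d", names(q$verdicts), unlist(q$verdicts)),
          collapse = ", "),
    q$n_removed_read_support, q$min_reads, q$n_annotation_failed,
    q$kb_version))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a classification result
#'
#' @param x An `ntrk_classification` object.
#' @param ... Unused.
#' @return The classified fusion tibble.
#' @export
tidy.ntrk_classification <- function(x, ...) x$classified

#' One-row QC summary of a classification result
#'
#' @param x An `ntrk_classification` object.
#' @param ... Unused.
#' @return One-row tibble of input/filtered/failed/classified counts and
#'   per-verdict totals.
#' @export
glance.ntrk_classification <- function(x, ...) {
  q <- x$qc
  tibble::tibble(
    n_input = q$n_input,
    n_removed_read_support = q$n_removed_read_support,
    n_annotation_failed = q$n_annotation_failed,
    n_classified = q$n_classified,
    n_oncogenic = q$verdicts$ONCOGENIC,
    n_likely_oncogenic = q$verdicts$LIKELY_ONCOGENIC,
    n_vus = q$verdicts$VUS,
    min_reads = q$min_reads,
    kb_version = q$kb_version)
}

#' Write a classification result to disk
#'
#' Emits the classified table as TSV and the QC report as JSON.
#'
#' @param x An `ntrk_classification` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_classification <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cols <- c("specimen_id", "fusion_name", "gene_5p", "gene_3p", "ntrk_gene",
            "verdict", "partner_status", "frame_status", "reasons",
            "kb_version")
  readr::write_tsv(x$classified[, intersect(cols, names(x$classified))],
                   file.path(dir, "classified_fusions.tsv"), progress = FALSE)
  jsonlite::write_json(x$qc, file.path(dir, "qc_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
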