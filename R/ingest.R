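#' Read candidate fusion calls
#'
#' The canonical fusion table is a TSV with columns `specimen_id`, `gene_5p`,
#' `bp_5p`, `gene_3p`, `bp_3p`, `unique_reads` (and optionally `caller_tag`).
#' Breakpoints are accepted as `chrN:pos`, `intronK`, or `exonK` /
#' `exonK+offset` strings; they are kept verbatim here and resolved by
#' [annotate_fusions()]. Parsing and read-support filtering are deliberately
#' separate steps, so sub-threshold rows survive ingestion.
#'
#' @param path Path to a fusion TSV.
#' @return Tibble of fusion calls in file order, with a `.row` column
#'   recording the input row.
#' @export
read_fusion_calls <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    specimen_id = readr::col_character(), gene_5p = readr::col_character(),
    bp_5p = readr::col_character(), gene_3p = readr::col_character(),
    bp_3p = readr::col_character(), unique_reads = readr::col_integer(),
    .default = readr::col_character()), progress = FALSE)
  abort_cols(df, c("specimen_id", "gene_5p", "bp_5p", "gene_3p", "bp_3p",
                   "unique_reads"), "fusion TSV")
  if (!"caller_tag" %in% names(df)) df$caller_tag <- NA_character_
  df$.row <- seq_len(nrow(df))
  bad <- integer(0)
  for (col in c("bp_5p", "bp_3p")) {
    ok <- vapply(df[[col]], function(x) !is.null(parse_breakpoint_string(x)),
                 logical(1))
    bad <- union(bad, which(!ok))
  }
  if (length(bad) > 0) {
    stop(sprintf("unparseable breakpoint string at line(s): %s",
                 paste(sort(bad) + 1L, collapse = ", ")), call. = FALSE)
  }
  if (any(is.na(df$gene_5p) | df$gene_5p == "" |
          is.na(df$gene_3p) | df$gene_3p == "")) {
    stop("fusion calls must name both a 5' and a 3' gene", call. = FALSE)
  }
  if (any(is.na(df$unique_reads) | df$unique_reads < 0)) {
    stop("unique_reads must be a non-negative integer", call. = FALSE)
  }
  df
}

#' Write fusion calls in the canonical TSV dialect
#'
#' @param calls Fusion call tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fusion_calls <- function(calls, path) {
  cols <- c("specimen_id", "gene_5p", "bp_5p", "gene_3p", "bp_3p",
            "unique_reads", "caller_tag")
  readr::write_tsv(calls[, intersect(cols, names(calls))], path, progress = FALSE)
  invisible(path)
}

# "chrN:pos" -> list(kind="genomic", chrom, pos)
# "intronK"  -> list(kind="intron", ordinal=K)
# "exonK" / "exonK+off" -> list(kind="exon", ordinal=K, offset)
parse_breakpoint_string <- function(x) {
  if (is.na(x) || x == "") return(NULL)
  m <- regmatches(x, regexec("^intron([0-9]+)$", x))[[1]]
  if (length(m) > 0) return(list(kind = "intron", ordinal = as.integer(m[2]),
                                 offset = 0L))
  m <- regmatches(x, regexec("^exon([0-9]+)(\\+([0-9]+))?$", x))[[1]]
  if (length(m) > 0) {
    off <- if (m[4] == "") 1L else as.integer(m[4])
    return(list(kind = "exon", ordinal = as.integer(m[2]), offset = off))
  }
  m <- regmatches(x, regexec("^([A-Za-z0-9_.]+):([0-9]+)$", x))[[1]]
  if (length(m) > 0) return(list(kind = "genomic", chrom = m[2],
                                 pos = as.integer(m[3])))
  NULL
}

#' Partition fusion calls by unique read support
#'
#' Candidate fusions qualify when supported by at least `min_reads` unique
#' fusion reads (default 5). The partition is exact and order-preserving,
#' and lowering the threshold can only grow the kept set.
#'
#' @param calls Fusion call tibble.
#' @param min_reads Minimum unique supporting reads (non-negative).
#' @return List with tibbles `kept` and `removed`.
#' @export
filter_read_support <- function(calls, min_reads = 5) {
  stopifnot(min_reads >= 0)
  keep <- calls$unique_reads >= min_reads
  list(kept = calls[keep, , drop = FALSE], removed = calls[!keep, , drop = FALSE])
}

#' Annotate fusion breakpoints against transcript models
#'
#' Resolves both breakpoints of each call to strand-aware descriptors
#' (intron ordinal, or exon ordinal plus offset) and assigns the NTRK role:
#' `3prime` whenever the 3' gene is an NTRK gene (a fusion with NTRK on both
#' sides counts as 3prime, the 5' NTRK acting as an ordinary partner),
#' `5prime` when only the 5' gene is NTRK, otherwise `none`.
#'
#' A gene absent from the transcript set is a hard error; a genomic
#' breakpoint outside its gene's span is recorded in `annotation_error` and
#' the row is excluded from classification but counted in the QC report.
#'
#' @param calls Fusion call tibble (see [read_fusion_calls()]).
#' @param transcripts Transcript tibble.
#' @return The calls with descriptor columns `bp5_kind`, `bp5_ordinal`,
#'   `bp5_offset`, `bp3_kind`, `bp3_ordinal`, `bp3_offset`, plus
#'   `ntrk_role`, `ntrk_gene`, and `annotation_error` (`NA` when clean).
#' @export
annotate_fusions <- function(calls, transcripts) {
  genes <- unique(c(calls$gene_5p, calls$gene_3p))
  missing <- setdiff(genes, unique(transcripts$gene))
  if (length(missing) > 0) {
    stop(sprintf("gene(s) not present in transcript models: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  resolve <- function(gene, bp_string) {
    parsed <- parse_breakpoint_string(bp_string)
    if (is.null(parsed)) stop(sprintf("unparseable breakpoint '%s'", bp_string))
    if (parsed$kind == "genomic") {
      d <- locate_breakpoint(transcripts, gene, parsed$pos)
      return(list(kind = d$kind, ordinal = d$ordinal, offset = d$exon_offset))
    }
    ex <- gene_exons(transcripts, gene)
    n <- nrow(ex)
    max_ord <- if (parsed$kind == "intron") n - 1L else n
    if (parsed$ordinal < 1 || parsed$ordinal > max_ord) {
      stop(sprintf("%s has no %s %d", gene, parsed$kind, parsed$ordinal))
    }
    if (parsed$kind == "exon" && parsed$offset > ex$exon_len[parsed$ordinal]) {
      stop(sprintf("%s exon %d: offset %d outside exon", gene, parsed$ordinal,
                   parsed$offset))
    }
    parsed[c("kind", "ordinal", "offset")]
  }
  out <- purrr::pmap(
    list(calls$gene_5p, calls$bp_5p, calls$gene_3p, calls$bp_3p),
    function(g5, b5, g3, b3) {
      res <- tryCatch({
        d5 <- resolve(g5, b5); d3 <- resolve(g3, b3)
        tibble::tibble(bp5_kind = d5$kind, bp5_ordinal = d5$ordinal,
                       bp5_offset = d5$offset, bp3_kind = d3$kind,
                       bp3_ordinal = d3$ordinal, bp3_offset = d3$offset,
                       annotation_error = NA_character_)
      }, error = function(e) {
        tibble::tibble(bp5_kind = NA_character_, bp5_ordinal = NA_integer_,
                       bp5_offset = NA_integer_, bp3_kind = NA_character_,
                       bp3_ordinal = NA_integer_, bp3_offset = NA_integer_,
                       annotation_error = conditionMessage(e))
      })
      res
    })
  ann <- dplyr::bind_cols(calls, dplyr::bind_rows(out))
  ann$ntrk_role <- dplyr::case_when(
    ann$gene_3p %in% ntrk_genes() ~ "3prime",
    ann$gene_5p %in% ntrk_genes() ~ "5prime",
    TRUE ~ "none")
  ann$ntrk_gene <- dplyr::case_when(
    ann$ntrk_role == "3prime" ~ ann$gene_3p,
    ann$ntrk_role == "5prime" ~ ann$gene_5p,
    TRUE ~ NA_character_)
  ann
}

#' Read fusion calls from a VCF with breakend (BND) records
#'
#' Thin adapter for caller output: `SVTYPE=BND` records are paired by their
#' `MATEID`, each pair becomes one fusion call, and genes are assigned by
#' locating each breakend within the transcript models. The mate whose ALT
#' carries its base *before* the bracket (`t[...[` / `t]...]`) continues 5'
#' into the junction and is taken as the 5' side. Unpaired breakends are
#' dropped and counted in the `qc` attribute of the result.
#'
#' @param path Path to a VCF file.
#' @param transcripts Transcript tibble used to assign genes.
#' @param support_field INFO key holding the unique supporting read count
#'   (default `"SR"`); records without it get 0 reads.
#' @return Fusion call tibble (same shape as [read_fusion_calls()]) with a
#'   `qc` attribute listing `n_bnd`, `n_paired`, `n_unpaired`.
#' @export
read_fusion_vcf <- function(path, transcripts, support_field = "SR") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(vcf),
                                         stringsAsFactors = FALSE))
  info_get <- function(key) vcfR::extract.info(vcf, element = key)
  svtype <- info_get("SVTYPE")
  bnd <- which(!is.na(svtype) & svtype == "BND")
  mateid <- info_get("MATEID")
  support <- suppressWarnings(as.integer(info_get(support_field)))
  ids <- fix$ID
  used <- rep(FALSE, length(ids))
  rows <- list()
  n_unpaired <- 0L
  for (i in bnd) {
    if (used[i]) next
    j <- match(mateid[i], ids)
    if (is.na(j) || !(j %in% bnd)) { n_unpaired <- n_unpaired + 1L; next }
    used[c(i, j)] <- TRUE
    # 5' side: ALT of form base-then-bracket
    five <- if (grepl("^[ACGTN]+[][]", fix$ALT[i])) c(i, j) else c(j, i)
    locate_gene <- function(k) {
      pos <- as.integer(fix$POS[k])
      hit <- transcripts |>
        dplyr::group_by(.data$gene) |>
        dplyr::summarise(chrom = dplyr::first(.data$chrom),
                         lo = min(.data$start), hi = max(.data$end),
                         .groups = "drop") |>
        dplyr::filter(.data$chrom == fix$CHROM[k], .data$lo <= pos,
                      .data$hi >= pos)
      if (nrow(hit) == 0) NA_character_ else hit$gene[1]
    }
    g5 <- locate_gene(five[1]); g3 <- locate_gene(five[2])
    reads <- support[five[1]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      specimen_id = sub("_[12]$", "", fix$ID[five[1]]),
      gene_5p = g5,
      bp_5p = paste0(fix$CHROM[five[1]], ":", fix$POS[five[1]]),
      gene_3p = g3,
      bp_3p = paste0(fix$CHROM[five[2]], ":", fix$POS[five[2]]),
      unique_reads = ifelse(is.na(reads), 0L, reads),
      caller_tag = "vcf_bnd")
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else tibble::tibble(
    specimen_id = character(), gene_5p = character(), bp_5p = character(),
    gene_3p = character(), bp_3p = character(), unique_reads = integer(),
    caller_tag = character())
  dropped <- is.na(out$gene_5p) | is.na(out$gene_3p)
  attr(out, "qc") <- list(n_bnd = length(bnd), n_paired = nrow(out),
                          n_unpaired = n_unpaired,
                          n_unassigned_gene = sum(dropped))
  out$.row <- seq_len(nrow(out))
  out
}
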