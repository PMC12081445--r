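#' Transcript models for fusion breakpoint interpretation
#'
#' A transcript set is a tibble with one row per exon and the columns
#' `gene`, `chrom`, `strand`, `exon_number`, `start`, `end`, `cds_start`,
#' `cds_end`, carrying a `domains` attribute (tibble with `gene`, `domain`,
#' `first_exon`, `last_exon`). Coordinates are 1-based, fully closed.
#' Exon numbering is in transcription order: exon 1 is the 5'-most exon of
#' the mRNA, which on the minus strand is the genomically rightmost exon.
#' `cds_start`/`cds_end` give the genomic sub-interval of the exon that is
#' coding (both `NA` for fully untranslated exons).
#'
#' @name transcripts
NULL

new_transcripts <- function(exons, domains = NULL) {
  exons <- tibble::as_tibble(exons)
  abort_cols(exons, c("gene", "chrom", "strand", "exon_number",
                      "start", "end", "cds_start", "cds_end"),
             "transcript table")
  exons <- dplyr::arrange(exons, .data$gene, .data$exon_number)
  domains <- if (is.null(domains)) {
    tibble::tibble(gene = character(), domain = character(),
                   first_exon = integer(), last_exon = integer())
  } else {
    tibble::as_tibble(domains)
  }
  attr(exons, "domains") <- domains
  class(exons) <- c("trk_transcripts", class(exons))
  validate_transcripts(exons)
  exons
}

#' Validate a transcript set
#'
#' Checks the structural invariants every downstream operation relies on:
#' consecutive 1..n exon numbering per gene, non-overlapping exons laid out
#' in transcription order consistent with the strand, and CDS sub-intervals
#' contained in their exons.
#'
#' @param transcripts A transcript tibble (see [transcripts]).
#' @param require_cds_multiple If `TRUE`, additionally require each gene's
#'   total CDS length to be a positive multiple of 3 (appropriate when the
#'   annotation includes the stop codon).
#' @return The input, invisibly; errors describe the offending gene.
#' @export
validate_transcripts <- function(transcripts, require_cds_multiple = FALSE) {
  for (g in unique(transcripts$gene)) {
    ex <- transcripts[transcripts$gene == g, ]
    n <- nrow(ex)
    if (n == 0) stop(sprintf("gene %s has zero exons", g), call. = FALSE)
    if (!identical(sort(ex$exon_number), seq_len(n))) {
      stop(sprintf("gene %s: exon numbers are not consecutive 1..%d", g, n),
           call. = FALSE)
    }
    if (length(unique(ex$strand)) != 1 || !unique(ex$strand) %in% c("+", "-")) {
      stop(sprintf("gene %s: strand must be a single '+' or '-'", g), call. = FALSE)
    }
    if (any(ex$start > ex$end)) {
      stop(sprintf("gene %s: exon with start > end", g), call. = FALSE)
    }
    ex <- ex[order(ex$exon_number), ]
    # transcription order: + strand ascending genomic, - strand descending
    ord <- if (unique(ex$strand) == "+") order(ex$start) else order(-ex$start)
    if (!identical(ex$exon_number[ord], seq_len(n))) {
      stop(sprintf("gene %s: exon numbering does not follow transcription order", g),
           call. = FALSE)
    }
    sorted <- ex[order(ex$start), ]
    if (n > 1 && any(sorted$start[-1] <= sorted$end[-n])) {
      stop(sprintf("gene %s: overlapping exons", g), call. = FALSE)
    }
    has_cds <- !is.na(ex$cds_start)
    if (any(has_cds != !is.na(ex$cds_end))) {
      stop(sprintf("gene %s: cds_start/cds_end must be both set or both NA", g),
           call. = FALSE)
    }
    bad <- has_cds & (ex$cds_start < ex$start | ex$cds_end > ex$end |
                        ex$cds_start > ex$cds_end)
    if (any(bad)) {
      stop(sprintf("gene %s: CDS not contained in exon", g), call. = FALSE)
    }
    if (require_cds_multiple) {
      total <- sum(ifelse(has_cds, ex$cds_end - ex$cds_start + 1, 0L))
      if (total == 0 || total %% 3 != 0) {
        stop(sprintf("gene %s: total CDS length %d is not a positive multiple of 3",
                     g, total), call. = FALSE)
      }
    }
  }
  invisible(transcripts)
}

#' Domain annotation of a transcript set
#'
#' @param transcripts A transcript tibble.
#' @return Tibble with `gene`, `domain`, `first_exon`, `last_exon`.
#' @export
transcript_domains <- function(transcripts) {
  attr(transcripts, "domains") %||%
    tibble::tibble(gene = character(), domain = character(),
                   first_exon = integer(), last_exon = integer())
}

# Exons of one gene in transcription order, with derived per-exon geometry:
# exon length, CDS length, transcript-orientation CDS offsets (1-based within
# the exon; NA when non-coding) and the cumulative CDS length upstream.
gene_exons <- function(transcripts, gene) {
  ex <- transcripts[transcripts$gene == gene, ]
  if (nrow(ex) == 0) {
    stop(sprintf("gene %s not found in transcript set", gene), call. = FALSE)
  }
  ex <- ex[order(ex$exon_number), ]
  ex$exon_len <- ex$end - ex$start + 1L
  has_cds <- !is.na(ex$cds_start)
  ex$cds_len <- ifelse(has_cds, ex$cds_end - ex$cds_start + 1L, 0L)
  plus <- unique(ex$strand) == "+"
  ex$cds_off_start <- ifelse(has_cds,
    if (plus) ex$cds_start - ex$start + 1L else ex$end - ex$cds_end + 1L,
    NA_integer_)
  ex$cds_off_end <- ifelse(has_cds,
    if (plus) ex$cds_end - ex$start + 1L else ex$end - ex$cds_start + 1L,
    NA_integer_)
  ex$cum_cds_before <- cumsum(dplyr::lag(ex$cds_len, default = 0L))
  ex
}

#' Reading-frame phase of an exon
#'
#' The phase of an exon is the cumulative CDS length of all upstream exons
#' modulo 3: the codon position at which the exon's first coding base enters
#' the reading frame. Two breakpoints are frame-compatible when their phases
#' match.
#'
#' @param transcripts A transcript tibble.
#' @param gene Gene symbol.
#' @param exon_number Integer vector of 1-based exon ordinals.
#' @return Integer vector of phases in 0:2; `NA` for exons with no CDS and no
#'   upstream CDS (non-coding).
#' @examples
#' tx <- simulate_transcriptome(n_novel_partners = 2, seed = 1)
#' exon_phase(tx, "NTRK1", 1:3)
#' @export
exon_phase <- function(transcripts, gene, exon_number) {
  ex <- gene_exons(transcripts, gene)
  if (any(exon_number < 1 | exon_number > nrow(ex))) {
    stop(sprintf("gene %s has no exon %s", gene,
                 paste(setdiff(exon_number, ex$exon_number), collapse = ",")),
         call. = FALSE)
  }
  phase <- ex$cum_cds_before[exon_number] %% 3L
  noncoding <- ex$cds_len[exon_number] == 0L & ex$cum_cds_before[exon_number] == 0L
  phase[noncoding] <- NA_integer_
  as.integer(phase)
}

#' Locate a genomic position within a transcript
#'
#' Maps a genomic coordinate to a strand-aware breakpoint descriptor: either
#' inside exon `j` (with a 1-based offset in transcript orientation) or in
#' intron `i`, the gap between exons `i` and `i + 1` of the mRNA.
#'
#' @param transcripts A transcript tibble.
#' @param gene Gene symbol.
#' @param position Genomic coordinate (1-based).
#' @return One-row tibble: `gene`, `kind` ("exon"/"intron"), `ordinal`,
#'   `exon_offset` (0 for introns), `genomic_position`.
#' @export
locate_breakpoint <- function(transcripts, gene, position) {
  ex <- gene_exons(transcripts, gene)
  span <- c(min(ex$start), max(ex$end))
  if (position < span[1] || position > span[2]) {
    stop(sprintf("position %d is outside the span of %s (%d-%d)",
                 position, gene, span[1], span[2]), call. = FALSE)
  }
  hit <- which(position >= ex$start & position <= ex$end)
  plus <- unique(ex$strand) == "+"
  if (length(hit) == 1) {
    off <- if (plus) position - ex$start[hit] + 1L else ex$end[hit] - position + 1L
    return(tibble::tibble(gene = gene, kind = "exon",
                          ordinal = ex$exon_number[hit],
                          exon_offset = as.integer(off),
                          genomic_position = as.integer(position)))
  }
  # intronic: intron i lies between exon i and exon i+1 in transcript order
  n <- nrow(ex)
  for (i in seq_len(n - 1)) {
    gap <- if (plus) c(ex$end[i] + 1L, ex$start[i + 1] - 1L)
           else c(ex$end[i + 1] + 1L, ex$start[i] - 1L)
    if (position >= gap[1] && position <= gap[2]) {
      return(tibble::tibble(gene = gene, kind = "intron", ordinal = i,
                            exon_offset = 0L,
                            genomic_position = as.integer(position)))
    }
  }
  stop(sprintf("position %d could not be placed within %s", position, gene),
       call. = FALSE)
}

#' Genomic coordinate of a breakpoint descriptor
#'
#' Inverse of [locate_breakpoint()]: an exonic descriptor maps to its exact
#' base; an intronic descriptor maps to a position inside the intron
#' (midpoint by default).
#'
#' @param transcripts A transcript tibble.
#' @param gene Gene symbol.
#' @param kind "exon" or "intron".
#' @param ordinal Exon or intron ordinal (transcript order).
#' @param exon_offset 1-based offset within the exon (exonic only).
#' @param intron_at "mid" for the intron midpoint, "random" for a uniform
#'   draw within the intron.
#' @return Integer genomic coordinate.
#' @export
breakpoint_genomic <- function(transcripts, gene, kind, ordinal, exon_offset = 1L,
                               intron_at = c("mid", "random")) {
  intron_at <- match.arg(intron_at)
  ex <- gene_exons(transcripts, gene)
  plus <- unique(ex$strand) == "+"
  n <- nrow(ex)
  if (kind == "exon") {
    if (ordinal < 1 || ordinal > n) stop(sprintf("%s has no exon %d", gene, ordinal))
    if (exon_offset < 1 || exon_offset > ex$exon_len[ordinal]) {
      stop(sprintf("%s exon %d: offset %d outside exon", gene, ordinal, exon_offset))
    }
    pos <- if (plus) ex$start[ordinal] + exon_offset - 1L
           else ex$end[ordinal] - exon_offset + 1L
    return(as.integer(pos))
  }
  if (ordinal < 1 || ordinal > n - 1) stop(sprintf("%s has no intron %d", gene, ordinal))
  gap <- if (plus) c(ex$end[ordinal] + 1L, ex$start[ordinal + 1] - 1L)
         else c(ex$end[ordinal + 1] + 1L, ex$start[ordinal] - 1L)
  if (gap[1] > gap[2]) stop(sprintf("%s intron %d has zero length", gene, ordinal))
  pos <- if (intron_at == "mid") (gap[1] + gap[2]) %/% 2L
         else sample(seq(gap[1], gap[2]), 1L)
  as.integer(pos)
}

#' Read transcript models from a GTF file or a simplified exon table
#'
#' The simplified TSV dialect has columns `gene`, `chrom`, `strand`,
#' `exon_number`, `start`, `end`, `cds_start`, `cds_end` and optionally
#' `domain` (a domain name attached to each exon it spans). The GTF dialect
#' (Ensembl-style `gene_id`/`transcript_id`/`exon_number` attributes, `CDS`
#' features, optional `domain` features with `domain_id`/`domain_first_exon`/
#' `domain_last_exon` attributes) yields identical content for equivalent
#' input. When a gene carries several transcripts in a GTF, the transcript
#' with the longest total CDS is kept and a message records the choice.
#'
#' @param path File path.
#' @param format "auto" (by extension), "tsv", or "gtf".
#' @return A transcript tibble (see [transcripts]).
#' @export
read_transcripts <- function(path, format = c("auto", "tsv", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "tsv"
  }
  if (format == "tsv") read_transcripts_tsv(path) else read_transcripts_gtf(path)
}

read_transcripts_tsv <- function(path) {
  # parse issues are re-reported as errors below, so silence readr's warning
  df <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), chrom = readr::col_character(),
    strand = readr::col_character(), exon_number = readr::col_integer(),
    start = readr::col_integer(), end = readr::col_integer(),
    cds_start = readr::col_integer(), cds_end = readr::col_integer(),
    .default = readr::col_character()), progress = FALSE))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop(sprintf("malformed transcript record at line %d: expected %s",
                 probs$row[1], probs$expected[1]), call. = FALSE)
  }
  abort_cols(df, c("gene", "chrom", "strand", "exon_number", "start", "end",
                   "cds_start", "cds_end"), "transcript TSV")
  domains <- NULL
  if ("domain" %in% names(df)) {
    domains <- df |>
      dplyr::filter(!is.na(.data$domain), .data$domain != "") |>
      dplyr::group_by(.data$gene, .data$domain) |>
      dplyr::summarise(first_exon = min(.data$exon_number),
                       last_exon = max(.data$exon_number), .groups = "drop")
    df$domain <- NULL
  }
  new_transcripts(df, domains)
}

read_transcripts_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GTF requires the rtracklayer package", call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- as.data.frame(gr)
  gene_of <- function(m) if ("gene_name" %in% names(m) && !all(is.na(m$gene_name)))
    m$gene_name else m$gene_id
  meta$.gene <- gene_of(meta)
  exons <- meta[meta$type == "exon", ]
  cds <- meta[meta$type == "CDS", ]
  if (nrow(exons) == 0) stop("GTF contains no exon features", call. = FALSE)
  out <- list(); doms <- list()
  for (g in unique(exons$.gene)) {
    gex <- exons[exons$.gene == g, ]
    gcds <- cds[cds$.gene == g, ]
    txs <- unique(gex$transcript_id)
    if (length(txs) > 1) {
      cds_len <- vapply(txs, function(t) {
        sum(gcds$width[gcds$transcript_id == t])
      }, numeric(1))
      keep <- txs[which.max(cds_len)]
      message(sprintf("gene %s: %d transcripts in GTF; keeping %s (longest CDS)",
                      g, length(txs), keep))
      gex <- gex[gex$transcript_id == keep, ]
      gcds <- gcds[gcds$transcript_id == keep, ]
    }
    if (nrow(gex) == 0) stop(sprintf("gene %s has zero exons", g), call. = FALSE)
    strand <- as.character(gex$strand[1])
    if ("exon_number" %in% names(gex) && !all(is.na(gex$exon_number))) {
      num <- as.integer(gex$exon_number)
    } else {
      num <- if (strand == "+") rank(gex$start) else rank(-gex$start)
    }
    cds_start <- rep(NA_integer_, nrow(gex))
    cds_end <- rep(NA_integer_, nrow(gex))
    if (nrow(gcds) > 0) {
      for (i in seq_len(nrow(gex))) {
        ov <- gcds[gcds$start <= gex$end[i] & gcds$end >= gex$start[i], ]
        if (nrow(ov) > 0) {
          cds_start[i] <- max(min(ov$start), gex$start[i])
          cds_end[i] <- min(max(ov$end), gex$end[i])
        }
      }
    }
    out[[g]] <- tibble::tibble(
      gene = g, chrom = as.character(gex$seqnames[1]), strand = strand,
      exon_number = num, start = as.integer(gex$start),
      end = as.integer(gex$end), cds_start = cds_start, cds_end = cds_end)
    gdom <- meta[meta$type == "domain" & meta$.gene == g, ]
    if (nrow(gdom) > 0) {
      doms[[g]] <- tibble::tibble(
        gene = g, domain = as.character(gdom$domain_id),
        first_exon = as.integer(gdom$domain_first_exon),
        last_exon = as.integer(gdom$domain_last_exon))
    }
  }
  new_transcripts(dplyr::bind_rows(out), dplyr::bind_rows(doms))
}

#' Write transcript models in the simplified TSV dialect
#'
#' @param transcripts A transcript tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts_tsv <- function(transcripts, path) {
  doms <- transcript_domains(transcripts)
  df <- tibble::as_tibble(transcripts)
  df$domain <- NA_character_
  for (i in seq_len(nrow(doms))) {
    sel <- df$gene == doms$gene[i] &
      df$exon_number >= doms$first_exon[i] & df$exon_number <= doms$last_exon[i]
    df$domain[sel] <- doms$domain[i]
  }
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Write transcript models as GTF
#'
#' Emits `exon` and `CDS` features with Ensembl-style attributes, plus a
#' non-standard `domain` feature per annotated domain so the two dialects
#' round-trip the same content.
#'
#' @param transcripts A transcript tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts_gtf <- function(transcripts, path) {
  lines <- character(0)
  doms <- transcript_domains(transcripts)
  for (g in unique(transcripts$gene)) {
    ex <- gene_exons(transcripts, g)
    tx <- paste0(g, ".t1")
    attr_str <- function(extra = "") sprintf(
      'gene_id "%s"; transcript_id "%s";%s', g, tx, extra)
    for (i in seq_len(nrow(ex))) {
      lines <- c(lines, paste(ex$chrom[i], "trkfusions", "exon", ex$start[i],
        ex$end[i], ".", ex$strand[i], ".",
        attr_str(sprintf(' exon_number "%d";', ex$exon_number[i])), sep = "\t"))
      if (!is.na(ex$cds_start[i])) {
        lines <- c(lines, paste(ex$chrom[i], "trkfusions", "CDS", ex$cds_start[i],
          ex$cds_end[i], ".", ex$strand[i], "0",
          attr_str(sprintf(' exon_number "%d";', ex$exon_number[i])), sep = "\t"))
      }
    }
    gd <- doms[doms$gene == g, ]
    for (i in seq_len(nrow(gd))) {
      lines <- c(lines, paste(ex$chrom[1], "trkfusions", "domain",
        min(ex$start), max(ex$end), ".", ex$strand[1], ".",
        attr_str(sprintf(' domain_id "%s"; domain_first_exon "%d"; domain_last_exon "%d";',
                         gd$domain[i], gd$first_exon[i], gd$last_exon[i])),
        sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
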