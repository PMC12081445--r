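#' Fusion-partner knowledge base
#'
#' The registry of known 5' fusion partners of the NTRK genes, the lookup
#' behind the oncogenic rule. Knownness is pair-level: a partner curated for
#' one NTRK gene is still *novel* for the others (EML4, for instance, is a
#' curated partner of both NTRK1 and NTRK3 and carries one entry per pair).
#' Entries are either `canonical` (reported in COSMIC/GENIE or more than
#' three studies) or `clinical_validity` (identified in the trials behind
#' the TRK-inhibitor approvals); the classifier treats both as known.
#'
#' The default table is versioned data shipped with the package, and every
#' classification records the version it used, because the
#' oncogenic/likely-oncogenic boundary moves as curation grows.
#'
#' @param path Path to a KB TSV with columns `partner_gene`, `ntrk_gene`,
#'   `evidence_class`, `source_tags`. A leading `# version: <id>` comment
#'   line, when present, sets the KB version.
#' @return Tibble of partner entries with a `kb_version` attribute.
#' @export
read_kb <- function(path) {
  first <- readLines(path, n = 1)
  version <- if (grepl("^#\\s*version:", first)) {
    trimws(sub("^#\\s*version:", "", first))
  } else {
    "unversioned"
  }
  kb <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    partner_gene = readr::col_character(), ntrk_gene = readr::col_character(),
    evidence_class = readr::col_character(),
    source_tags = readr::col_character()), progress = FALSE)
  abort_cols(kb, c("partner_gene", "ntrk_gene", "evidence_class"), "KB table")
  bad <- !kb$evidence_class %in% c("canonical", "clinical_validity")
  if (any(bad)) {
    stop(sprintf("invalid evidence_class: %s",
                 paste(unique(kb$evidence_class[bad]), collapse = ", ")),
         call. = FALSE)
  }
  dup <- duplicated(kb[, c("partner_gene", "ntrk_gene")])
  if (any(dup)) {
    warning(sprintf("KB contains %d duplicate (partner, NTRK) entries; keeping first",
                    sum(dup)), call. = FALSE)
    kb <- kb[!dup, ]
  }
  attr(kb, "kb_version") <- version
  kb
}

#' The bundled default knowledge base
#'
#' Contains the 18 curated (partner, NTRK) pairs: LMNA, PEAR1, RABGAP1L,
#' TP53, EML4, TPM3, LGR6, TPR and IRF2BP2 for NTRK1; GKAP1, SQSTM1 and GNAQ
#' for NTRK2; SASH1, ETV6, EML4, ARNT2, SQSTM1 and TARSL2 for NTRK3.
#'
#' @return Tibble of partner entries with a `kb_version` attribute.
#' @export
default_kb <- function() {
  read_kb(system.file("extdata", "ntrk_partner_kb.tsv",
                      package = "trkfusions", mustWork = TRUE))
}

#' Version identifier of a knowledge base
#'
#' @param kb A KB tibble from [read_kb()].
#' @return Character scalar.
#' @export
kb_version <- function(kb) attr(kb, "kb_version") %||% "unversioned"

#' Knownness of a (partner, NTRK) pair
#'
#' Exact pair lookup: a partner known for a different NTRK gene returns
#' "novel". Vectorised over `partner_gene`/`ntrk_gene`.
#'
#' @param kb A KB tibble.
#' @param partner_gene Character vector of 5' partner symbols.
#' @param ntrk_gene Character vector of NTRK gene symbols.
#' @return Character vector: "known_canonical", "known_clinical_validity",
#'   or "novel".
#' @examples
#' kb <- default_kb()
#' partner_status(kb, c("LMNA", "LMNA", "HMCN1"), c("NTRK1", "NTRK2", "NTRK1"))
#' @export
partner_status <- function(kb, partner_gene, ntrk_gene) {
  if (!all(ntrk_gene %in% ntrk_genes())) {
    stop("ntrk_gene must be one of NTRK1/NTRK2/NTRK3", call. = FALSE)
  }
  key <- paste(partner_gene, ntrk_gene, sep = "\r")
  kb_key <- paste(kb$partner_gene, kb$ntrk_gene, sep = "\r")
  idx <- match(key, kb_key)
  out <- rep("novel", length(key))
  hit <- !is.na(idx)
  out[hit] <- paste0("known_", kb$evidence_class[idx[hit]])
  out
}
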