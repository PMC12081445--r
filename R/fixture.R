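#' Published-count fixture cohort
#'
#' A deterministic, synthetic case-level reconstruction of a 19,591-specimen
#' pan-solid-tumour fusion-testing cohort, built so that every published
#' aggregate count is reproduced exactly when the reconstruction is fed
#' through the cohort analytics: 69 fusion-positive specimens carrying 73
#' oncogenic or likely oncogenic fusions among 19,531 specimens passing RNA
#' QC (19,591 submitted; recurrence cohort percentages use the submitted
#' total); per-type positives 18/7,630 (NSCLC), 9/1,423 (breast), 4/423
#' (head and neck), 3/157 (glioblastoma), 1/76 (small intestine), 1/514
#' (uterine); the eight recurrent fusions (ETV6-NTRK3 x5, TPM3-NTRK1 x3,
#' LMNA-NTRK1 x3, EML4-NTRK3/TPR-NTRK1/PEAR1-NTRK1/IRF2BP2-NTRK1/KANK1-NTRK3
#' x2); TP53 co-altered in 35, ARID1A and KRAS in 9, NOTCH1 in 7; 59
#' specimens with an SNV/indel, 20 with a CNV, 18 with a non-NTRK fusion, 20
#' with a co-occurring driver (11 of 18 NSCLC); 6 of 12 colorectal/
#' small-intestine positives MSI-H against 136/2,064 negatives; and group
#' TMB/PD-L1 medians of 1.1 vs 5.4 and 0 vs 10 (head and neck), 7.8 vs 6.2
#' and 20 vs 0 (colorectal).
#'
#' Quantities the published tables do not pin down (per-type totals outside
#' the listed types, the identity of specimens sharing an alteration, exact
#' non-median biomarker values) are fixed here once as realistic choices;
#' the constructor asserts every published count before returning.
#'
#' @return List with `cohort` (specimen tibble, RNA-passed specimens),
#'   `classified` (classified fusion tibble), `flags` (positivity flags),
#'   and `counts` (named list of the published numerators/denominators,
#'   including `n_submitted` = 19591 and `n_rna_pass` = 19531).
#' @export
paper_fixture <- function() {
  types <- tibble::tribble(
    ~tumor_type,       ~code,  ~n_total, ~n_positive,
    "NSCLC",            "LU",      7630,          18,
    "breast",           "BR",      1423,           9,
    "head and neck",    "HN",       423,           4,
    "glioblastoma",     "GB",       157,           3,
    "small intestine",  "SI",        76,           1,
    "uterine",          "UT",       514,           1,
    "colorectal",       "CR",      2000,          11,
    "thyroid",          "TH",       600,           1,
    "sarcoma",          "SA",       700,           2,
    "prostate",         "PR",       900,           1,
    "ovarian",          "OV",       800,           2,
    "unknown primary",  "UP",       500,           1,
    "pancreatic",       "PA",       400,           1,
    "esophageal",       "ES",       300,           1,
    "other",            "OT",      3108,          13)
  stopifnot(sum(types$n_total) == 19531, sum(types$n_positive) == 69)

  pid <- function(code, i) sprintf("%s-P%02d", code, i)
  p <- function(code, i) pid(code, i)  # shorthand for assignment tables

  # ---- classified fusions (73 rows over 69 specimens) ----------------------
  onc <- "ONCOGENIC"; lik <- "LIKELY_ONCOGENIC"
  rec <- tibble::tribble(
    ~specimen_id,  ~gene_5p,  ~ntrk_gene, ~verdict,
    p("HN", 1),    "ETV6",    "NTRK3",    onc,
    p("HN", 2),    "ETV6",    "NTRK3",    onc,
    p("HN", 3),    "ETV6",    "NTRK3",    onc,
    p("HN", 4),    "ETV6",    "NTRK3",    onc,
    p("TH", 1),    "ETV6",    "NTRK3",    onc,
    p("BR", 1),    "TPM3",    "NTRK1",    onc,
    p("SI", 1),    "TPM3",    "NTRK1",    onc,
    p("UP", 1),    "TPM3",    "NTRK1",    onc,
    p("CR", 1),    "LMNA",    "NTRK1",    onc,
    p("CR", 2),    "LMNA",    "NTRK1",    onc,
    p("LU", 1),    "LMNA",    "NTRK1",    onc,
    p("CR", 3),    "EML4",    "NTRK3",    onc,
    p("SA", 1),    "EML4",    "NTRK3",    onc,
    p("CR", 4),    "TPR",     "NTRK1",    onc,
    p("CR", 5),    "TPR",     "NTRK1",    onc,
    p("PR", 1),    "PEAR1",   "NTRK1",    onc,
    p("SA", 2),    "PEAR1",   "NTRK1",    onc,
    p("BR", 2),    "IRF2BP2", "NTRK1",    onc,
    p("LU", 2),    "IRF2BP2", "NTRK1",    onc,
    p("OV", 1),    "KANK1",   "NTRK3",    lik,
    p("OV", 2),    "KANK1",   "NTRK3",    lik)
  known_single <- tibble::tribble(
    ~specimen_id, ~gene_5p,   ~ntrk_gene,
    p("LU", 3),   "RABGAP1L", "NTRK1",
    p("LU", 4),   "TP53",     "NTRK1",
    p("BR", 3),   "LGR6",     "NTRK1",
    p("CR", 6),   "EML4",     "NTRK1",
    p("GB", 1),   "GKAP1",    "NTRK2",
    p("OT", 1),   "SQSTM1",   "NTRK2",
    p("ES", 1),   "GNAQ",     "NTRK2",
    p("OT", 2),   "SASH1",    "NTRK3",
    p("CR", 7),   "ARNT2",    "NTRK3",
    p("UT", 1),   "SQSTM1",   "NTRK3",
    p("OT", 3),   "TARSL2",   "NTRK3") |>
    dplyr::mutate(verdict = onc)
  # 41 novel partners: 21 fused to NTRK2, 10 to NTRK1, 10 to NTRK3
  novel_single <- tibble::tribble(
    ~specimen_id, ~gene_5p,    ~ntrk_gene,
    p("LU", 5),   "PRKACA",    "NTRK2",
    p("LU", 6),   "SLC6A6",    "NTRK2",
    p("LU", 7),   "KRT5",      "NTRK2",
    p("LU", 8),   "HMSD",      "NTRK2",
    p("LU", 9),   "SERPINB8",  "NTRK2",
    p("LU", 10),  "ZNF98",     "NTRK2",
    p("LU", 11),  "CTSA",      "NTRK2",
    p("LU", 12),  "DYRK1A",    "NTRK2",
    p("LU", 13),  "ASTN2",     "NTRK2",
    p("LU", 14),  "MSANTD3",   "NTRK2",
    p("LU", 15),  "NOVB01",    "NTRK2",
    p("LU", 16),  "NOVB02",    "NTRK2",
    p("LU", 17),  "HMCN1",     "NTRK1",
    p("LU", 18),  "LRRC16A",   "NTRK1",
    p("BR", 4),   "ERBB2",     "NTRK3",
    p("BR", 5),   "FAM174B",   "NTRK3",
    p("BR", 6),   "PIAS1",     "NTRK3",
    p("BR", 7),   "FAM227B",   "NTRK1",
    p("BR", 8),   "MKKS",      "NTRK1",
    p("BR", 9),   "NOVA01",    "NTRK1",
    p("GB", 2),   "NOVB03",    "NTRK2",
    p("GB", 3),   "NOVB04",    "NTRK2",
    p("CR", 8),   "NOVA02",    "NTRK1",
    p("CR", 9),   "NOVA03",    "NTRK1",
    p("CR", 10),  "SETD5",     "NTRK3",
    p("CR", 11),  "SND1",      "NTRK3",
    p("PA", 1),   "FHOD3",     "NTRK3",
    p("OT", 4),   "NOVB05",    "NTRK2",
    p("OT", 4),   "NOVA04",    "NTRK1",
    p("OT", 5),   "NOVB06",    "NTRK2",
    p("OT", 5),   "NOVA05",    "NTRK1",
    p("OT", 6),   "NOVB07",    "NTRK2",
    p("OT", 6),   "INTS2",     "NTRK3",
    p("OT", 7),   "NOVB08",    "NTRK2",
    p("OT", 7),   "AKAP13",    "NTRK3",
    p("OT", 8),   "NOVB09",    "NTRK2",
    p("OT", 9),   "NOVB10",    "NTRK2",
    p("OT", 10),  "NOVB11",    "NTRK2",
    p("OT", 11),  "NOVA06",    "NTRK1",
    p("OT", 12),  "MDM2",      "NTRK3",
    p("OT", 13),  "NOVC01",    "NTRK3") |>
    dplyr::mutate(verdict = lik)
  classified <- dplyr::bind_rows(rec, known_single, novel_single) |>
    dplyr::mutate(gene_3p = .data$ntrk_gene,
                  fusion_name = paste(.data$gene_5p, .data$gene_3p, sep = "-"),
                  ntrk_role = "3prime")
  stopifnot(nrow(classified) == 73,
            dplyr::n_distinct(classified$specimen_id) == 69,
            sum(novel_single$ntrk_gene == "NTRK2") == 21)

  # ---- alteration assignments over the 69 positives ------------------------
  alt <- list()
  add <- function(ids, gene, class) {
    alt[[length(alt) + 1L]] <<- tibble::tibble(
      specimen_id = ids, gene = gene, alteration_class = class,
      known_pathogenic = TRUE)
  }
  lu <- function(i) pid("LU", i); cr <- function(i) pid("CR", i)
  br <- function(i) pid("BR", i); hn <- function(i) pid("HN", i)
  ot <- function(i) pid("OT", i); gb <- function(i) pid("GB", i)
  add(c(sapply(1:18, lu), sapply(1:9, br), sapply(1:4, hn), sapply(1:3, gb),
        pid("SI", 1)), "TP53", "snv_indel")                       # 35
  add(c(sapply(1:5, cr), sapply(1:4, ot)), "ARID1A", "snv_indel") # 9
  add(c(lu(1), lu(2), cr(1), sapply(5:10, ot)), "KRAS", "snv_indel") # 9
  add(c(sapply(11:13, ot), pid("UT", 1), pid("TH", 1), pid("SA", 1),
        pid("SA", 2)), "NOTCH1", "snv_indel")                     # 7
  add(sapply(3:6, lu), "EGFR", "snv_indel")
  add(lu(7), "ALK", "fusion"); add(lu(8), "RET", "fusion")
  add(lu(9), "BRAF", "snv_indel"); add(lu(10), "MET", "snv_indel")
  add(lu(11), "ERBB2", "snv_indel")
  add(c(br(1), br(4)), "PIK3CA", "snv_indel")
  add(c(pid("OV", 1), pid("PR", 1)), "KMT2D", "snv_indel")
  add(cr(1), "RET", "fusion")                     # CCDC6-RET co-driver
  add(c(gb(1), pid("SA", 1), ot(1)), "MDM2", "cnv_amp")
  add(c(pid("PR", 1), gb(2), ot(2)), "PTEN", "cnv_loss")
  add(br(4), "ERBB2", "cnv_amp")                  # HER2+ ERBB2-NTRK3 case
  add(c(sapply(12:17, lu), sapply(8:11, cr), ot(3), ot(4), pid("UP", 1)),
      "CCND1", "cnv_amp")
  add(c(sapply(5:9, br), hn(3), hn(4), sapply(5:10, ot)), "FGFR2", "fusion")
  add(pid("PA", 1), "NRG1", "fusion")
  add(pid("PR", 1), "TBL1XR1", "fusion")
  alt_long <- dplyr::bind_rows(alt)

  # printed aggregate counts must hold before the fixture is released
  by_spec <- function(sel) dplyr::n_distinct(alt_long$specimen_id[sel])
  stopifnot(
    by_spec(alt_long$gene == "TP53") == 35,
    by_spec(alt_long$gene == "ARID1A") == 9,
    by_spec(alt_long$gene == "KRAS") == 9,
    by_spec(alt_long$gene == "NOTCH1") == 7,
    by_spec(alt_long$alteration_class == "snv_indel") == 59,
    by_spec(alt_long$alteration_class %in% c("cnv_amp", "cnv_loss")) == 20,
    by_spec(alt_long$alteration_class == "fusion") == 18,
    by_spec(alt_long$gene %in% default_driver_genes()) == 20)

  # ---- specimen table ------------------------------------------------------
  blocks <- purrr::pmap(types, function(tumor_type, code, n_total, n_positive) {
    ids <- c(pid(code, seq_len(n_positive)),
             sprintf("%s-N%05d", code, seq_len(n_total - n_positive)))
    tibble::tibble(specimen_id = ids, tumor_type = tumor_type,
                   positive = c(rep(TRUE, n_positive),
                                rep(FALSE, n_total - n_positive)))
  })
  cohort <- dplyr::bind_rows(blocks)

  # biomarkers: values chosen so stratum medians equal the published ones
  cohort$tmb <- 5.0
  cohort$tmb[cohort$specimen_id %in% sapply(1:11, cr)] <-
    c(4, 5, 6, 7, 7.5, 7.8, 8, 9, 12, 30, 91.6)
  cohort$tmb[cohort$tumor_type == "colorectal" & !cohort$positive] <-
    rep(c(5.0, 6.2, 7.4), length.out = 1989)
  cohort$tmb[cohort$specimen_id %in% sapply(1:4, hn)] <- c(0.9, 1.1, 1.1, 1.3)
  cohort$tmb[cohort$tumor_type == "head and neck" & !cohort$positive] <-
    rep(c(4.4, 5.4, 6.4), length.out = 419)
  cohort$tmb[cohort$specimen_id == pid("SI", 1)] <- 80

  cohort$pdl1_score <- NA_real_
  cohort$pdl1_score_type <- ifelse(cohort$tumor_type == "NSCLC", "TPS", "CPS")
  cohort$pdl1_score[cohort$tumor_type == "NSCLC" & cohort$positive] <-
    rep(c(0, 25, 75), each = 6)
  cohort$pdl1_score[cohort$tumor_type == "NSCLC" & !cohort$positive] <- 0
  cohort$pdl1_score[cohort$specimen_id %in% sapply(1:4, hn)] <- c(0, 0, 0, 5)
  cohort$pdl1_score[cohort$tumor_type == "head and neck" & !cohort$positive] <-
    rep(c(5, 10, 20), length.out = 419)
  cohort$pdl1_score[cohort$specimen_id %in% sapply(1:11, cr)] <-
    c(0, 0, 10, 15, 18, 20, 25, 30, 40, 60, 80)
  cohort$pdl1_score[cohort$tumor_type == "colorectal" & !cohort$positive] <-
    rep(c(0, 0, 1), length.out = 1989)

  cohort$msi <- "MSS"
  cohort$msi[cohort$specimen_id %in% c(sapply(7:11, cr), pid("SI", 1))] <- "MSI-H"
  crc_si_neg <- which(cohort$tumor_type %in% c("colorectal", "small intestine") &
                        !cohort$positive)
  stopifnot(length(crc_si_neg) == 2064)
  cohort$msi[crc_si_neg[seq_len(136)]] <- "MSI-H"

  # demographics of the positives match the published characteristics table
  cohort$age <- 65
  cohort$sex <- rep(c("male", "female"), length.out = nrow(cohort))
  cohort$stage <- "unknown"
  lu_pos <- cohort$specimen_id %in% sapply(1:18, lu)
  cohort$age[lu_pos] <- c(27, 40, 45, 50, 55, 60, 63, 65, 65, 66, 68, 70, 72,
                          75, 78, 80, 82, 85)
  cohort$sex[lu_pos] <- rep(c("male", "female"), c(8, 10))
  cohort$stage[lu_pos] <- rep(c("<=III", "IV", "unknown"), c(1, 5, 12))
  other_pos <- cohort$positive & !lu_pos
  cohort$age[other_pos] <- round(c(seq(26, 65, length.out = 25), 66,
                                   seq(67, 89, length.out = 25)))
  cohort$sex[other_pos] <- rep(c("male", "female"), c(20, 31))
  cohort$stage[other_pos] <- rep(c("<=III", "IV", "unknown"), c(3, 20, 28))

  alt_nested <- split(alt_long[, c("gene", "alteration_class",
                                   "known_pathogenic")],
                      factor(alt_long$specimen_id,
                             levels = cohort$specimen_id))
  cohort$alterations <- unname(lapply(alt_nested, tibble::as_tibble))
  cohort$positive <- NULL

  flags <- specimen_positivity(classified)
  stopifnot(attr(flags, "n_specimens_positive") == 69,
            attr(flags, "n_fusions_qualifying") == 73)

  counts <- list(
    n_total = 19591L, n_submitted = 19591L, n_rna_pass = 19531L,
    n_positive = 69L,
    n_fusions = 73L, nsclc = c(18L, 7630L), other_solid = c(51L, 11901L),
    glioblastoma = c(3L, 157L), small_intestine = c(1L, 76L),
    head_and_neck = c(4L, 423L), uterine = c(1L, 514L), breast = c(9L, 1423L),
    tp53 = 35L, arid1a = 9L, kras = 9L, notch1 = 7L,
    any_snv = 59L, any_cnv = 20L, any_fusion = 18L, any_driver = 20L,
    nsclc_driver = c(11L, 18L), msi_crc_si = c(6L, 12L),
    kras_nras_braf_wt = c(11L, 12L))
  list(cohort = cohort, classified = classified, flags = flags,
       counts = counts)
}
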