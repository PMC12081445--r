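# small hand-made cohort: 6 specimens, 3 positive, alterations known exactly
mini_cohort <- function() {
  alt <- function(...) tibble::tibble(...)
  tibble::tibble(
    specimen_id = sprintf("M%02d", 1:6),
    tumor_type = c("NSCLC", "NSCLC", "colorectal", "colorectal", "breast",
                   "breast"),
    age = c(60, 70, 50, 55, 65, 40),
    sex = c("male", "female", "female", "male", "female", "female"),
    stage = c("IV", "unknown", "<=III", "IV", "unknown", "IV"),
    tmb = c(12, 3, 8, 6, 4, 2),
    pdl1_score = c(60, 0, 10, 0, 5, NA),
    pdl1_score_type = c("TPS", "TPS", "CPS", "CPS", "CPS", "CPS"),
    msi = c("MSS", "MSS", "MSI-H", "MSS", "MSS", "MSS"),
    alterations = list(
      alt(gene = c("TP53", "KRAS"), alteration_class = c("snv_indel", "snv_indel"),
          known_pathogenic = c(TRUE, TRUE)),
      alt(gene = "MUC16", alteration_class = "snv_indel",
          known_pathogenic = FALSE),
      alt(gene = c("TP53", "MDM2"), alteration_class = c("snv_indel", "cnv_amp"),
          known_pathogenic = c(TRUE, TRUE)),
      alt(gene = character(), alteration_class = character(),
          known_pathogenic = logical()),
      alt(gene = "TP53", alteration_class = "snv_indel",
          known_pathogenic = TRUE),
      alt(gene = character(), alteration_class = character(),
          known_pathogenic = logical())))
}

mini_classified <- function() {
  out <- tibble::tibble(
    specimen_id = c("M01", "M03", "M05", "M05", "M02"),
    gene_5p = c("LMNA", "ETV6", "TPM3", "LMNA", "HMCN1"),
    gene_3p = c("NTRK1", "NTRK3", "NTRK1", "NTRK1", "NTRK1"),
    ntrk_gene = c("NTRK1", "NTRK3", "NTRK1", "NTRK1", "NTRK1"),
    verdict = c("ONCOGENIC", "ONCOGENIC", "ONCOGENIC", "ONCOGENIC", "VUS"))
  out$fusion_name <- paste(out$gene_5p, out$gene_3p, sep = "-")
  out
}

test_that("positivity counts specimens once however many fusions they carry", {
  flags <- specimen_positivity(mini_classified())
  expect_equal(attr(flags, "n_specimens_positive"), 3)
  expect_equal(attr(flags, "n_fusions_qualifying"), 4)
  expect_false(flags$ntrk_positive[flags$specimen_id == "M02"])  # VUS only
})

test_that("prevalence rows sum to the overall row", {
  flags <- specimen_positivity(mini_classified())
  prev <- prevalence_table(mini_cohort(), flags)
  per_type <- prev[prev$tumor_type != "overall", ]
  overall <- prev[prev$tumor_type == "overall", ]
  expect_equal(sum(per_type$n_positive), overall$n_positive)
  expect_equal(sum(per_type$n_total), overall$n_total)
  expect_equal(overall$n_total, 6)
  expect_equal(prev$percent[prev$tumor_type == "NSCLC"],
               round_half_up(100 / 2, 2))
  # a positive specimen missing from the cohort is an error
  expect_error(prevalence_table(mini_cohort()[-1, ], flags), "absent")
})

test_that("recurrence counts distinct specimens and takes the severest verdict", {
  cl <- mini_classified()
  cl <- dplyr::bind_rows(cl, tibble::tibble(
    specimen_id = "M06", gene_5p = "TPM3", gene_3p = "NTRK1",
    ntrk_gene = "NTRK1", verdict = "LIKELY_ONCOGENIC",
    fusion_name = "TPM3-NTRK1"))
  rec <- recurrence_table(cl, n_cohort_total = 6, cohort = mini_cohort())
  tpm3 <- rec[rec$fusion_name == "TPM3-NTRK1", ]
  expect_equal(tpm3$n_specimens, 2)
  expect_equal(tpm3$verdict, "ONCOGENIC")  # severest across carriers
  expect_equal(tpm3$fusion_pct, round_half_up(100 * 2 / 4, 2))
  expect_equal(tpm3$cohort_pct, round_half_up(100 * 2 / 6, 3))
  expect_false("HMCN1-NTRK1" %in% rec$fusion_name)  # VUS excluded
  expect_match(tpm3$tumor_types, "breast")
  expect_error(recurrence_table(cl, n_cohort_total = 2), "smaller")
})

test_that("co-occurrence uses known-pathogenic alterations only", {
  flags <- specimen_positivity(mini_classified())
  co <- cooccurrence_summary(mini_cohort(), flags)
  expect_equal(co$gene_freq$n_specimens[co$gene_freq$gene == "TP53"], 3)
  expect_false("MUC16" %in% co$gene_freq$gene)  # benign alteration ignored
  expect_false("KRAS" %in% co$gene_freq$gene[co$gene_freq$percent < 3])
  expect_equal(
    co$class_freq$n_specimens[co$class_freq$alteration_class == "snv_indel"], 3)
  expect_equal(
    co$class_freq$n_specimens[co$class_freq$alteration_class == "cnv"], 1)
  # matrix: one column per positive specimen plus the gene column
  expect_equal(ncol(co$matrix), 1 + 3)
})

test_that("relaxing the oncoprint frequency filter only adds rows", {
  fx <- paper_fixture()
  strict <- cooccurrence_summary(fx$cohort, fx$flags, analysis_config())
  loose <- cooccurrence_summary(fx$cohort, fx$flags,
                                analysis_config(oncoprint_min_freq = 0.1))
  expect_true(all(strict$matrix$gene %in% loose$matrix$gene))
  expect_gt(nrow(loose$matrix), nrow(strict$matrix))
  shared <- loose$matrix[match(strict$matrix$gene, loose$matrix$gene),
                         names(strict$matrix)]
  expect_equal(as.data.frame(shared), as.data.frame(strict$matrix))
  expect_equal(ncol(strict$matrix) - 1, attr(fx$flags, "n_specimens_positive"))
})

test_that("driver and wild-type summaries respect strata and the gene list", {
  flags <- specimen_positivity(mini_classified())
  drv <- driver_cooccurrence(mini_cohort(), flags)
  expect_equal(drv$n_with_driver, 1)  # only M01 (KRAS)
  expect_equal(drv$n_positive, 3)
  drv_crc <- driver_cooccurrence(mini_cohort(), flags,
                                 tumor_types = "colorectal")
  expect_equal(drv_crc$n_with_driver, 0)
  wt <- wildtype_fraction(mini_cohort(), flags, c("KRAS", "NRAS", "BRAF"))
  expect_equal(wt$n_wildtype, 2)
  custom <- driver_cooccurrence(mini_cohort(), flags, driver_genes = "MDM2")
  expect_equal(custom$n_with_driver, 1)
})

test_that("TMB test is invariant to its monotone transform", {
  fx <- paper_fixture()
  raw <- fx$cohort
  cmp <- biomarker_comparison(raw, fx$flags, "tmb", "colorectal")
  # rank-sum on log(tmb+1) equals rank-sum on raw tmb
  ids <- fx$flags$specimen_id[fx$flags$ntrk_positive]
  crc <- raw[raw$tumor_type == "colorectal", ]
  w_raw <- stats::wilcox.test(crc$tmb[crc$specimen_id %in% ids],
                              crc$tmb[!crc$specimen_id %in% ids])
  expect_equal(cmp$statistic, unname(w_raw$statistic))
  expect_equal(cmp$p_value, w_raw$p.value)
  expect_equal(cmp$median_positive, 7.8)  # medians reported on original scale
})

test_that("PD-L1 never pools score types", {
  fx <- paper_fixture()
  expect_error(biomarker_comparison(fx$cohort, fx$flags, "pdl1"),
               "score_type")
  ok <- biomarker_comparison(fx$cohort, fx$flags, "pdl1", "head and neck")
  expect_equal(ok$score_type, "CPS")
  tps <- biomarker_comparison(fx$cohort, fx$flags, "pdl1",
                              score_type = "TPS")
  expect_equal(tps$score_type, "TPS")
  expect_equal(tps$n_positive, 18)  # only NSCLC carries TPS
})

test_that("empty comparison groups are skipped with a warning", {
  fx <- paper_fixture()
  expect_warning(
    out <- biomarker_comparison(fx$cohort, fx$flags, "tmb",
                                tumor_types = "no such type"),
    "skipped")
  expect_equal(nrow(out), 0)
})

test_that("MSI proportions and characteristics summarise the fixture", {
  fx <- paper_fixture()
  msi <- msi_proportions(fx$cohort, fx$flags,
                         c("colorectal", "small intestine"))
  expect_equal(msi$percent[msi$ntrk_positive], 50.0)
  expect_equal(msi$percent[!msi$ntrk_positive], 6.6)
  ch <- cohort_characteristics(fx$cohort, fx$flags)
  expect_equal(ch$median_age[ch$group == "NSCLC"], 65.5)
  expect_equal(ch$pct_female[ch$group == "other solid tumors"], 61)
})

test_that("cohort TSV round-trips the nested alteration column", {
  co <- mini_cohort()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back$specimen_id, co$specimen_id)
  expect_equal(back$alterations, co$alterations)
  expect_equal(back$pdl1_score, co$pdl1_score)
  # duplicate ids rejected
  dup <- dplyr::bind_rows(co, co[1, ])
  write_cohort(dup, path)
  expect_error(read_cohort(path), "unique")
})

test_that("plot functions return ggplot objects", {
  fx <- paper_fixture()
  prev <- prevalence_table(fx$cohort, fx$flags)
  expect_s3_class(plot_prevalence(prev), "ggplot")
  expect_s3_class(plot_biomarker(fx$cohort, fx$flags, "tmb", "colorectal"),
                  "ggplot")
  expect_s3_class(
    plot_msi(msi_proportions(fx$cohort, fx$flags,
                             c("colorectal", "small intestine"))), "ggplot")
  co <- cooccurrence_summary(fx$cohort, fx$flags)
  expect_s3_class(plot_oncoprint(co), "ggplot")
})
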