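test_that("the worked fusions classify as published", {
  tx <- worked_tx()
  res <- classify_batch(worked_calls(tx), tx, default_kb())
  cl <- tidy(res)
  verdict_of <- function(name) cl$verdict[cl$fusion_name == name]
  expect_equal(verdict_of("LMNA-NTRK1"), "ONCOGENIC")
  expect_equal(verdict_of("GNAQ-NTRK2"), "ONCOGENIC")
  expect_equal(verdict_of("ERBB2-NTRK3"), "LIKELY_ONCOGENIC")
  expect_equal(verdict_of("NTRK1-SIMPART02"), "VUS")
  # the 4-read LMNA-NTRK1 duplicate was filtered, so only one row remains
  expect_equal(sum(cl$fusion_name == "LMNA-NTRK1"), 1)
  expect_equal(res$qc$n_removed_read_support, 1)
  expect_match(cl$reasons[cl$fusion_name == "NTRK1-SIMPART02"],
               "orientation=5prime")
  expect_match(cl$reasons[cl$fusion_name == "ERBB2-NTRK3"],
               "partner=novel\\|frame=in_frame")
})

test_that("rules fire in order: TKD loss and frame failures give VUS", {
  tx <- shared_tx()
  calls <- tibble::tibble(
    specimen_id = c("T1", "T2"),
    gene_5p = c("LMNA", "SIMPART03"),
    bp_5p = c("intron3", "intron2"),
    gene_3p = c("NTRK1", "NTRK1"),
    bp_3p = c("intron13", "intron3"),  # 13 >= required_first_exon 12
    unique_reads = c(9L, 9L))
  ann <- frame_preserved(annotate_fusions(calls, tx), tx)
  cl <- classify_fusions(ann, tx, default_kb())
  expect_equal(cl$verdict[1], "VUS")
  expect_match(cl$reasons[1], "tkd=lost")
  expect_false(grepl("partner=", cl$reasons[1]))  # later rules not evaluated
  # row 2: novel partner, verdict depends on its frame status
  expect_equal(cl$verdict[2],
               if (cl$frame_status[2] == "in_frame") "LIKELY_ONCOGENIC"
               else "VUS")
})

test_that("known partners do not require frame; novel partners do", {
  tx <- shared_tx()
  # a junction retaining no LMNA coding sequence is frame-indeterminate:
  # cut LMNA inside its 5' UTR (exon 1, offset 1)
  calls <- tibble::tibble(
    specimen_id = c("K1", "N1"),
    gene_5p = c("LMNA", "SIMPART01"),
    bp_5p = c("exon1+1", "intron1"),  # SIMPART01 exon 1 is fully non-coding
    gene_3p = c("NTRK1", "NTRK1"),
    bp_3p = c("intron11", "intron11"),
    unique_reads = c(9L, 9L))
  ann <- frame_preserved(annotate_fusions(calls, tx), tx)
  expect_equal(ann$frame_status, c("indeterminate", "indeterminate"))
  cl <- classify_fusions(ann, tx, default_kb())
  expect_equal(cl$verdict, c("ONCOGENIC", "VUS"))
})

test_that("frame_preserved matches the translate-and-scan oracle on 500+ fusions", {
  skip_if_not_installed("Biostrings")
  tx <- shared_tx()
  seqs <- oracle_sequences(tx, seed = 7)
  partners <- setdiff(unique(tx$gene), c("NTRK1", "NTRK2", "NTRK3"))
  withr::with_seed(19, {
    n_target <- 520
    g5 <- sample(partners, n_target, replace = TRUE)
    g3 <- sample(c("NTRK1", "NTRK2", "NTRK3"), n_target, replace = TRUE)
    o5 <- vapply(g5, function(g) sample(sum(tx$gene == g) - 1L, 1), 1L)
    o3 <- vapply(g3, function(g) sample(sum(tx$gene == g) - 1L, 1), 1L)
  })
  ann <- tibble::tibble(
    specimen_id = sprintf("F%04d", seq_along(g5)),
    gene_5p = g5, gene_3p = g3,
    bp5_kind = "intron", bp5_ordinal = o5, bp5_offset = 0L,
    bp3_kind = "intron", bp3_ordinal = o3, bp3_offset = 0L)
  got <- frame_preserved(ann, tx)
  want <- vapply(seq_len(nrow(ann)), function(i) {
    r <- oracle_in_frame(tx, seqs, g5[i], o5[i], g3[i], o3[i])
    if (is.na(r)) "indeterminate" else if (r) "in_frame" else "out_of_frame"
  }, character(1))
  expect_gte(nrow(ann), 500)
  expect_equal(got$frame_status, want)
  # both outcomes are represented, so the agreement is not vacuous
  expect_true(all(c("in_frame", "out_of_frame") %in% want))
})

test_that("classification is idempotent and records the KB version", {
  tx <- worked_tx()
  res1 <- classify_batch(worked_calls(tx), tx, default_kb())
  res2 <- classify_batch(tidy(res1), tx, default_kb())
  expect_equal(tidy(res2)$verdict, tidy(res1)$verdict)
  expect_equal(unique(tidy(res1)$kb_version), kb_version(default_kb()))
})

test_that("KB upgrades are monotone: verdicts never move toward VUS", {
  tx <- shared_tx()
  sim <- simulate_cohort(sim_params(n_specimens = 20000, seed = 23), tx)
  kb_full <- default_kb()
  kb_small <- kb_full[seq_len(6), ]
  attr(kb_small, "kb_version") <- "small"
  before <- tidy(classify_batch(sim$fusions, tx, kb_small))$verdict
  after <- tidy(classify_batch(sim$fusions, tx, kb_full))$verdict
  rank <- function(v) match(v, c("VUS", "LIKELY_ONCOGENIC", "ONCOGENIC"))
  expect_true(all(rank(after) >= rank(before)))
  expect_true(any(rank(after) > rank(before)))  # the upgrade actually bites
})

test_that("QC totals reconcile exactly", {
  tx <- shared_tx()
  sim <- simulate_cohort(sim_params(n_specimens = 20000, seed = 29), tx)
  res <- classify_batch(sim$fusions, tx, default_kb())
  q <- res$qc
  expect_equal(q$n_input,
               q$n_classified + q$n_removed_read_support + q$n_annotation_failed)
  expect_equal(sum(unlist(q$verdicts)), q$n_classified)
  g <- glance(res)
  expect_equal(g$n_input, q$n_input)
  expect_s3_class(g, "tbl_df")
  expect_output(print(res), "classified")
})

test_that("empty input yields an empty, well-formed classification", {
  tx <- shared_tx()
  empty <- worked_calls()[0, ]
  res <- classify_batch(empty, tx, default_kb())
  expect_equal(res$qc$n_input, 0)
  expect_equal(nrow(tidy(res)), 0)
  expect_true(all(c("verdict", "reasons") %in% names(tidy(res))))
})

test_that("classification results write to disk and annotation errors block classify_fusions", {
  tx <- worked_tx()
  res <- classify_batch(worked_calls(tx), tx, default_kb())
  dir <- withr::local_tempdir()
  write_classification(res, dir)
  expect_true(file.exists(file.path(dir, "classified_fusions.tsv")))
  qc <- jsonlite::read_json(file.path(dir, "qc_report.json"))
  expect_equal(qc$n_input, res$qc$n_input)
  bad <- annotate_fusions(tibble::tibble(
    specimen_id = "X", gene_5p = "LMNA", bp_5p = "intron99",
    gene_3p = "NTRK1", bp_3p = "intron11", unique_reads = 9L), tx)
  expect_error(classify_fusions(bad, tx, default_kb()), "annotation errors")
})
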