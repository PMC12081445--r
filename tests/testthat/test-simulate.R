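test_that("same seed gives byte-identical outputs", {
  tx1 <- simulate_transcriptome(n_novel_partners = 5, seed = 77)
  tx2 <- simulate_transcriptome(n_novel_partners = 5, seed = 77)
  expect_identical(tibble::as_tibble(tx1), tibble::as_tibble(tx2))
  s1 <- simulate_cohort(sim_params(n_specimens = 3000, seed = 77), tx1)
  s2 <- simulate_cohort(sim_params(n_specimens = 3000, seed = 77), tx2)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fusion_calls(s1$fusions, f1); write_fusion_calls(s2$fusions, f2)
  expect_identical(readLines(f1), readLines(f2))
  c1 <- withr::local_tempfile(); c2 <- withr::local_tempfile()
  write_cohort(s1$cohort, c1); write_cohort(s2$cohort, c2)
  expect_identical(readLines(c1), readLines(c2))
  tx3 <- simulate_transcriptome(n_novel_partners = 5, seed = 78)
  expect_false(identical(tibble::as_tibble(tx1), tibble::as_tibble(tx3)))
})

test_that("simulated transcriptome satisfies the generator contract", {
  tx <- shared_tx()
  expect_silent(validate_transcripts(tx, require_cds_multiple = TRUE))
  doms <- transcript_domains(tx)
  expect_equal(doms[doms$gene == "NTRK2", c("first_exon", "last_exon")],
               tibble::tibble(first_exon = 16L, last_exon = 20L))
  # CDS phases of first introns cover {0,1,2} and one gene starts non-coding
  phases <- vapply(unique(tx$gene), function(g) {
    ex <- trkfusions:::gene_exons(tx, g)
    as.integer((ex$cum_cds_before[2] + 0L) %% 3L)
  }, 1L)
  first_cds <- vapply(unique(tx$gene), function(g) {
    trkfusions:::gene_exons(tx, g)$cds_len[1]
  }, 1L)
  expect_setequal(unique(phases[first_cds > 0]), 0:2)
  expect_true(any(first_cds == 0))
})

test_that("parameter validation rejects infeasible settings", {
  expect_error(sim_params(tumor_types = dplyr::mutate(
    default_tumor_types(), prevalence = prevalence * 1000)), "\\[0, 1\\]")
  expect_error(sim_params(tumor_types = dplyr::mutate(
    default_tumor_types(), weight = weight * 2)), "sum to 1")
  expect_error(simulate_cohort(sim_params(n_specimens = 10)), "seed")
})

test_that("prevalence 0 yields no fusion rows; emitted files pass their readers", {
  tx <- shared_tx()
  p0 <- sim_params(n_specimens = 500, seed = 9, vus_rate = 0,
                   subthreshold_rate = 0, tumor_types = dplyr::mutate(
                     default_tumor_types(), prevalence = 0))
  s0 <- simulate_cohort(p0, tx)
  expect_equal(sum(s0$truth$specimen_truth$ntrk_positive), 0)
  expect_equal(nrow(s0$fusions), 0)
  # schema closure on a normal simulation
  sim <- simulate_cohort(sim_params(n_specimens = 4000, seed = 13), tx)
  ftsv <- withr::local_tempfile(fileext = ".tsv")
  ctsv <- withr::local_tempfile(fileext = ".tsv")
  ttsv <- withr::local_tempfile(fileext = ".tsv")
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_fusion_calls(sim$fusions, ftsv)
  write_cohort(sim$cohort, ctsv)
  write_transcripts_tsv(tx, ttsv)
  write_transcripts_gtf(tx, gtf)
  expect_silent(read_transcripts(ttsv))
  expect_silent(read_transcripts(gtf))
  calls <- read_fusion_calls(ftsv)
  cohort <- read_cohort(ctsv)
  expect_equal(nrow(calls), nrow(sim$fusions))
  expect_equal(nrow(cohort), 4000)
  # and the read-back files classify without annotation failures
  res <- classify_batch(calls, tx, default_kb())
  expect_equal(res$qc$n_annotation_failed, 0)
})

test_that("end-to-end verdicts equal ground truth on a 10,000-specimen cohort", {
  tx <- shared_tx()
  sim <- simulate_cohort(sim_params(n_specimens = 10000, seed = 31), tx)
  res <- classify_batch(sim$fusions, tx, default_kb())
  cl <- tidy(res)
  # truth row i corresponds to input call row i, which classify_batch tracks
  # through its .row column
  truth <- sim$truth$fusion_truth
  truth$.row <- seq_len(nrow(truth))
  kept <- truth[truth$true_verdict != "FILTERED", ]
  m <- dplyr::inner_join(kept, cl[, c(".row", "verdict")], by = ".row")
  expect_equal(nrow(m), nrow(kept))
  expect_equal(m$verdict, m$true_verdict)
  # filtered truth rows never reach classification
  expect_equal(res$qc$n_removed_read_support,
               sum(truth$true_verdict == "FILTERED"))
  # specimen-level truth recovery
  flags <- specimen_positivity(res)
  st <- sim$truth$specimen_truth
  expect_setequal(flags$specimen_id[flags$ntrk_positive],
                  st$specimen_id[st$ntrk_positive])
})

test_that("observed prevalence lands in the exact binomial CI of the truth", {
  tx <- shared_tx()
  sim <- simulate_cohort(sim_params(n_specimens = 10000, seed = 37), tx)
  st <- sim$truth$specimen_truth
  nsclc <- st[st$tumor_type == "NSCLC", ]
  ci <- stats::binom.test(sum(nsclc$ntrk_positive), nrow(nsclc))$conf.int
  expect_true(ci[1] <= 0.0024 && 0.0024 <= ci[2])
})

test_that("co-alteration frequencies converge to params at n = 10,000", {
  tx <- shared_tx()
  sim <- simulate_cohort(sim_params(n_specimens = 10000, seed = 41), tx)
  st <- sim$truth$specimen_truth
  neg <- st$specimen_id[!st$ntrk_positive]
  alt <- dplyr::bind_rows(purrr::map2(
    sim$cohort$specimen_id, sim$cohort$alterations,
    function(id, a) if (nrow(a) > 0) dplyr::mutate(a, specimen_id = id)))
  p_tp53 <- mean(neg %in% alt$specimen_id[alt$gene == "TP53" &
                                            alt$known_pathogenic])
  ci <- stats::binom.test(round(p_tp53 * length(neg)), length(neg))$conf.int
  expect_true(ci[1] <= 0.45 && 0.45 <= ci[2])
  expect_true(any(!alt$known_pathogenic))  # benign rows are emitted
})
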