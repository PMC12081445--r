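# trkfusions

Rule-based oncogenicity classification and cohort analytics for RNA-detected
NTRK1/NTRK2/NTRK3 gene fusions.

The package covers the full path from raw fusion calls to cohort-level
results:

- **Transcript models** — exon/intron structures with CDS annotations,
  1-based closed coordinates, exons numbered in transcription order;
  readable from TSV or GTF (`read_transcripts_tsv()`, `read_transcripts_gtf()`).
- **Ingestion** — canonical fusion TSVs (`read_fusion_calls()`) or VCF
  breakend records (`read_fusion_vcf()`), a unique-read-support filter
  (`filter_read_support()`, default ≥ 5 reads), and breakpoint annotation
  against the transcript models (`annotate_fusions()`).
- **Classification** — `classify_batch()` applies ordered rules: NTRK must
  be the 3′ partner; the tyrosine kinase domain must be retained (data-driven
  via `default_tkd_regions()`); a curated partner (`default_kb()`, 18 pairs)
  gives **ONCOGENIC**; a novel partner with an in-frame junction (exon phase
  arithmetic, `frame_preserved()`) gives **LIKELY_ONCOGENIC**; anything else
  is a **VUS**.
- **Cohort analytics** — `prevalence_table()`, `recurrence_table()`,
  `cooccurrence_summary()`, `biomarker_comparison()` (TMB, PD-L1),
  `msi_summary()`, `cohort_characteristics()`, and `plot_*()` companions.
- **Simulation** — `simulate_transcriptome()` and `simulate_cohort()` emit
  transcript models, fusion calls, and specimen metadata with known ground
  truth for end-to-end validation. `paper_fixture()` ships a deterministic
  19,591-specimen case-level cohort whose aggregates reproduce a published
  pan-solid-tumour NTRK study through these same analytics functions.

## Worked example

Classify a handful of fusion calls against a simulated transcriptome:

```r
library(trkfusions)

tx <- simulate_transcriptome(n_novel_partners = 4, seed = 7)

calls <- tibble::tibble(
  specimen_id  = c("S1", "S2", "S3", "S4"),
  gene_5p      = c("LMNA", "GNAQ", "NTRK1", "LMNA"),
  bp_5p        = c("intron3", "intron1", "intron11", "intron3"),
  gene_3p      = c("NTRK1", "NTRK2", "SIMPART02", "NTRK1"),
  bp_3p        = c("intron11", "intron15", "intron2", "intron11"),
  unique_reads = c(12L, 9L, 20L, 4L))

res <- classify_batch(calls, tx, default_kb())
res
#> <ntrk_classification> 4 calls: 3 classified (ONCOGENIC 2, LIKELY_ONCOGENIC 0, VUS 1), 1 below 5 reads, 0 failed annotation [KB 2025.05]

tidy(res)[, c("specimen_id", "fusion_name", "verdict", "reasons")]
#>   specimen_id     fusion_name   verdict                                                 reasons
#> 1          S1      LMNA-NTRK1 ONCOGENIC orientation=3prime|tkd=retained|partner=known_canonical
#> 2          S2      GNAQ-NTRK2 ONCOGENIC orientation=3prime|tkd=retained|partner=known_canonical
#> 3          S3 NTRK1-SIMPART02       VUS                                      orientation=5prime
```

The `LMNA-NTRK1` and `GNAQ-NTRK2` fusions retain the kinase domain and hit
curated partners; the NTRK-5′ call is a VUS by orientation; the 4-read call
is filtered before classification and reported in the QC line.

Cohort analytics on the bundled fixture:

```r
fx <- paper_fixture()
prevalence_table(fx$cohort, fx$flags) |>
  dplyr::filter(tumor_type %in% c("NSCLC", "glioblastoma", "colorectal", "overall"))
#>     tumor_type n_positive n_total percent
#> 1        NSCLC         18    7630    0.24
#> 2   colorectal         11    2000    0.55
#> 3 glioblastoma          3     157    1.91
#> 4      overall         69   19531    0.35
```

See the vignette (`vignettes/classifying-ntrk-fusions.Rmd`) for the full
methods walkthrough, including the exon-phase frame rule, the TKD retention
convention, biomarker comparisons, and simulation-based verification.

## Acceptance script

`scripts/acceptance.R` runs the analytics end to end against the installed
package and writes the headline quantities as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results.json
```
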