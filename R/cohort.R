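#' Analysis configuration
#'
#' Thresholds and rounding conventions for the cohort analytics: TMB is
#' called high at >= 10 mutations/Mb; PD-L1 scores band into negative (< 1),
#' low (1-49) and high (>= 50); the oncoprint keeps genes altered in at
#' least 3% of fusion-positive specimens (boundary inclusive); percentages
#' round half-up at the precision of the published tables (2 decimals for
#' prevalence and fusion %, 3 for cohort %, 1 for co-occurrence %).
#'
#' @param tmb_high_threshold TMB-high cut-off in mutations/Mb.
#' @param pdl1_low,pdl1_high PD-L1 band boundaries.
#' @param oncoprint_min_freq Minimum cumulative alteration frequency (%) for
#'   a gene to enter the oncoprint matrix.
#' @param min_reads Unique-read support threshold for fusion calls.
#' @param prevalence_digits,fusion_pct_digits,cohort_pct_digits,cooccurrence_digits
#'   Half-up rounding precision for the respective percentages.
#' @return A named list of settings.
#' @export
analysis_config <- function(tmb_high_threshold = 10, pdl1_low = 1,
                            pdl1_high = 50, oncoprint_min_freq = 3,
                            min_reads = 5, prevalence_digits = 2,
                            fusion_pct_digits = 2, cohort_pct_digits = 3,
                            cooccurrence_digits = 1) {
  stopifnot(tmb_high_threshold > 0, oncoprint_min_freq > 0, min_reads >= 0)
  list(tmb_high_threshold = tmb_high_threshold, pdl1_low = pdl1_low,
       pdl1_high = pdl1_high, oncoprint_min_freq = oncoprint_min_freq,
       min_reads = min_reads, prevalence_digits = prevalence_digits,
       fusion_pct_digits = fusion_pct_digits,
       cohort_pct_digits = cohort_pct_digits,
       cooccurrence_digits = cooccurrence_digits)
}

#' Default oncogenic driver gene list
#'
#' Genes counted as co-occurring oncogenic drivers (configurable; the same
#' list governs the pan-tumour and NSCLC driver summaries).
#'
#' @return Character vector of gene symbols.
#' @export
default_driver_genes <- function() {
  c("ALK", "KRAS", "BRAF", "EGFR", "RET", "ROS1", "MET", "ERBB2", "PIK3CA")
}

#' Per-specimen NTRK fusion positivity
#'
#' A specimen is NTRK-positive when it carries at least one ONCOGENIC or
#' LIKELY_ONCOGENIC fusion; several qualifying fusions still count the
#' specimen once (fusion-level and specimen-level totals both reported).
#'
#' @param classified Classified fusion tibble (or `ntrk_classification`).
#' @return Tibble with one row per specimen appearing in `classified`:
#'   `specimen_id`, `n_qualifying`, `ntrk_positive`; attributes
#'   `n_fusions_qualifying` and `n_specimens_positive` carry the totals.
#' @export
specimen_positivity <- function(classified) {
  if (inherits(classified, "ntrk_classification")) classified <- classified$classified
  if (nrow(classified) == 0) {
    out <- tibble::tibble(specimen_id = character(), n_qualifying = integer(),
                          ntrk_positive = logical())
  } else {
    out <- classified |>
      dplyr::group_by(.data$specimen_id) |>
      dplyr::summarise(
        n_qualifying = sum(.data$verdict %in% c("ONCOGENIC", "LIKELY_ONCOGENIC")),
        .groups = "drop") |>
      dplyr::mutate(ntrk_positive = .data$n_qualifying > 0)
  }
  attr(out, "n_fusions_qualifying") <- sum(out$n_qualifying)
  attr(out, "n_specimens_positive") <- sum(out$ntrk_positive)
  out
}

positive_ids <- function(flags) flags$specimen_id[flags$ntrk_positive]

#' NTRK fusion prevalence per tumour type
#'
#' @param cohort Specimen tibble with `specimen_id` and `tumor_type`.
#' @param flags Positivity flags from [specimen_positivity()].
#' @param config See [analysis_config()].
#' @return Tibble with `tumor_type`, `n_positive`, `n_total`, `percent`
#'   (half-up, `prevalence_digits` decimals), plus an `overall` row; per-type
#'   counts sum to the overall row.
#' @export
prevalence_table <- function(cohort, flags, config = analysis_config()) {
  pos <- positive_ids(flags)
  unknown <- setdiff(pos, cohort$specimen_id)
  if (length(unknown) > 0) {
    stop(sprintf("positive specimen(s) absent from cohort: %s",
                 paste(utils::head(unknown, 5), collapse = ", ")), call. = FALSE)
  }
  per_type <- cohort |>
    dplyr::group_by(.data$tumor_type) |>
    dplyr::summarise(n_positive = sum(.data$specimen_id %in% pos),
                     n_total = dplyr::n(), .groups = "drop")
  overall <- tibble::tibble(tumor_type = "overall",
                            n_positive = sum(per_type$n_positive),
                            n_total = sum(per_type$n_total))
  dplyr::bind_rows(per_type, overall) |>
    dplyr::mutate(percent = round_half_up(100 * .data$n_positive / .data$n_total,
                                          config$prevalence_digits))
}

#' Fusion recurrence table
#'
#' One row per distinct fusion (5'-3' gene pair) among oncogenic or likely
#' oncogenic calls: the number of distinct specimens carrying it, its share
#' of all fusion-positive specimens (`fusion_pct`), its share of the whole
#' cohort (`cohort_pct`), the verdict, and a tumour-type breakdown when the
#' cohort table is supplied. Sorted by N descending, then name.
#'
#' @param classified Classified fusion tibble.
#' @param n_cohort_total Total number of specimens analysed.
#' @param cohort Optional specimen tibble for the tumour-type breakdown.
#' @param config See [analysis_config()].
#' @return Tibble `fusion_name`, `ntrk_gene`, `n_specimens`, `fusion_pct`,
#'   `cohort_pct`, `verdict`, `tumor_types`.
#' @export
recurrence_table <- function(classified, n_cohort_total, cohort = NULL,
                             config = analysis_config()) {
  if (inherits(classified, "ntrk_classification")) classified <- classified$classified
  qual <- classified[classified$verdict %in% c("ONCOGENIC", "LIKELY_ONCOGENIC"), ]
  n_pos <- dplyr::n_distinct(qual$specimen_id)
  if (n_cohort_total < n_pos) {
    stop("n_cohort_total is smaller than the number of positive specimens",
         call. = FALSE)
  }
  if (!"fusion_name" %in% names(qual)) {
    qual$fusion_name <- paste(qual$gene_5p, qual$gene_3p, sep = "-")
  }
  if (!is.null(cohort)) {
    qual <- dplyr::left_join(qual,
      cohort[, c("specimen_id", "tumor_type")], by = "specimen_id")
  } else {
    qual$tumor_type <- NA_character_
  }
  qual |>
    dplyr::group_by(.data$fusion_name) |>
    dplyr::summarise(
      ntrk_gene = dplyr::first(.data$ntrk_gene),
      n_specimens = dplyr::n_distinct(.data$specimen_id),
      verdict = verdict_levels()[min(match(.data$verdict, verdict_levels()))],
      tumor_types = type_breakdown(.data$tumor_type, .data$specimen_id),
      .groups = "drop") |>
    dplyr::mutate(
      fusion_pct = round_half_up(100 * .data$n_specimens / n_pos,
                                 config$fusion_pct_digits),
      cohort_pct = round_half_up(100 * .data$n_specimens / n_cohort_total,
                                 config$cohort_pct_digits)) |>
    dplyr::arrange(dplyr::desc(.data$n_specimens), .data$fusion_name) |>
    dplyr::select("fusion_name", "ntrk_gene", "n_specimens", "fusion_pct",
                  "cohort_pct", "verdict", "tumor_types")
}

type_breakdown <- function(tumor_type, specimen_id) {
  if (all(is.na(tumor_type))) return(NA_character_)
  tab <- table(tumor_type[!duplicated(specimen_id)])
  tab <- sort(tab, decreasing = TRUE)
  paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", ")
}

#' Known and novel partner-pair counts
#'
#' Counts distinct (partner, NTRK) pairs among oncogenic or likely oncogenic
#' fusions, split by knowledge-base status. A partner fused to two NTRK
#' genes contributes two pairs.
#'
#' @param classified Classified fusion tibble.
#' @param kb Knowledge base.
#' @return One-row tibble `n_known_pairs`, `n_novel_pairs`.
#' @export
partner_novelty_summary <- function(classified, kb = default_kb()) {
  if (inherits(classified, "ntrk_classification")) classified <- classified$classified
  qual <- classified[classified$verdict %in% c("ONCOGENIC", "LIKELY_ONCOGENIC"), ]
  if (nrow(qual) == 0) {
    return(tibble::tibble(n_known_pairs = 0L, n_novel_pairs = 0L))
  }
  pairs <- dplyr::distinct(qual, .data$gene_5p, .data$ntrk_gene)
  status <- partner_status(kb, pairs$gene_5p, pairs$ntrk_gene)
  tibble::tibble(n_known_pairs = sum(startsWith(status, "known")),
                 n_novel_pairs = sum(status == "novel"))
}

# long table of known-pathogenic alterations for the flagged specimens
pathogenic_alterations <- function(cohort, ids) {
  abort_cols(cohort, c("specimen_id", "alterations"), "cohort table")
  cohort |>
    dplyr::filter(.data$specimen_id %in% ids) |>
    dplyr::select("specimen_id", "alterations") |>
    tidyr::unnest("alterations") |>
    dplyr::filter(.data$known_pathogenic)
}

#' Co-occurring alteration summary and oncoprint matrix
#'
#' Restricted to alterations annotated known pathogenic. Per-gene cumulative
#' alteration frequency counts each fusion-positive specimen once however
#' many alterations it carries in the gene; the oncoprint matrix keeps genes
#' at or above the configured minimum frequency, with one column per
#' positive specimen and cells listing the alteration classes present.
#' Class-level frequencies (any SNV/indel, any CNV, any non-NTRK fusion) are
#' reported alongside.
#'
#' @param cohort Specimen tibble with a nested `alterations` list-column
#'   (tibbles with `gene`, `alteration_class`, `known_pathogenic`).
#' @param flags Positivity flags.
#' @param config See [analysis_config()].
#' @return List with `gene_freq` (gene, n_specimens, percent), `class_freq`,
#'   and `matrix` (wide tibble, genes x specimens).
#' @export
cooccurrence_summary <- function(cohort, flags, config = analysis_config()) {
  ids <- positive_ids(flags)
  n_pos <- length(ids)
  alt <- pathogenic_alterations(cohort, ids)
  gene_freq <- alt |>
    dplyr::distinct(.data$specimen_id, .data$gene) |>
    dplyr::count(.data$gene, name = "n_specimens") |>
    dplyr::mutate(percent = round_half_up(100 * .data$n_specimens / n_pos,
                                          config$cooccurrence_digits)) |>
    dplyr::arrange(dplyr::desc(.data$n_specimens), .data$gene)
  class_of <- function(cls) {
    alt |>
      dplyr::filter(.data$alteration_class %in% cls) |>
      dplyr::pull(.data$specimen_id) |>
      dplyr::n_distinct()
  }
  class_freq <- tibble::tibble(
    alteration_class = c("snv_indel", "cnv", "fusion"),
    n_specimens = c(class_of("snv_indel"), class_of(c("cnv_amp", "cnv_loss")),
                    class_of("fusion"))) |>
    dplyr::mutate(percent = round_half_up(100 * .data$n_specimens / n_pos,
                                          config$cooccurrence_digits))
  keep <- gene_freq$gene[gene_freq$percent >= config$oncoprint_min_freq]
  cells <- alt |>
    dplyr::filter(.data$gene %in% keep) |>
    dplyr::group_by(.data$gene, .data$specimen_id) |>
    dplyr::summarise(cell = paste(sort(unique(.data$alteration_class)),
                                  collapse = ";"), .groups = "drop")
  mat <- tidyr::expand_grid(gene = keep, specimen_id = ids) |>
    dplyr::left_join(cells, by = c("gene", "specimen_id")) |>
    tidyr::pivot_wider(names_from = "specimen_id", values_from = "cell")
  list(gene_freq = gene_freq, class_freq = class_freq, matrix = mat)
}

#' Co-occurring oncogenic driver frequency
#'
#' Fraction of fusion-positive specimens (optionally within a tumour-type
#' stratum) carrying at least one known-pathogenic alteration in a driver
#' gene.
#'
#' @param cohort Specimen tibble.
#' @param flags Positivity flags.
#' @param driver_genes Driver gene list, see [default_driver_genes()].
#' @param tumor_types Optional character vector restricting the stratum.
#' @param config See [analysis_config()].
#' @return One-row tibble `n_with_driver`, `n_positive`, `percent` (half-up,
#'   0 decimals, matching the published headline figures).
#' @export
driver_cooccurrence <- function(cohort, flags,
                                driver_genes = default_driver_genes(),
                                tumor_types = NULL,
                                config = analysis_config()) {
  ids <- positive_ids(flags)
  if (!is.null(tumor_types)) {
    ids <- intersect(ids,
      cohort$specimen_id[cohort$tumor_type %in% tumor_types])
  }
  alt <- pathogenic_alterations(cohort, ids)
  n_drv <- dplyr::n_distinct(alt$specimen_id[alt$gene %in% driver_genes])
  tibble::tibble(n_with_driver = n_drv, n_positive = length(ids),
                 percent = round_half_up(100 * n_drv / length(ids), 0))
}

#' Wild-type fraction for a gene set
#'
#' Fraction of fusion-positive specimens in a stratum with no
#' known-pathogenic alteration in any of the given genes (e.g. the
#' KRAS/NRAS/BRAF wild-type share of colorectal and small-intestine cases).
#'
#' @inheritParams driver_cooccurrence
#' @param genes Genes whose absence defines wild-type.
#' @return One-row tibble `n_wildtype`, `n_positive`, `percent`.
#' @export
wildtype_fraction <- function(cohort, flags, genes, tumor_types = NULL,
                              config = analysis_config()) {
  ids <- positive_ids(flags)
  if (!is.null(tumor_types)) {
    ids <- intersect(ids,
      cohort$specimen_id[cohort$tumor_type %in% tumor_types])
  }
  alt <- pathogenic_alterations(cohort, ids)
  mut <- unique(alt$specimen_id[alt$gene %in% genes])
  n_wt <- length(setdiff(ids, mut))
  tibble::tibble(n_wildtype = n_wt, n_positive = length(ids),
                 percent = round_half_up(100 * n_wt / length(ids), 0))
}

#' Compare an immunotherapy biomarker between fusion-positive and negative tumours
#'
#' Two-sided Wilcoxon rank-sum test with group medians reported on the
#' original scale. TMB values get a pseudo-count of 1 and are log-transformed
#' before testing (the monotone transform leaves the rank-sum p unchanged;
#' it matches the scale on which the distributions are displayed). PD-L1 is
#' tested on the raw score and never pools TPS with CPS: the stratum must
#' resolve to a single score type, either because all its specimens share
#' one or because `score_type` says which to keep. Missing biomarker values
#' are dropped and counted.
#'
#' @param cohort Specimen tibble with `tmb` or `pdl1_score`/`pdl1_score_type`.
#' @param flags Positivity flags.
#' @param biomarker `"tmb"` or `"pdl1"`.
#' @param tumor_types Optional tumour-type stratum.
#' @param score_type For PD-L1, `"TPS"` or `"CPS"`.
#' @return One-row tibble with group sizes, medians, the rank-sum statistic
#'   and the uncorrected two-sided p-value; zero rows (with a warning) when
#'   a group is empty after missing-value removal.
#' @export
biomarker_comparison <- function(cohort, flags, biomarker = c("tmb", "pdl1"),
                                 tumor_types = NULL, score_type = NULL) {
  biomarker <- match.arg(biomarker)
  df <- dplyr::mutate(cohort,
    ntrk_positive = .data$specimen_id %in% positive_ids(flags))
  if (!is.null(tumor_types)) {
    df <- dplyr::filter(df, .data$tumor_type %in% tumor_types)
  }
  if (biomarker == "tmb") {
    df$value <- df$tmb
    df$test_value <- log(df$tmb + 1)
    transform <- "log(tmb + 1)"
    st <- NA_character_
  } else {
    if (is.null(score_type)) {
      types <- unique(stats::na.omit(df$pdl1_score_type[!is.na(df$pdl1_score)]))
      if (length(types) > 1) {
        stop("stratum mixes PD-L1 score types; pass score_type = 'TPS' or 'CPS'",
             call. = FALSE)
      }
      score_type <- types
    }
    df <- dplyr::filter(df, .data$pdl1_score_type %in% score_type)
    df$value <- df$pdl1_score
    df$test_value <- df$pdl1_score
    transform <- "identity"
    st <- score_type
  }
  n_missing <- sum(is.na(df$value))
  df <- df[!is.na(df$value), ]
  pos <- df[df$ntrk_positive, ]
  neg <- df[!df$ntrk_positive, ]
  if (nrow(pos) == 0 || nrow(neg) == 0) {
    warning("a comparison group is empty after missing-value removal; stratum skipped",
            call. = FALSE)
    return(tibble::tibble())
  }
  wt <- suppressWarnings(stats::wilcox.test(pos$test_value, neg$test_value,
                                            alternative = "two.sided"))
  tibble::tibble(
    biomarker = biomarker, score_type = st,
    stratum = if (is.null(tumor_types)) "all" else
      paste(tumor_types, collapse = "+"),
    n_positive = nrow(pos), n_negative = nrow(neg), n_missing = n_missing,
    median_positive = stats::median(pos$value),
    median_negative = stats::median(neg$value),
    statistic = unname(wt$statistic), p_value = wt$p.value,
    transform = transform, p_adjusted = "none (uncorrected)")
}

#' MSI-high proportions by NTRK status
#'
#' Fractions of MSI-H cases among fusion-positive and fusion-negative
#' specimens in a stratum. No hypothesis test is attached: MSI-H group
#' sizes are typically too small for one.
#'
#' @param cohort Specimen tibble with an `msi` column (`"MSI-H"`/`"MSS"`/NA).
#' @param flags Positivity flags.
#' @param tumor_types Optional tumour-type stratum.
#' @param config See [analysis_config()].
#' @return Tibble with one row per NTRK status: `n`, `n_msi_h`, `percent`.
#' @export
msi_proportions <- function(cohort, flags, tumor_types = NULL,
                            config = analysis_config()) {
  df <- dplyr::mutate(cohort,
    ntrk_positive = .data$specimen_id %in% positive_ids(flags))
  if (!is.null(tumor_types)) {
    df <- dplyr::filter(df, .data$tumor_type %in% tumor_types)
  }
  df <- df[!is.na(df$msi), ]
  df |>
    dplyr::group_by(.data$ntrk_positive) |>
    dplyr::summarise(n = dplyr::n(), n_msi_h = sum(.data$msi == "MSI-H"),
                     .groups = "drop") |>
    dplyr::mutate(percent = round_half_up(100 * .data$n_msi_h / .data$n,
                                          config$cooccurrence_digits))
}

#' Clinical characteristics of fusion-positive specimens
#'
#' Age, sex, and stage summaries of the NTRK-positive specimens, split into
#' NSCLC versus all other solid tumours.
#'
#' @param cohort Specimen tibble with `age`, `sex`, `stage`, `tumor_type`.
#' @param flags Positivity flags.
#' @return Tibble with one row per group: positive count, median/range of
#'   age, sex counts and half-up percentages, stage counts.
#' @export
cohort_characteristics <- function(cohort, flags) {
  df <- cohort[cohort$specimen_id %in% positive_ids(flags), ]
  df$group <- ifelse(df$tumor_type == "NSCLC", "NSCLC", "other solid tumors")
  df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_positive = dplyr::n(),
      median_age = stats::median(.data$age, na.rm = TRUE),
      age_min = min(.data$age, na.rm = TRUE),
      age_max = max(.data$age, na.rm = TRUE),
      n_male = sum(.data$sex == "male", na.rm = TRUE),
      n_female = sum(.data$sex == "female", na.rm = TRUE),
      pct_male = round_half_up(100 * n_male / dplyr::n(), 0),
      pct_female = round_half_up(100 * n_female / dplyr::n(), 0),
      n_stage_le3 = sum(.data$stage == "<=III", na.rm = TRUE),
      n_stage_4 = sum(.data$stage == "IV", na.rm = TRUE),
      n_stage_unknown = sum(is.na(.data$stage) | .data$stage == "unknown"),
      .groups = "drop")
}
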