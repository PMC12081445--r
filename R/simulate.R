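#' Simulate a transcriptome for fusion testing
#'
#' Builds NTRK1/NTRK2/NTRK3-like transcript models (17, 20, and 19 exons
#' with kinase-domain annotations on exons 9-17, 16-20, and 15-19; NTRK3 on
#' the minus strand) plus partner genes: every partner named in the default
#' knowledge base, and `n_novel_partners` additional genes (SIMPARTxx).
#' Partner geometry varies exon counts and CDS layout; the first three novel
#' partners are constructed so their first-intron phases cover 0, 1 and 2
#' (guaranteeing frame-matched and frame-mismatched junction choices), and
#' the first novel partner starts with a fully non-coding exon so
#' indeterminate-frame junctions are reachable.
#'
#' Output is deterministic for a given seed.
#'
#' @param n_novel_partners Number of novel partner genes (>= 1).
#' @param seed Integer seed (mandatory).
#' @return A transcript tibble (see [transcripts]).
#' @export
simulate_transcriptome <- function(n_novel_partners = 12, seed) {
  stopifnot(n_novel_partners >= 1, !missing(seed))
  withr::with_seed(seed, {
    specs <- list(
      list(gene = "NTRK1", chrom = "chr1", strand = "+", n_exons = 17L,
           tkd = c(9L, 17L)),
      list(gene = "NTRK2", chrom = "chr9", strand = "+", n_exons = 20L,
           tkd = c(16L, 20L)),
      list(gene = "NTRK3", chrom = "chr15", strand = "-", n_exons = 19L,
           tkd = c(15L, 19L)))
    out <- list(); doms <- list()
    for (s in specs) {
      out[[s$gene]] <- sim_gene(s$gene, s$chrom, s$strand, s$n_exons)
      doms[[s$gene]] <- tibble::tibble(gene = s$gene, domain = "TKD",
                                       first_exon = s$tkd[1],
                                       last_exon = s$tkd[2])
    }
    kb_partners <- dplyr::distinct(default_kb(), .data$partner_gene)$partner_gene
    partners <- c(kb_partners,
                  sprintf("SIMPART%02d", seq_len(n_novel_partners)))
    for (i in seq_along(partners)) {
      g <- partners[i]
      chrom <- sample(paste0("chr", 1:22), 1)
      strand <- sample(c("+", "-"), 1)
      n_ex <- sample(4:15, 1)
      novel_idx <- i - length(kb_partners)
      # first novel partner: fully non-coding first exon; next three pin the
      # exon-1 CDS length to 0/1/2 mod 3 so junction phases cover all classes
      utr_exons <- if (novel_idx == 1) 1L else 0L
      phase_pin <- if (novel_idx %in% 2:4) (novel_idx - 2L) else NA_integer_
      out[[g]] <- sim_gene(g, chrom, strand, n_ex, utr5_exons = utr_exons,
                           first_cds_phase = phase_pin)
    }
    new_transcripts(dplyr::bind_rows(out), dplyr::bind_rows(doms))
  })
}

# one multi-exon gene with a CDS whose total length is a multiple of 3;
# utr5_exons leading exons are fully non-coding; first_cds_phase, when set,
# forces (length of the first coding exon's CDS) %% 3
sim_gene <- function(gene, chrom, strand, n_exons, utr5_exons = 0L,
                     first_cds_phase = NA_integer_) {
  exon_len <- sample(90:280, n_exons, replace = TRUE)
  intron_len <- sample(400:5000, n_exons - 1, replace = TRUE)
  first_cds_exon <- utr5_exons + 1L
  # CDS offsets within each exon (transcript orientation), NA for UTR exons
  cds_a <- rep(NA_integer_, n_exons); cds_b <- rep(NA_integer_, n_exons)
  utr5_len <- sample(10:40, 1)
  utr3_len <- sample(10:40, 1)
  exon_len[first_cds_exon] <- max(exon_len[first_cds_exon], utr5_len + 30L)
  exon_len[n_exons] <- max(exon_len[n_exons], utr3_len + 30L)
  cds_a[first_cds_exon] <- utr5_len + 1L
  cds_b[first_cds_exon] <- exon_len[first_cds_exon]
  if (!is.na(first_cds_phase)) {
    len1 <- cds_b[first_cds_exon] - cds_a[first_cds_exon] + 1L
    cds_b[first_cds_exon] <- cds_b[first_cds_exon] -
      (len1 - first_cds_phase) %% 3L
  }
  mid <- setdiff(seq_len(n_exons), c(seq_len(utr5_exons), first_cds_exon,
                                     n_exons))
  cds_a[mid] <- 1L; cds_b[mid] <- exon_len[mid]
  if (n_exons > first_cds_exon) {
    cds_a[n_exons] <- 1L
    cds_b[n_exons] <- exon_len[n_exons] - utr3_len
  }
  total <- sum(ifelse(is.na(cds_a), 0L, cds_b - cds_a + 1L))
  trim <- total %% 3L
  cds_b[n_exons] <- cds_b[n_exons] - trim  # end on a codon boundary
  # genomic layout: transcript order left-to-right on +, right-to-left on -
  tx_start <- sample(1e5:5e5, 1)
  starts <- integer(n_exons); ends <- integer(n_exons)
  pos <- tx_start
  for (k in seq_len(n_exons)) {
    if (strand == "+") {
      starts[k] <- pos; ends[k] <- pos + exon_len[k] - 1L
      pos <- ends[k] + (if (k < n_exons) intron_len[k] else 0L) + 1L
    } else {
      ends[k] <- pos; starts[k] <- pos - exon_len[k] + 1L
      pos <- starts[k] - (if (k < n_exons) intron_len[k] else 0L) - 1L
    }
  }
  if (strand == "-") {
    shift <- tx_start - min(starts) + 1L  # keep coordinates positive
    starts <- starts + shift; ends <- ends + shift
  }
  cds_start <- rep(NA_integer_, n_exons); cds_end <- rep(NA_integer_, n_exons)
  for (k in seq_len(n_exons)) {
    if (is.na(cds_a[k])) next
    if (strand == "+") {
      cds_start[k] <- starts[k] + cds_a[k] - 1L
      cds_end[k] <- starts[k] + cds_b[k] - 1L
    } else {
      cds_end[k] <- ends[k] - cds_a[k] + 1L
      cds_start[k] <- ends[k] - cds_b[k] + 1L
    }
  }
  tibble::tibble(gene = gene, chrom = chrom, strand = strand,
                 exon_number = seq_len(n_exons), start = starts, end = ends,
                 cds_start = cds_start, cds_end = cds_end)
}

#' Simulation parameters for a synthetic tumour cohort
#'
#' The defaults encode the study conditions the simulator emulates: a
#' pan-solid-tumour cohort dominated by NSCLC (39%), per-type fusion
#' prevalences of roughly 0.2-2% (glioblastoma highest), read support
#' straddling the 5-read threshold, TP53 co-altered in ~51% of
#' fusion-positive cases, log-normal TMB with a downward shift in
#' fusion-positive head-and-neck tumours and an upward shift in colorectal,
#' zero-inflated PD-L1 scores typed TPS or CPS by tumour type, and MSI-H
#' enrichment in fusion-positive colorectal/small-intestine cases (50% vs
#' 6.6%).
#'
#' @param n_specimens Cohort size.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param tumor_types Tibble with per-type columns `tumor_type`, `weight`,
#'   `prevalence`, `pdl1_score_type`, `tmb_mu`, `tmb_sigma` (log scale of
#'   tmb+1), `tmb_shift_pos` (additive log-scale shift for fusion-positive),
#'   `pdl1_zero`, `msi_h_pos`, `msi_h_neg`. Defaults described above.
#' @param p_oncogenic Probability a qualifying fusion uses a known partner
#'   (true verdict ONCOGENIC rather than LIKELY_ONCOGENIC).
#' @param p_second_fusion Probability a fusion-positive specimen carries a
#'   second qualifying fusion (the published cohort had 73 fusions in 69
#'   specimens).
#' @param frac_intronic Fraction of breakpoints placed in introns.
#' @param vus_rate Per-specimen probability (among fusion-negative
#'   specimens) of a VUS-only fusion call.
#' @param subthreshold_rate Per-specimen probability of a fusion call with
#'   fewer than 5 supporting reads.
#' @param read_lambda Poisson mean added to the 5-read floor for qualifying
#'   calls.
#' @param coalterations Tibble `gene`, `alteration_class`, `p_pos`, `p_neg`:
#'   per-gene known-pathogenic alteration probabilities among fusion-positive
#'   and fusion-negative specimens.
#' @param benign_rate Per-specimen probability of an additional alteration
#'   annotated NOT known-pathogenic (exercises the pathogenic-only filter).
#' @return A named list of validated parameters.
#' @export
sim_params <- function(n_specimens = 2000, seed = NULL,
                       tumor_types = default_tumor_types(),
                       p_oncogenic = 0.5, p_second_fusion = 0.06,
                       frac_intronic = 0.7, vus_rate = 0.0015,
                       subthreshold_rate = 0.0008, read_lambda = 8,
                       coalterations = default_coalterations(),
                       benign_rate = 0.03) {
  stopifnot(n_specimens >= 1)
  probs <- c(tumor_types$prevalence, tumor_types$pdl1_zero,
             tumor_types$msi_h_pos, tumor_types$msi_h_neg,
             p_oncogenic, p_second_fusion, frac_intronic, vus_rate,
             subthreshold_rate, coalterations$p_pos, coalterations$p_neg,
             benign_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(tumor_types$weight) - 1) > 1e-6) {
    stop("tumor type weights must sum to 1", call. = FALSE)
  }
  list(n_specimens = n_specimens, seed = seed, tumor_types = tumor_types,
       p_oncogenic = p_oncogenic, p_second_fusion = p_second_fusion,
       frac_intronic = frac_intronic, vus_rate = vus_rate,
       subthreshold_rate = subthreshold_rate, read_lambda = read_lambda,
       coalterations = coalterations, benign_rate = benign_rate)
}

#' @rdname sim_params
#' @export
default_tumor_types <- function() {
  tibble::tribble(
    ~tumor_type,       ~weight, ~prevalence, ~pdl1_score_type, ~tmb_mu, ~tmb_sigma, ~tmb_shift_pos, ~pdl1_zero, ~msi_h_pos, ~msi_h_neg,
    "NSCLC",             0.390,      0.0024, "TPS",              2.00,       0.80,           0.00,       0.30,       0.00,      0.003,
    "colorectal",        0.100,      0.0055, "CPS",              1.97,       0.70,           0.20,       0.55,       0.50,      0.066,
    "breast",            0.073,      0.0063, "CPS",              1.50,       0.70,           0.00,       0.50,       0.00,      0.010,
    "head and neck",     0.022,      0.0095, "CPS",              1.86,       0.75,          -1.11,       0.25,       0.00,      0.010,
    "glioblastoma",      0.008,      0.0191, "CPS",              1.30,       0.60,           0.00,       0.60,       0.00,      0.005,
    "small intestine",   0.004,      0.0132, "CPS",              1.80,       0.70,           0.20,       0.55,       0.50,      0.066,
    "uterine",           0.026,      0.0019, "CPS",              1.70,       0.80,           0.00,       0.50,       0.00,      0.080,
    "ovarian",           0.041,      0.0040, "CPS",              1.55,       0.65,           0.00,       0.50,       0.00,      0.010,
    "other",             0.336,      0.0043, "CPS",              1.70,       0.80,           0.00,       0.45,       0.00,      0.010)
}

#' @rdname sim_params
#' @export
default_coalterations <- function() {
  tibble::tribble(
    ~gene,    ~alteration_class, ~p_pos, ~p_neg,
    "TP53",   "snv_indel",        0.507,   0.45,
    "ARID1A", "snv_indel",        0.130,   0.08,
    "KRAS",   "snv_indel",        0.130,   0.20,
    "NOTCH1", "snv_indel",        0.101,   0.05,
    "PIK3CA", "snv_indel",        0.080,   0.10,
    "KMT2D",  "snv_indel",        0.300,   0.25,
    "MDM2",   "cnv_amp",          0.040,   0.03,
    "PTEN",   "cnv_loss",         0.040,   0.03,
    "CCND1",  "cnv_amp",          0.100,   0.08,
    "RET",    "fusion",           0.030,   0.01,
    "FGFR2",  "fusion",           0.150,   0.05)
}

#' Simulate a tumour cohort with ground truth
#'
#' Generates fusion calls and specimen metadata by working backward from
#' intended verdicts: fusion-positive specimens receive one (occasionally
#' two) fusions constructed to be ONCOGENIC (known partner) or
#' LIKELY_ONCOGENIC (novel partner, frame-matched junction); a small share
#' of fusion-negative specimens receive VUS constructions (NTRK on the 5'
#' side, frame-mismatched novel-partner junctions, or kinase-domain-losing
#' breakpoints) or sub-threshold calls. Breakpoints are emitted as genomic
#' coordinates consistent with the simulated transcriptome, and the ground
#' truth records the intended verdict, frame status, and descriptors of
#' every emitted row.
#'
#' @param params Parameter list from [sim_params()] (seed mandatory).
#' @param transcripts Transcript tibble from [simulate_transcriptome()];
#'   simulated from the same seed when omitted.
#' @return List with `fusions` (fusion call tibble), `cohort` (specimen
#'   tibble), `truth` (list of `fusion_truth` and `specimen_truth` tibbles),
#'   and `transcripts`.
#' @export
simulate_cohort <- function(params, transcripts = NULL) {
  if (is.null(params$seed)) stop("params$seed is mandatory", call. = FALSE)
  if (is.null(transcripts)) {
    transcripts <- simulate_transcriptome(seed = params$seed)
  }
  withr::with_seed(params$seed + 1L, {
    tt <- params$tumor_types
    n <- params$n_specimens
    specimen_id <- sprintf("SIM%06d", seq_len(n))
    tumor_type <- sample(tt$tumor_type, n, replace = TRUE, prob = tt$weight)
    row <- match(tumor_type, tt$tumor_type)
    positive <- stats::rbinom(n, 1, tt$prevalence[row]) == 1

    # clinical covariates -------------------------------------------------
    log_tmb1 <- stats::rnorm(n, tt$tmb_mu[row] + positive * tt$tmb_shift_pos[row],
                             tt$tmb_sigma[row])
    tmb <- round(pmax(exp(log_tmb1) - 1, 0), 1)
    pdl1_zero <- stats::runif(n) < tt$pdl1_zero[row]
    band_high <- stats::runif(n) < 0.3
    pdl1_score <- ifelse(pdl1_zero, 0,
                         ifelse(band_high, sample(50:100, n, replace = TRUE),
                                sample(1:49, n, replace = TRUE)))
    pdl1_score[stats::runif(n) < 0.05] <- NA  # not all tumours are scored
    msi_p <- ifelse(positive, tt$msi_h_pos[row], tt$msi_h_neg[row])
    msi <- ifelse(stats::runif(n) < msi_p, "MSI-H", "MSS")
    msi[stats::runif(n) < 0.02] <- NA
    age <- pmin(pmax(round(stats::rnorm(n, 66, 12)), 20), 95)
    sex <- sample(c("male", "female"), n, replace = TRUE)
    stage <- sample(c("<=III", "IV", "unknown"), n, replace = TRUE,
                    prob = c(0.1, 0.35, 0.55))

    # co-occurring alterations --------------------------------------------
    ca <- params$coalterations
    alt_rows <- purrr::pmap(ca, function(gene, alteration_class, p_pos, p_neg) {
      hit <- stats::runif(n) < ifelse(positive, p_pos, p_neg)
      if (!any(hit)) return(NULL)
      tibble::tibble(specimen_id = specimen_id[hit], gene = gene,
                     alteration_class = alteration_class,
                     known_pathogenic = TRUE)
    })
    benign_hit <- stats::runif(n) < params$benign_rate
    alt_rows <- c(alt_rows, list(tibble::tibble(
      specimen_id = specimen_id[benign_hit], gene = "MUC16",
      alteration_class = "snv_indel", known_pathogenic = FALSE)))
    alt_long <- dplyr::bind_rows(alt_rows)
    alt_nested <- split(
      alt_long[, c("gene", "alteration_class", "known_pathogenic")],
      factor(alt_long$specimen_id, levels = specimen_id))
    cohort <- tibble::tibble(
      specimen_id = specimen_id, tumor_type = tumor_type, age = age,
      sex = sex, stage = stage, tmb = tmb, pdl1_score = pdl1_score,
      pdl1_score_type = tt$pdl1_score_type[row], msi = msi,
      alterations = unname(lapply(alt_nested, tibble::as_tibble)))

    # fusion construction --------------------------------------------------
    geno <- junction_catalog(transcripts)
    fus <- list(); truth <- list()
    add_fusion <- function(sid, intent) {
      f <- build_fusion(intent, transcripts, geno, params)
      fus[[length(fus) + 1L]] <<- f$call |>
        dplyr::mutate(specimen_id = sid, .before = 1)
      truth[[length(truth) + 1L]] <<- f$truth |>
        dplyr::mutate(specimen_id = sid, .before = 1)
    }
    for (sid in specimen_id[positive]) {
      k <- 1L + stats::rbinom(1, 1, params$p_second_fusion)
      for (j in seq_len(k)) {
        intent <- if (stats::runif(1) < params$p_oncogenic) "ONCOGENIC"
                  else "LIKELY_ONCOGENIC"
        add_fusion(sid, intent)
      }
    }
    neg_ids <- specimen_id[!positive]
    vus_hit <- neg_ids[stats::runif(length(neg_ids)) < params$vus_rate]
    vus_kinds <- rep(c("vus_orientation", "vus_out_of_frame", "vus_tkd_lost"),
                     length.out = length(vus_hit))
    for (i in seq_along(vus_hit)) add_fusion(vus_hit[i], vus_kinds[i])
    sub_hit <- setdiff(neg_ids[stats::runif(length(neg_ids)) <
                                 params$subthreshold_rate], vus_hit)
    for (sid in sub_hit) add_fusion(sid, "subthreshold")

    fusions <- if (length(fus) > 0) dplyr::bind_rows(fus) else tibble::tibble(
      specimen_id = character(), gene_5p = character(), bp_5p = character(),
      gene_3p = character(), bp_3p = character(), unique_reads = integer(),
      caller_tag = character())
    fusion_truth <- if (length(truth) > 0) dplyr::bind_rows(truth) else
      tibble::tibble()
    list(fusions = fusions, cohort = cohort,
         truth = list(
           fusion_truth = fusion_truth,
           specimen_truth = tibble::tibble(specimen_id = specimen_id,
                                           tumor_type = tumor_type,
                                           ntrk_positive = positive)),
         transcripts = transcripts)
  })
}

# precomputed junction geometry: for every gene, the phase after each intron
# (5' use) and before each intron (3' use), plus NTRK retention bounds
junction_catalog <- function(transcripts) {
  genes <- unique(transcripts$gene)
  cat5 <- list(); cat3 <- list()
  for (g in genes) {
    ex <- gene_exons(transcripts, g)
    n <- nrow(ex)
    if (n < 2) next
    introns <- seq_len(n - 1)
    end_cds <- ex$cum_cds_before[introns] + ex$cds_len[introns]
    cat5[[g]] <- tibble::tibble(gene = g, ordinal = introns,
                                cds_before = end_cds,
                                phase = ifelse(end_cds == 0, NA_integer_,
                                               end_cds %% 3L))
    total <- sum(ex$cds_len)
    cat3[[g]] <- tibble::tibble(gene = g, ordinal = introns,
                                cds_before = end_cds,
                                phase = ifelse(total - end_cds <= 0,
                                               NA_integer_, end_cds %% 3L))
  }
  kb <- default_kb()
  tkd <- default_tkd_regions()
  list(cat5 = dplyr::bind_rows(cat5), cat3 = dplyr::bind_rows(cat3),
       kb = kb, tkd = tkd,
       novel_partners = grep("^SIMPART", genes, value = TRUE),
       genes = genes)
}

# verdict-first construction of one fusion call + its ground truth row
build_fusion <- function(intent, transcripts, geno, params) {
  ntrk <- sample(ntrk_genes(), 1)
  req <- geno$tkd$required_first_exon[geno$tkd$ntrk_gene == ntrk]
  known_partners <- intersect(
    geno$kb$partner_gene[geno$kb$ntrk_gene == ntrk], geno$genes)
  pick3_retained <- function() sample(seq_len(req - 1L), 1)
  cand3 <- geno$cat3[geno$cat3$gene == ntrk & geno$cat3$ordinal < req, ]

  verdict <- intent
  frame <- NA_character_
  if (intent == "ONCOGENIC") {
    g5 <- sample(known_partners, 1)
    o3 <- pick3_retained()
    o5 <- sample(geno$cat5$ordinal[geno$cat5$gene == g5], 1)
    p5 <- geno$cat5$phase[geno$cat5$gene == g5 & geno$cat5$ordinal == o5]
    p3 <- geno$cat3$phase[geno$cat3$gene == ntrk & geno$cat3$ordinal == o3]
    frame <- if (is.na(p5) || is.na(p3)) "indeterminate"
             else if (p5 == p3) "in_frame" else "out_of_frame"
  } else if (intent %in% c("LIKELY_ONCOGENIC", "vus_out_of_frame",
                           "subthreshold")) {
    want_match <- intent != "vus_out_of_frame"
    repeat {
      g5 <- sample(geno$novel_partners, 1)
      c5 <- geno$cat5[geno$cat5$gene == g5 & !is.na(geno$cat5$phase), ]
      c3 <- cand3[!is.na(cand3$phase), ]
      if (nrow(c5) == 0 || nrow(c3) == 0) next
      grid <- tidyr::expand_grid(i5 = seq_len(nrow(c5)), i3 = seq_len(nrow(c3)))
      ok <- (c5$phase[grid$i5] == c3$phase[grid$i3]) == want_match
      if (!any(ok)) next
      pick <- grid[sample(which(ok), 1), ]
      o5 <- c5$ordinal[pick$i5]; o3 <- c3$ordinal[pick$i3]
      break
    }
    frame <- if (want_match) "in_frame" else "out_of_frame"
    if (intent == "vus_out_of_frame") verdict <- "VUS"
    if (intent == "subthreshold") verdict <- "FILTERED"
  } else if (intent == "vus_tkd_lost") {
    g5 <- sample(c(known_partners, geno$novel_partners), 1)
    n3 <- max(geno$cat3$ordinal[geno$cat3$gene == ntrk]) + 1L
    o3 <- sample(seq(req, n3 - 1L), 1)
    o5 <- sample(geno$cat5$ordinal[geno$cat5$gene == g5], 1)
    verdict <- "VUS"
  } else if (intent == "vus_orientation") {
    # NTRK on the 5' side
    g3 <- sample(geno$novel_partners, 1)
    o5 <- sample(geno$cat5$ordinal[geno$cat5$gene == ntrk], 1)
    o3 <- sample(geno$cat3$ordinal[geno$cat3$gene == g3], 1)
    reads <- 5L + stats::rpois(1, params$read_lambda)
    b5 <- emit_breakpoint(transcripts, ntrk, o5, "5p", params$frac_intronic)
    b3 <- emit_breakpoint(transcripts, g3, o3, "3p", params$frac_intronic)
    call <- tibble::tibble(
      gene_5p = ntrk, bp_5p = b5$string, gene_3p = g3, bp_3p = b3$string,
      unique_reads = reads, caller_tag = "sim")
    truth <- tibble::tibble(
      gene_5p = ntrk, gene_3p = g3, true_verdict = "VUS",
      true_frame = NA_character_, bp5_kind = b5$kind, bp5_ordinal = b5$ordinal,
      bp5_offset = b5$offset, bp3_kind = b3$kind, bp3_ordinal = b3$ordinal,
      bp3_offset = b3$offset)
    return(list(call = call, truth = truth))
  } else {
    stop("unknown intent ", intent)
  }
  reads <- if (identical(verdict, "FILTERED")) sample(1:4, 1)
           else 5L + stats::rpois(1, params$read_lambda)
  b5 <- emit_breakpoint(transcripts, g5, o5, "5p", params$frac_intronic)
  b3 <- emit_breakpoint(transcripts, ntrk, o3, "3p", params$frac_intronic,
                        max_exon_ordinal = req - 1L)
  call <- tibble::tibble(
    gene_5p = g5, bp_5p = b5$string, gene_3p = ntrk, bp_3p = b3$string,
    unique_reads = reads, caller_tag = "sim")
  truth <- tibble::tibble(
    gene_5p = g5, gene_3p = ntrk, true_verdict = verdict,
    true_frame = frame, bp5_kind = b5$kind, bp5_ordinal = b5$ordinal,
    bp5_offset = b5$offset, bp3_kind = b3$kind, bp3_ordinal = b3$ordinal,
    bp3_offset = b3$offset)
  list(call = call, truth = truth)
}

# Emit an intron breakpoint, or (with probability 1 - frac_intronic) an
# exonic breakpoint with identical retained-CDS arithmetic: the 5' side cuts
# at the end of its exon's CDS, the 3' side at the first coding base of the
# next exon, so the intended frame and retention labels carry over exactly.
# max_exon_ordinal caps the exon ordinal usable on the 3' side so a
# kinase-domain-retaining intron is never converted into an exonic
# breakpoint inside the required domain span.
emit_breakpoint <- function(transcripts, gene, intron_ordinal, side,
                            frac_intronic, max_exon_ordinal = Inf) {
  ex <- gene_exons(transcripts, gene)
  chrom <- ex$chrom[1]
  if (stats::runif(1) >= frac_intronic) {
    ord <- if (side == "5p") intron_ordinal else intron_ordinal + 1L
    off <- if (side == "5p") ex$cds_off_end[ord] else ex$cds_off_start[ord]
    if (!is.na(off) && ord <= max_exon_ordinal) {
      pos <- breakpoint_genomic(transcripts, gene, "exon", ord, off)
      return(list(string = paste0(chrom, ":", pos), kind = "exon",
                  ordinal = ord, offset = as.integer(off)))
    }
  }
  pos <- breakpoint_genomic(transcripts, gene, "intron", intron_ordinal,
                            intron_at = "random")
  list(string = paste0(chrom, ":", pos), kind = "intron",
       ordinal = intron_ordinal, offset = 0L)
}
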