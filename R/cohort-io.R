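#' Read a cohort specimen table
#'
#' TSV columns: `specimen_id`, `tumor_type`, `age`, `sex`, `stage`, `tmb`,
#' `pdl1_score`, `pdl1_score_type`, `msi`, `alterations`. The `alterations`
#' column encodes the per-specimen alteration list as
#' `GENE:class:1;GENE:class:0;...` (class one of snv_indel, cnv_amp,
#' cnv_loss, fusion; the trailing flag marks known-pathogenic); it is parsed
#' into a nested list-column of tibbles.
#'
#' @param path Path to a cohort TSV.
#' @return Specimen tibble with a nested `alterations` list-column.
#' @export
read_cohort <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    specimen_id = readr::col_character(), tumor_type = readr::col_character(),
    age = readr::col_double(), sex = readr::col_character(),
    stage = readr::col_character(), tmb = readr::col_double(),
    pdl1_score = readr::col_double(),
    pdl1_score_type = readr::col_character(), msi = readr::col_character(),
    alterations = readr::col_character()), progress = FALSE)
  abort_cols(df, c("specimen_id", "tumor_type", "tmb", "alterations"),
             "cohort TSV")
  if (any(duplicated(df$specimen_id))) {
    stop("specimen_id values must be unique", call. = FALSE)
  }
  if (any(df$pdl1_score < 0 | df$pdl1_score > 100, na.rm = TRUE)) {
    stop("pdl1_score must lie in [0, 100]", call. = FALSE)
  }
  if (any(df$tmb < 0, na.rm = TRUE)) stop("tmb must be >= 0", call. = FALSE)
  df$alterations <- purrr::map(df$alterations, parse_alterations)
  df
}

parse_alterations <- function(x) {
  empty <- tibble::tibble(gene = character(), alteration_class = character(),
                          known_pathogenic = logical())
  if (is.na(x) || x == "") return(empty)
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- lengths(parts) != 3
  if (any(bad)) stop(sprintf("malformed alteration entry '%s'", x), call. = FALSE)
  tibble::tibble(
    gene = vapply(parts, `[`, "", 1),
    alteration_class = vapply(parts, `[`, "", 2),
    known_pathogenic = vapply(parts, `[`, "", 3) == "1")
}

format_alterations <- function(alt) {
  if (is.null(alt) || nrow(alt) == 0) return("")
  paste(sprintf("%s:%s:%d", alt$gene, alt$alteration_class,
                as.integer(alt$known_pathogenic)), collapse = ";")
}

#' Write a cohort specimen table
#'
#' Inverse of [read_cohort()]: the nested `alterations` list-column is
#' flattened back into its string encoding.
#'
#' @param cohort Specimen tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- cohort
  df$alterations <- vapply(df$alterations, format_alterations, "")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
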