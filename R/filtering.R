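#' Somatic-filter configuration
#'
#' Thresholds for the matched-normal exclusion filters applied to somatic
#' variant candidates. Defaults follow common practice for exome data:
#' a candidate fails if it falls in a segmental duplication; if the normal
#' shows any variant read; if the normal has fewer than ten reads in total;
#' if the tumor has fewer than eight reads in total; fewer than three
#' variant reads; or a variant allele fraction below 3%; if the variant is
#' seen in a population database above 2%; or in a local non-cancer cohort
#' at 5% or more (such recurrent variants are more likely systematic
#' artifacts than genuine somatic mutations).
#'
#' @param min_normal_total Minimum total reads in the normal (default 10).
#' @param max_normal_alt Maximum variant reads tolerated in the normal
#'   (default 0: any variant read in the normal excludes the candidate).
#' @param min_tumor_total Minimum total reads in the tumor (default 8).
#' @param min_tumor_alt Minimum variant reads in the tumor (default 3).
#' @param min_tumor_vaf Minimum tumor variant allele fraction (default 0.03);
#'   failure is strict (`vaf < min_tumor_vaf`).
#' @param max_population_freq Population-database frequency above which
#'   (strictly) a candidate fails (default 0.02).
#' @param max_local_cohort_freq Local-cohort frequency at or above which a
#'   candidate fails (default 0.05).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_normal_total = 10L, max_normal_alt = 0L,
                          min_tumor_total = 8L, min_tumor_alt = 3L,
                          min_tumor_vaf = 0.03, max_population_freq = 0.02,
                          max_local_cohort_freq = 0.05) {
  stopifnot(min_normal_total >= 0, max_normal_alt >= 0, min_tumor_total >= 0,
            min_tumor_alt >= 0)
  if (min_tumor_vaf < 0 || min_tumor_vaf > 1 ||
      max_population_freq < 0 || max_population_freq > 1 ||
      max_local_cohort_freq < 0 || max_local_cohort_freq > 1)
    stop("frequency thresholds must lie in [0, 1]")
  structure(list(min_normal_total = min_normal_total,
                 max_normal_alt = max_normal_alt,
                 min_tumor_total = min_tumor_total,
                 min_tumor_alt = min_tumor_alt,
                 min_tumor_vaf = min_tumor_vaf,
                 max_population_freq = max_population_freq,
                 max_local_cohort_freq = max_local_cohort_freq),
            class = "filter_config")
}

.variant_key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")

#' Classify a variant as germline or somatic from the matched normal
#'
#' A variant is germline if present in any read of the matched tumor-free
#' tissue, somatic otherwise. A single variant read in the normal therefore
#' makes the call germline; as a somatic candidate the same variant would
#' independently fail the normal-contamination exclusion filter.
#'
#' @param tumor_variant,normal_obs Single-row observation data.frames (or
#'   lists) with `chrom`, `pos`, `ref`, `alt`, `total_reads`, `alt_reads`,
#'   describing the same variant in tumor and matched normal.
#' @return `"germline"` or `"somatic"`.
#' @export
classify_origin <- function(tumor_variant, normal_obs) {
  if (!identical(.variant_key(tumor_variant), .variant_key(normal_obs)))
    stop("tumor and normal observations describe different variants")
  if (normal_obs$alt_reads > 0) "germline" else "somatic"
}

#' Apply the somatic exclusion filters to one candidate
#'
#' Evaluates all exclusion filters without short-circuiting, so the verdict
#' lists every reason that applies. A tumor observation with zero total
#' reads fails `tumor_low_depth` (its VAF is undefined, not an error).
#'
#' @param tumor_obs,normal_obs Observations of the same variant in tumor
#'   and matched normal (lists or single-row data.frames).
#' @param in_segdup Logical: does the site fall in a segmental duplication?
#' @param population_freq Population-database allele frequency, or `NULL`
#'   if the variant is absent from the resource (filter not applicable).
#' @param local_cohort_freq Local non-cancer cohort frequency, or `NULL`.
#' @param cfg A [filter_config()].
#' @return A list of class `filter_verdict` with `key`, `status`
#'   (`"pass"`/`"fail"`) and `reasons` (character vector; empty iff pass).
#' @export
apply_somatic_filters <- function(tumor_obs, normal_obs, in_segdup = FALSE,
                                  population_freq = NULL,
                                  local_cohort_freq = NULL,
                                  cfg = filter_config()) {
  if (!identical(.variant_key(tumor_obs), .variant_key(normal_obs)))
    stop("tumor and normal observations describe different variants")
  reasons <- character(0)
  if (isTRUE(in_segdup)) reasons <- c(reasons, "segdup")
  if (normal_obs$alt_reads > cfg$max_normal_alt)
    reasons <- c(reasons, "normal_alt_present")
  if (normal_obs$total_reads < cfg$min_normal_total)
    reasons <- c(reasons, "normal_low_depth")
  if (tumor_obs$total_reads < cfg$min_tumor_total)
    reasons <- c(reasons, "tumor_low_depth")
  if (tumor_obs$alt_reads < cfg$min_tumor_alt)
    reasons <- c(reasons, "tumor_few_alt_reads")
  if (tumor_obs$total_reads > 0 &&
      tumor_obs$alt_reads / tumor_obs$total_reads < cfg$min_tumor_vaf)
    reasons <- c(reasons, "tumor_low_vaf")
  if (!is.null(population_freq) && !is.na(population_freq) &&
      population_freq > cfg$max_population_freq)
    reasons <- c(reasons, "population_frequent")
  if (!is.null(local_cohort_freq) && !is.na(local_cohort_freq) &&
      local_cohort_freq >= cfg$max_local_cohort_freq)
    reasons <- c(reasons, "local_cohort_frequent")
  structure(list(key = .variant_key(tumor_obs),
                 status = if (length(reasons) == 0) "pass" else "fail",
                 reasons = reasons),
            class = "filter_verdict")
}

.in_bed <- function(chrom, pos, bed) {
  # bed: 0-based half-open intervals; pos: 1-based
  if (is.null(bed) || nrow(bed) == 0) return(rep(FALSE, length(chrom)))
  vapply(seq_along(chrom), function(i) {
    any(bed$chrom == chrom[i] & bed$start <= pos[i] - 1 & bed$end >= pos[i])
  }, TRUE)
}

.freq_lookup <- function(keys, freq_table) {
  if (is.null(freq_table) || nrow(freq_table) == 0)
    return(rep(NA_real_, length(keys)))
  tk <- paste(freq_table$chrom, freq_table$pos, freq_table$ref,
              freq_table$alt, sep = ":")
  freq_table$freq[match(keys, tk)]
}

#' Filter a full variant table against the matched normal
#'
#' Applies [apply_somatic_filters()] to every tumor-sample variant row. A
#' tumor variant with no matching normal observation is treated as 0/0 in
#' the normal and consequently fails `normal_low_depth`. Germline variants
#' (any variant read in the normal) fail `normal_alt_present` and so never
#' enter the somatic pass sets.
#'
#' @param variants Observation data.frame covering all samples (columns
#'   `sample_id`, `chrom`, `pos`, `ref`, `alt`, `total_reads`, `alt_reads`).
#' @param normal_sample Sample id of the matched normal within `variants`.
#' @param segdup_bed Optional data.frame of segmental-duplication intervals
#'   (`chrom`, `start`, `end`; 0-based half-open).
#' @param population_freq Optional frequency table (`chrom`, `pos`, `ref`,
#'   `alt`, `freq`); variants absent from it are not filtered on population
#'   frequency.
#' @param cohort_freq Optional local-cohort frequency table, same layout.
#' @param cfg A [filter_config()].
#' @return A list with `verdicts` (one row per tumor variant-sample pair:
#'   key fields, `status`, comma-joined `reasons`) and `pass_sets` (named
#'   list per tumor sample of passing variant keys `chrom:pos:ref:alt`).
#' @export
filter_variant_table <- function(variants, normal_sample = "N",
                                 segdup_bed = NULL, population_freq = NULL,
                                 cohort_freq = NULL, cfg = filter_config()) {
  key <- .variant_key(variants)
  if (anyDuplicated(paste(variants$sample_id, key)))
    stop("duplicate variant keys within a sample")
  normal <- variants[variants$sample_id == normal_sample, ]
  tumor <- variants[variants$sample_id != normal_sample, ]
  if (nrow(tumor) == 0)
    return(list(verdicts = data.frame(), pass_sets = list()))
  tkey <- .variant_key(tumor)
  nkey <- .variant_key(normal)
  m <- match(tkey, nkey)
  n_total <- ifelse(is.na(m), 0L, normal$total_reads[m])
  n_alt <- ifelse(is.na(m), 0L, normal$alt_reads[m])

  reasons <- vector("list", nrow(tumor))
  add <- function(cond, code) {
    for (i in which(cond)) reasons[[i]] <<- c(reasons[[i]], code)
  }
  add(.in_bed(tumor$chrom, tumor$pos, segdup_bed), "segdup")
  add(n_alt > cfg$max_normal_alt, "normal_alt_present")
  add(n_total < cfg$min_normal_total, "normal_low_depth")
  add(tumor$total_reads < cfg$min_tumor_total, "tumor_low_depth")
  add(tumor$alt_reads < cfg$min_tumor_alt, "tumor_few_alt_reads")
  vaf <- ifelse(tumor$total_reads > 0, tumor$alt_reads / tumor$total_reads, NA)
  add(!is.na(vaf) & vaf < cfg$min_tumor_vaf, "tumor_low_vaf")
  pf <- .freq_lookup(tkey, population_freq)
  add(!is.na(pf) & pf > cfg$max_population_freq, "population_frequent")
  cf <- .freq_lookup(tkey, cohort_freq)
  add(!is.na(cf) & cf >= cfg$max_local_cohort_freq, "local_cohort_frequent")

  n_reasons <- lengths(reasons)
  verdicts <- data.frame(
    sample_id = tumor$sample_id, chrom = tumor$chrom, pos = tumor$pos,
    ref = tumor$ref, alt = tumor$alt,
    status = ifelse(n_reasons == 0, "pass", "fail"),
    reasons = vapply(reasons, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  pass <- verdicts$status == "pass"
  pass_sets <- lapply(split(tkey[pass], tumor$sample_id[pass]), unique)
  # samples with no passing variant still get an (empty) set
  for (s in setdiff(unique(tumor$sample_id), names(pass_sets)))
    pass_sets[[s]] <- character(0)
  list(verdicts = verdicts, pass_sets = pass_sets)
}
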