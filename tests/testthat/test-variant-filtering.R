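test_that("germline/somatic classification follows presence in the normal", {
  t <- obs_row("T", alt_reads = 30L)
  expect_identical(classify_origin(t, obs_row("N", alt_reads = 5L)), "germline")
  expect_identical(classify_origin(t, obs_row("N", alt_reads = 0L)), "somatic")
  # a single normal read is enough for a germline call
  expect_identical(classify_origin(t, obs_row("N", alt_reads = 1L)), "germline")
  expect_error(classify_origin(t, obs_row("N", pos = 999)), "different variants")
})

test_that("each exclusion filter fires with its own reason code", {
  cfg <- filter_config()
  clean_n <- obs_row("N", total_reads = 50L, alt_reads = 0L)
  clean_t <- obs_row("T", total_reads = 300L, alt_reads = 30L)
  v <- apply_somatic_filters(clean_t, clean_n, cfg = cfg)
  expect_identical(v$status, "pass")
  expect_length(v$reasons, 0)

  expect_identical(
    apply_somatic_filters(clean_t, clean_n, in_segdup = TRUE, cfg = cfg)$reasons,
    "segdup")
  expect_identical(
    apply_somatic_filters(clean_t, obs_row("N", total_reads = 50L, alt_reads = 1L),
                          cfg = cfg)$reasons,
    "normal_alt_present")
  expect_identical(
    apply_somatic_filters(clean_t, obs_row("N", total_reads = 9L), cfg = cfg)$reasons,
    "normal_low_depth")
  expect_identical(
    apply_somatic_filters(obs_row("T", total_reads = 7L, alt_reads = 3L),
                          clean_n, cfg = cfg)$reasons,
    "tumor_low_depth")
  expect_identical(
    apply_somatic_filters(obs_row("T", total_reads = 40L, alt_reads = 2L),
                          clean_n, cfg = cfg)$reasons,
    "tumor_few_alt_reads")
  expect_identical(
    apply_somatic_filters(obs_row("T", total_reads = 200L, alt_reads = 4L),
                          clean_n, cfg = cfg)$reasons,
    "tumor_low_vaf")
  expect_identical(
    apply_somatic_filters(clean_t, clean_n, population_freq = 0.05, cfg = cfg)$reasons,
    "population_frequent")
  expect_identical(
    apply_somatic_filters(clean_t, clean_n, local_cohort_freq = 0.05, cfg = cfg)$reasons,
    "local_cohort_frequent")
})

test_that("boundary semantics match the stated thresholds", {
  cfg <- filter_config()
  clean_n <- obs_row("N", total_reads = 50L)
  # population frequency fails strictly above 2%
  expect_identical(
    apply_somatic_filters(obs_row("T", alt_reads = 30L), clean_n,
                          population_freq = 0.02, cfg = cfg)$status, "pass")
  # cohort frequency fails at exactly 5%
  expect_identical(
    apply_somatic_filters(obs_row("T", alt_reads = 30L), clean_n,
                          local_cohort_freq = 0.049, cfg = cfg)$status, "pass")
  # VAF of exactly 3% passes; alt reads exactly 3 pass
  expect_identical(
    apply_somatic_filters(obs_row("T", total_reads = 100L, alt_reads = 3L),
                          clean_n, cfg = cfg)$status, "pass")
  # zero tumor depth is a low-depth failure, not an exception
  v <- apply_somatic_filters(obs_row("T", total_reads = 0L, alt_reads = 0L),
                             clean_n, cfg = cfg)
  expect_true("tumor_low_depth" %in% v$reasons)
  expect_false("tumor_low_vaf" %in% v$reasons)
  # no short-circuit: several reasons accumulate
  v <- apply_somatic_filters(obs_row("T", total_reads = 7L, alt_reads = 0L),
                             obs_row("N", total_reads = 5L, alt_reads = 2L),
                             in_segdup = TRUE, cfg = cfg)
  expect_setequal(v$reasons, c("segdup", "normal_alt_present", "normal_low_depth",
                               "tumor_low_depth", "tumor_few_alt_reads",
                               "tumor_low_vaf"))
})

test_that("the bundled demo VCF trips filters one each and the clean variant passes", {
  dir <- system.file("extdata", package = "cnaphase")
  obs <- read_vcf_observations(file.path(dir, "filter_demo.vcf"))
  segdup <- utils::read.delim(file.path(dir, "segdup.bed"), header = FALSE,
                              col.names = c("chrom", "start", "end"),
                              colClasses = c("character", "numeric", "numeric"))
  pop <- utils::read.delim(file.path(dir, "popfreq.tsv"),
                           colClasses = c("character", "numeric", "character",
                                          "character", "numeric"))
  res <- filter_variant_table(obs, "N", segdup_bed = segdup,
                              population_freq = pop)
  v <- res$verdicts[order(res$verdicts$pos), ]
  expect_equal(v$status, c("fail", "fail", "fail", "fail", "fail", "fail", "pass"))
  expect_equal(v$reasons,
               c("segdup", "normal_alt_present", "normal_low_depth",
                 "tumor_low_depth", "tumor_few_alt_reads",
                 "population_frequent", ""))
  expect_identical(res$pass_sets[["T1R1"]], "1:7000:C:G")
})

test_that("filter_variant_table handles edge inputs", {
  # empty input
  empty <- data.frame(sample_id = character(0), chrom = character(0),
                      pos = numeric(0), ref = character(0), alt = character(0),
                      total_reads = integer(0), alt_reads = integer(0))
  res <- filter_variant_table(empty)
  expect_equal(nrow(res$verdicts), 0)
  expect_length(res$pass_sets, 0)
  # missing normal observation behaves as 0/0 and fails normal_low_depth
  one <- data.frame(sample_id = "T1", chrom = "1", pos = 5, ref = "A",
                    alt = "G", total_reads = 100L, alt_reads = 30L)
  res <- filter_variant_table(one, "N")
  expect_true(grepl("normal_low_depth", res$verdicts$reasons))
  # duplicate keys per sample are rejected
  dup <- rbind(one, one)
  expect_error(filter_variant_table(dup, "N"), "duplicate")
})

test_that("filtering recovers exactly the true somatic mutations on clean simulations", {
  cfg <- pair_config(21, same_homolog = TRUE, depth = 100,
                     somatic = somatic_params(trunk_mutations_per_tumor = 15L,
                                              private_mutations_per_region = 5L,
                                              trunk_detection_prob = 1,
                                              vaf_mean = 0.35,
                                              vaf_dispersion = 0.02))
  sim <- simulate_patient(cfg)
  res <- filter_variant_table(sim$observations, "N")
  truth <- sim$truth
  for (s in unique(truth$detected$sample_id)) {
    det_ids <- truth$detected$mut_id[truth$detected$sample_id == s]
    m <- truth$mutations[truth$mutations$mut_id %in% det_ids, ]
    truth_keys <- paste(m$chrom, m$pos, m$ref, m$alt, sep = ":")
    # with depth 100 and VAF ~0.35 every true mutation clears the read filters
    expect_setequal(res$pass_sets[[s]], truth_keys)
  }
})

test_that("filters are monotone in their thresholds and idempotent", {
  cfg <- pair_config(22, same_homolog = TRUE,
                     somatic = somatic_params(trunk_mutations_per_tumor = 20L,
                                              private_mutations_per_region = 5L,
                                              vaf_mean = 0.15,
                                              vaf_dispersion = 0.3))
  sim <- simulate_patient(cfg)
  base <- filter_variant_table(sim$observations, "N", cfg = filter_config())
  n_pass <- function(res) sum(lengths(res$pass_sets))
  # raising min_* thresholds never grows the pass set
  for (arg in c("min_normal_total", "min_tumor_total", "min_tumor_alt")) {
    args <- list(); args[[arg]] <- 30L
    stricter <- filter_variant_table(sim$observations, "N",
                                     cfg = do.call(filter_config, args))
    for (s in names(base$pass_sets))
      expect_true(all(stricter$pass_sets[[s]] %in% base$pass_sets[[s]]))
  }
  strict_vaf <- filter_variant_table(sim$observations, "N",
                                     cfg = filter_config(min_tumor_vaf = 0.2))
  expect_lte(n_pass(strict_vaf), n_pass(base))
  # raising the max_normal_alt tolerance never shrinks the pass set
  looser <- filter_variant_table(sim$observations, "N",
                                 cfg = filter_config(max_normal_alt = 5L))
  for (s in names(base$pass_sets))
    expect_true(all(base$pass_sets[[s]] %in% looser$pass_sets[[s]]))
  # idempotence: re-filtering the passing observations changes nothing
  obs <- sim$observations
  key <- paste(obs$chrom, obs$pos, obs$ref, obs$alt, sep = ":")
  keep <- obs$sample_id == "N" |
    mapply(function(s, k) k %in% base$pass_sets[[s]], obs$sample_id, key)
  again <- filter_variant_table(obs[keep, ], "N", cfg = filter_config())
  expect_equal(again$pass_sets[order(names(again$pass_sets))],
               base$pass_sets[order(names(base$pass_sets))])
})
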