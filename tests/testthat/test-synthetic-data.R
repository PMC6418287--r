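test_that("het-site generation is seeded-deterministic and respects the genome", {
  cfg <- simulation_config(seed = 7, genome = c("1" = 5e6, "2" = 3e6),
                           het_site_density = 10)
  a <- simulate_het_sites(cfg)
  b <- simulate_het_sites(cfg)
  expect_identical(a, b)
  expect_true(all(a$chrom %in% c("1", "2")))
  # positions unique and sorted within chromosome, inside the chromosome
  for (chr in unique(a$chrom)) {
    p <- a$pos[a$chrom == chr]
    expect_false(is.unsorted(p, strictly = TRUE))
    expect_true(all(p >= 1 & p <= cfg$genome[[chr]]))
  }
  expect_true(all(a$alt_homolog %in% c("A", "B")))
})

test_that("het-site counts follow the Poisson expectation", {
  # density 10/Mb on a 100 Mb chromosome: mean count 1000
  counts <- vapply(1:200, function(s) {
    cfg <- simulation_config(seed = s, genome = c("1" = 1e8),
                             het_site_density = 10)
    nrow(simulate_het_sites(cfg))
  }, 0L)
  se <- sqrt(1000 / 200)  # Poisson var = mean
  expect_lt(abs(mean(counts) - 1000), 3 * se)
})

test_that("zero-length chromosomes and invalid densities are rejected", {
  expect_error(simulation_config(genome = c("1" = 0)), "zero-length")
  expect_error(simulation_config(het_site_density = 0), "het_site_density")
  expect_error(simulation_config(purity_per_region = 1.2), "purity")
})

test_that("expected_vaf implements the purity-mixture model", {
  loss_A <- cna_spec(1, "1", 0, 1e6, "A", 0)
  gain_A <- cna_spec(1, "1", 0, 1e6, "A", 2)
  # pure normal: always 0.5
  expect_equal(expected_vaf("A", loss_A, 0), 0.5)
  expect_equal(expected_vaf("B", gain_A, 0), 0.5)
  # pure tumor, loss of the ALT-carrying homolog: AF 0
  expect_equal(expected_vaf("A", loss_A, 1), 0)
  # purity 0.6, loss of the non-ALT homolog: hand-evaluated mixture
  expect_equal(expected_vaf("B", loss_A, 0.6), (0.6 + 0.4) / (0.6 + 0.8))
  # diploid site: 0.5 at any purity
  expect_equal(expected_vaf("A", NULL, 0.73), 0.5)
  expect_error(expected_vaf("C", NULL, 0.5), "alt_homolog")
  expect_error(expected_vaf("A", NULL, 1.5))
})

test_that("read-count sampling matches its binomial expectation and bounds", {
  set.seed(1)
  x <- sample_read_counts(rep(0, 100), 50)
  expect_true(all(x$alt_reads == 0))
  x <- sample_read_counts(rep(1, 100), 50)
  expect_true(all(x$alt_reads == x$total_reads))
  x <- sample_read_counts(rep(0.5, 10000), 100)
  expect_true(all(x$total_reads >= 1))
  expect_true(all(x$alt_reads >= 0 & x$alt_reads <= x$total_reads))
  af <- mean(x$alt_reads / x$total_reads)
  se <- sqrt(0.25 / 100) / sqrt(10000)  # per-draw AF sd at depth ~100, over 10k draws
  expect_lt(abs(af - 0.5), 3 * se)
})

test_that("simulate_patient is deterministic and conserves read-count bounds", {
  cfg <- pair_config(11, same_homolog = TRUE)
  a <- simulate_patient(cfg)
  b <- simulate_patient(cfg)
  expect_identical(a$observations, b$observations)
  expect_identical(a$truth, b$truth)
  expect_true(all(a$observations$alt_reads >= 0))
  expect_true(all(a$observations$alt_reads <= a$observations$total_reads))
})

test_that("multi-centric scenario shares no somatic keys across tumors", {
  cfg <- pair_config(3, same_homolog = TRUE,
                     somatic = somatic_params(trunk_mutations_per_tumor = 20L,
                                              private_mutations_per_region = 5L,
                                              cross_tumor_shared = 0L))
  sim <- simulate_patient(cfg)
  m <- sim$truth$mutations
  expect_equal(nrow(m), 2 * 20 + 2 * 5)
  keys_t1 <- m$mut_id[!is.na(m$tumor_id) & m$tumor_id == 1]
  keys_t2 <- m$mut_id[!is.na(m$tumor_id) & m$tumor_id == 2]
  expect_length(intersect(keys_t1, keys_t2), 0)
  expect_identical(sim$truth$scenario, "multi-centric")
})

test_that("metastasis scenario shares exactly k keys before thinning", {
  cfg <- pair_config(4, same_homolog = TRUE,
                     somatic = somatic_params(trunk_mutations_per_tumor = 5L,
                                              private_mutations_per_region = 2L,
                                              cross_tumor_shared = 7L))
  sim <- simulate_patient(cfg)
  expect_equal(sum(sim$truth$mutations$class == "shared"), 7)
  expect_identical(sim$truth$scenario, "metastasis")
})

test_that("high-purity deep sequencing separates the homologs cleanly", {
  # purity 1, depth 10000, one-copy loss of homolog A: expected AF is 0 for
  # ALT-on-A sites and 1 for ALT-on-B sites; binomial noise cannot cross 0.5
  cfg <- pair_config(5, same_homolog = TRUE, purity = 1, depth = 10000)
  sim <- simulate_patient(cfg)
  obs <- sim$observations
  t1 <- obs[obs$sample_id == "T1R1", ]
  het <- sim$truth$het_sites
  m <- match(paste(het$chrom, het$pos), paste(t1$chrom, t1$pos))
  af <- t1$alt_reads[m] / t1$total_reads[m]
  expect_true(all(af[het$alt_homolog == "A"] < 0.5))
  expect_true(all(af[het$alt_homolog == "B"] > 0.5))
})

test_that("normal-sample AFs at het sites center on 0.5 and CNA sites on expected_vaf", {
  cfg <- pair_config(6, same_homolog = TRUE, mean_sites = 200)
  sim <- simulate_patient(cfg)
  obs <- sim$observations
  n <- obs[obs$sample_id == "N", ]
  het <- sim$truth$het_sites
  m <- match(paste(het$chrom, het$pos), paste(n$chrom, n$pos))
  af_n <- n$alt_reads[m] / n$total_reads[m]
  expect_lt(abs(mean(af_n) - 0.5), 3 * sqrt(0.25 / 100) / sqrt(length(af_n)))
  # tumor 1: loss of A at purity 0.8; ALT-on-B sites expect 1/1.2
  t1 <- obs[obs$sample_id == "T1R1", ]
  m1 <- match(paste(het$chrom, het$pos), paste(t1$chrom, t1$pos))
  af_b <- (t1$alt_reads[m1] / t1$total_reads[m1])[het$alt_homolog == "B"]
  exp_b <- expected_vaf("B", cna_spec(1, "1", 0, 1e7, "A", 0), 0.8)
  expect_lt(abs(mean(af_b) - exp_b), 4 * sqrt(exp_b * (1 - exp_b) / 100) / sqrt(length(af_b)))
})

test_that("overlapping CNA specs for one tumor are rejected", {
  cfg <- simulation_config(
    seed = 1, genome = c("1" = 1e7),
    cna_specs = list(cna_spec(1, "1", 0, 5e6, "A", 0),
                     cna_spec(1, "1", 4e6, 9e6, "B", 2)))
  expect_error(simulate_patient(cfg), "overlapping")
})

test_that("truth bundles round-trip through JSON losslessly", {
  cfg <- pair_config(9, same_homolog = FALSE,
                     somatic = somatic_params(trunk_mutations_per_tumor = 3L,
                                              private_mutations_per_region = 1L))
  truth <- simulate_patient(cfg)$truth
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(truth, path)
  back <- read_truth(path)
  for (el in c("scenario", "patient")) expect_identical(back[[el]], truth[[el]])
  for (el in c("het_sites", "cna_specs", "mutations", "detected", "region_map")) {
    expect_equal(as.data.frame(back[[el]]), as.data.frame(truth[[el]]),
                 ignore_attr = TRUE)
  }
  # empty truth round-trips too
  cfg0 <- simulation_config(seed = 2, genome = c("1" = 1e6),
                            het_site_density = 0.001,
                            somatic_params = somatic_params(
                              trunk_mutations_per_tumor = 0L,
                              private_mutations_per_region = 0L))
  t0 <- simulate_patient(cfg0)$truth
  write_truth(t0, path)
  b0 <- read_truth(path)
  expect_equal(nrow(b0$mutations), 0)
  expect_equal(as.data.frame(b0$cna_specs), as.data.frame(t0$cna_specs),
               ignore_attr = TRUE)
})

test_that("VCF and SEG emission round-trip the observation and segment tables", {
  cfg <- pair_config(10, same_homolog = TRUE,
                     somatic = somatic_params(trunk_mutations_per_tumor = 4L,
                                              private_mutations_per_region = 2L))
  sim <- simulate_patient(cfg)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_patient_vcf(sim$observations, vcf, genome = cfg$genome)
  back <- read_vcf_observations(vcf)
  key <- function(d) paste(d$sample_id, d$chrom, d$pos, d$ref, d$alt,
                           d$total_reads, d$alt_reads)
  expect_setequal(key(back), key(sim$observations))
  expect_equal(attr(back, "contig_lengths"), c("1" = 1e7))
  seg <- withr::local_tempfile(fileext = ".seg")
  write_seg(sim$segments, seg)
  expect_equal(read_seg(seg), sim$segments, ignore_attr = TRUE)
  # same seed twice: byte-identical VCF
  vcf2 <- withr::local_tempfile(fileext = ".vcf")
  write_patient_vcf(simulate_patient(cfg)$observations, vcf2, genome = cfg$genome)
  expect_identical(readLines(vcf), readLines(vcf2))
})
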