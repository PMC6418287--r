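# Shared fixtures: tumor-pair simulations with a one-copy loss of a known
# homolog in each tumor, and a minimal observation builder.

# Config for two single-region tumors with a whole-chromosome one-copy loss:
# tumor 1 always loses homolog A; tumor 2 loses A (same_homolog = TRUE) or B.
pair_config <- function(seed, same_homolog, purity = 0.8, depth = 100,
                        mean_sites = 50, chrom_len = 1e7,
                        somatic = somatic_params(trunk_mutations_per_tumor = 0L,
                                                 private_mutations_per_region = 0L)) {
  simulation_config(
    seed = seed, tumors_per_patient = 2L, regions_per_tumor = 1L,
    purity_per_region = purity, mean_depth = depth,
    het_site_density = mean_sites / (chrom_len / 1e6),
    genome = c("1" = chrom_len),
    cna_specs = list(
      cna_spec(1L, "1", 0, chrom_len, "A", 0L),
      cna_spec(2L, "1", 0, chrom_len, if (same_homolog) "A" else "B", 0L)),
    somatic_params = somatic)
}

# Simulate a pair and return the deltas table ready for the concordance test.
pair_deltas <- function(seed, same_homolog, purity = 0.8, depth = 100,
                        mean_sites = 50, cfg_phase = phasing_config()) {
  cfg <- pair_config(seed, same_homolog, purity = purity, depth = depth,
                     mean_sites = mean_sites)
  sim <- simulate_patient(cfg)
  obs <- sim$observations
  sites <- select_polymorphic_sites(obs[obs$sample_id == "N", ],
                                    list(chrom = "1", start = 0, end = 1e7),
                                    cfg_phase)
  list(deltas = compute_deltas(sites, obs[obs$sample_id != "N", ],
                               sim$truth$region_map, cfg_phase),
       truth = sim$truth, observations = obs)
}

# One observation row as a list (for the scalar filter/classification ops).
obs_row <- function(sample_id = "T", chrom = "1", pos = 100, ref = "A",
                    alt = "G", total_reads = 100L, alt_reads = 0L) {
  list(sample_id = sample_id, chrom = chrom, pos = pos, ref = ref, alt = alt,
       total_reads = total_reads, alt_reads = alt_reads)
}

# Random mutation-key sets for recall oracle tests.
random_key_sets <- function(n_sets, max_keys = 20, pool = 40) {
  keys <- sprintf("1:%d:A:G", seq_len(pool))
  lapply(seq_len(n_sets), function(i)
    region_variant_set("P", (i + 1) %/% 2, i,
                       sample(keys, sample.int(max_keys, 1))))
}

# Study-layout demo: three tumors per patient, candidate losses shared by
# tumors 1 and 2 on chromosomes 17, 8 and 21 sitting on different homologs,
# and a terminal 6q loss on the same homolog whose proximal breakpoints
# differ by 10 Mb.
demo_sim_config <- function(n_patients = 1, seed = 99) {
  list(
    seed = seed, n_patients = n_patients, tumors_per_patient = 3,
    regions_per_tumor = 2, purity_per_region = 0.8, mean_depth = 100,
    het_site_density = 2,
    genome = list("6" = 171115067, "8" = 146364022, "17" = 81195210,
                  "21" = 48129895),
    cna_specs = list(
      list(tumor_id = 1, chrom = "17", start = 0, end = 22e6,
           affected_homolog = "A", homolog_copies = 0),
      list(tumor_id = 2, chrom = "17", start = 0, end = 22e6,
           affected_homolog = "B", homolog_copies = 0),
      list(tumor_id = 1, chrom = "8", start = 100e6, end = 146364022,
           affected_homolog = "A", homolog_copies = 0),
      list(tumor_id = 2, chrom = "8", start = 100e6, end = 146364022,
           affected_homolog = "B", homolog_copies = 0),
      list(tumor_id = 1, chrom = "21", start = 15e6, end = 48129895,
           affected_homolog = "A", homolog_copies = 0),
      list(tumor_id = 2, chrom = "21", start = 15e6, end = 48129895,
           affected_homolog = "B", homolog_copies = 0),
      list(tumor_id = 1, chrom = "6", start = 120e6, end = 171115067,
           affected_homolog = "A", homolog_copies = 0),
      list(tumor_id = 2, chrom = "6", start = 130e6, end = 171115067,
           affected_homolog = "A", homolog_copies = 0)),
    somatic_params = list(trunk_mutations_per_tumor = 30,
                          private_mutations_per_region = 8,
                          trunk_detection_prob = 0.8, cross_tumor_shared = 0,
                          vaf_mean = 0.25, vaf_dispersion = 0.1))
}
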