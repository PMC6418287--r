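#' Simulation configuration
#'
#' Describes one simulated patient cohort: genome, heterozygous-site density,
#' sequencing depth, tumor/region layout, purity, copy-number alterations and
#' somatic mutation structure. All downstream generator output is a pure
#' function of this object (including its `seed`).
#'
#' @param seed Integer seed; fixes all generator randomness.
#' @param n_patients Number of patients to simulate.
#' @param tumors_per_patient Number of synchronous tumors per patient.
#' @param regions_per_tumor Number of sampled regions per tumor.
#' @param purity_per_region Tumor-cell fraction of each region in `[0, 1]`;
#'   recycled across regions. Defaults to 0.8, matching a pathology check
#'   that sampled tumor tissue contains at least 80% tumor cells.
#' @param mean_depth Mean sequencing depth (Poisson mean), in reads.
#' @param het_site_density Germline heterozygous sites per megabase.
#' @param genome Named numeric vector of chromosome lengths in bp. The
#'   default covers the four chromosomes that typically carry candidate
#'   arm-scale events in this analysis (6, 8, 17, 21; GRCh37 lengths).
#' @param cna_specs List of [cna_spec()] objects.
#' @param somatic_params A [somatic_params()] object.
#' @param breakpoint_jitter_bp Half-width of uniform jitter added to emitted
#'   segment breakpoints (bp). 0 (default) emits exact simulated breakpoints.
#' @param error_rate Per-read sequencing error rate folded into the expected
#'   allele fraction; default 0 keeps the noise model purely
#'   Poisson-depth/binomial-allele and analytically checkable.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_patients = 1L,
                              tumors_per_patient = 3L,
                              regions_per_tumor = 3L,
                              purity_per_region = 0.8,
                              mean_depth = 118,
                              het_site_density = 2,
                              genome = c("6" = 171115067, "8" = 146364022,
                                         "17" = 81195210, "21" = 48129895),
                              cna_specs = list(),
                              somatic_params = cnaphase::somatic_params(),
                              breakpoint_jitter_bp = 0,
                              error_rate = 0) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (length(genome) == 0L || is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("genome must be a named vector of chromosome lengths")
  if (any(genome <= 0)) stop("zero-length chromosome in genome")
  if (anyDuplicated(names(genome))) stop("duplicate chromosome names in genome")
  stopifnot(n_patients >= 1, tumors_per_patient >= 1, regions_per_tumor >= 1)
  if (het_site_density <= 0) stop("het_site_density must be > 0")
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (any(purity_per_region < 0 | purity_per_region > 1))
    stop("purity_per_region must lie in [0, 1]")
  if (error_rate < 0 || error_rate > 1) stop("error_rate must lie in [0, 1]")
  if (breakpoint_jitter_bp < 0) stop("breakpoint_jitter_bp must be >= 0")
  for (cs in cna_specs) {
    if (!inherits(cs, "cna_spec")) stop("cna_specs must be a list of cna_spec objects")
    if (!cs$chrom %in% names(genome))
      stop("cna_spec chromosome '", cs$chrom, "' not in genome")
    if (cs$end > genome[[cs$chrom]]) stop("cna_spec extends beyond chromosome end")
    if (cs$tumor_id > tumors_per_patient) stop("cna_spec tumor_id out of range")
  }
  structure(list(
    seed = as.integer(seed), n_patients = as.integer(n_patients),
    tumors_per_patient = as.integer(tumors_per_patient),
    regions_per_tumor = as.integer(regions_per_tumor),
    purity_per_region = purity_per_region, mean_depth = mean_depth,
    het_site_density = het_site_density, genome = genome,
    cna_specs = cna_specs, somatic_params = somatic_params,
    breakpoint_jitter_bp = breakpoint_jitter_bp, error_rate = error_rate
  ), class = "simulation_config")
}

#' Copy-number alteration specification
#'
#' One simulated gain or loss, assigned to a specific parental homolog.
#' Coordinates are 0-based half-open; the emitted SEG file converts to
#' 1-based inclusive at the boundary.
#'
#' @param tumor_id Integer index of the tumor carrying the event.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval in bp, `start < end`.
#' @param affected_homolog `"A"` or `"B"`: which parental homolog the event hits.
#' @param homolog_copies Tumor copy number of the affected homolog: 0 is a
#'   one-copy loss, 2 a one-copy gain. 1 would be no event and is rejected.
#'   The unaffected homolog stays at one copy.
#'
#' @return An object of class `cna_spec`.
#' @export
cna_spec <- function(tumor_id, chrom, start, end, affected_homolog,
                     homolog_copies) {
  stopifnot(start < end, start >= 0)
  if (!affected_homolog %in% c("A", "B"))
    stop("affected_homolog must be 'A' or 'B'")
  if (homolog_copies == 1) stop("homolog_copies = 1 is no event")
  if (homolog_copies < 0) stop("homolog_copies must be >= 0")
  structure(list(tumor_id = as.integer(tumor_id), chrom = as.character(chrom),
                 start = as.numeric(start), end = as.numeric(end),
                 affected_homolog = affected_homolog,
                 homolog_copies = as.integer(homolog_copies)),
            class = "cna_spec")
}

#' Somatic mutation parameters for the simulator
#'
#' Controls the clonal structure of simulated somatic SNVs: truncal
#' mutations shared by all regions of one tumor, region-private mutations,
#' and (for the metastasis scenario) mutations shared across tumors.
#'
#' @param trunk_mutations_per_tumor Truncal SNVs per tumor, present in every
#'   region of that tumor subject to `trunk_detection_prob`.
#' @param private_mutations_per_region SNVs private to a single region.
#' @param trunk_detection_prob Probability that a truncal (or cross-tumor
#'   shared) mutation is detected in a given region; models the incomplete
#'   within-tumor recall seen in multi-region sequencing.
#' @param cross_tumor_shared Number of SNVs shared by all tumors of the
#'   patient. 0 gives the multi-centric scenario (independent primaries),
#'   > 0 the metastasis scenario (clonally related tumors).
#' @param vaf_mean,vaf_dispersion Mean and dispersion (0, 1) of the beta
#'   distribution from which true somatic variant allele fractions are
#'   drawn; defaults mimic the low-VAF spread typical of these tumors.
#'
#' @return An object of class `somatic_params`.
#' @export
somatic_params <- function(trunk_mutations_per_tumor = 30L,
                           private_mutations_per_region = 10L,
                           trunk_detection_prob = 0.8,
                           cross_tumor_shared = 0L,
                           vaf_mean = 0.2, vaf_dispersion = 0.1) {
  stopifnot(trunk_mutations_per_tumor >= 0, private_mutations_per_region >= 0,
            cross_tumor_shared >= 0)
  if (trunk_detection_prob < 0 || trunk_detection_prob > 1)
    stop("trunk_detection_prob must lie in [0, 1]")
  if (vaf_mean <= 0 || vaf_mean >= 1) stop("vaf_mean must lie in (0, 1)")
  if (vaf_dispersion <= 0 || vaf_dispersion >= 1)
    stop("vaf_dispersion must lie in (0, 1)")
  structure(list(trunk_mutations_per_tumor = as.integer(trunk_mutations_per_tumor),
                 private_mutations_per_region = as.integer(private_mutations_per_region),
                 trunk_detection_prob = trunk_detection_prob,
                 cross_tumor_shared = as.integer(cross_tumor_shared),
                 vaf_mean = vaf_mean, vaf_dispersion = vaf_dispersion),
            class = "somatic_params")
}
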