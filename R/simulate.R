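#' Simulate germline heterozygous sites with phase
#'
#' Site counts per chromosome are Poisson with mean
#' `het_site_density * length / 1e6`; positions are uniform, unique and
#' sorted. Each site's alternate allele is placed on parental homolog A or B
#' by a fair coin — this phase is the ground truth the phasing test must
#' recover.
#'
#' @param config A [simulation_config()]. The configuration seed is applied,
#'   so repeated calls are identical.
#' @return A data.frame with columns `chrom`, `pos` (1-based), `alt_homolog`.
#' @export
simulate_het_sites <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  .sim_het_sites(config)
}

.sim_het_sites <- function(config) {
  out <- lapply(names(config$genome), function(chrom) {
    len <- config$genome[[chrom]]
    n <- stats::rpois(1L, config$het_site_density * len / 1e6)
    n <- min(n, len)
    pos <- sort(sample.int(len, n))
    data.frame(chrom = rep(chrom, n), pos = pos,
               alt_homolog = sample(c("A", "B"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Expected allele fraction of a heterozygous site under purity mixing
#'
#' A tumor sample is modelled as a mixture of tumor cells (fraction
#' `purity`) and normal cells. A heterozygous site contributes one ALT copy
#' per normal cell; in tumor cells its ALT copy number depends on whether a
#' copy-number event hit the homolog carrying the ALT allele. The expected
#' allele fraction is
#' `(purity * c_alt + (1 - purity)) / (purity * (c_A + c_B) + 2 * (1 - purity))`
#' where `c_alt` is the tumor copy number of the ALT-carrying homolog and
#' `c_A + c_B` the total tumor copy number at the site.
#'
#' @param alt_homolog `"A"` or `"B"`: homolog carrying the ALT allele.
#' @param spec A [cna_spec()] covering the site, or `NULL` for a diploid
#'   site (both homologs at one copy).
#' @param purity Tumor-cell fraction in `[0, 1]`.
#' @return Expected allele fraction in `[0, 1]`.
#' @export
expected_vaf <- function(alt_homolog, spec = NULL, purity) {
  stopifnot(purity >= 0, purity <= 1)
  if (!alt_homolog %in% c("A", "B")) stop("alt_homolog must be 'A' or 'B'")
  copies <- c(A = 1, B = 1)
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "cna_spec"))
    copies[spec$affected_homolog] <- spec$homolog_copies
  }
  c_alt <- copies[[alt_homolog]]
  denom <- purity * sum(copies) + (1 - purity) * 2
  if (denom == 0)
    stop("degenerate site: zero total copy number at purity 1 (homozygous deletion)")
  (purity * c_alt + (1 - purity) * 1) / denom
}

#' Sample read counts at a site
#'
#' Total depth is Poisson(`mean_depth`) truncated at >= 1 read; ALT reads
#' are Binomial(total, `expected_af`). Vectorized over `expected_af`.
#'
#' @param expected_af Expected allele fraction(s) in `[0, 1]`.
#' @param mean_depth Poisson mean depth, > 0.
#' @param n Number of draws; defaults to `length(expected_af)`.
#' @return A data.frame with columns `alt_reads`, `total_reads`.
#' @export
sample_read_counts <- function(expected_af, mean_depth, n = length(expected_af)) {
  stopifnot(mean_depth > 0, all(expected_af >= 0), all(expected_af <= 1))
  expected_af <- rep_len(expected_af, n)
  total <- stats::rpois(n, mean_depth)
  while (any(zero <- total == 0L))
    total[zero] <- stats::rpois(sum(zero), mean_depth)
  alt <- stats::rbinom(n, total, expected_af)
  data.frame(alt_reads = alt, total_reads = total)
}

.apply_error <- function(af, error_rate) {
  if (error_rate == 0) return(af)
  af * (1 - error_rate) + (1 - af) * error_rate
}

# Draw n unique genome positions (chrom, pos) avoiding the keys in `taken`.
.draw_positions <- function(genome, n, taken_keys) {
  chroms <- names(genome)
  out_chrom <- character(0); out_pos <- numeric(0)
  while (length(out_pos) < n) {
    need <- n - length(out_pos)
    ci <- sample.int(length(genome), need, replace = TRUE,
                     prob = genome / sum(genome))
    pos <- floor(stats::runif(need, 0, genome[ci])) + 1
    key <- paste(chroms[ci], pos, sep = ":")
    ok <- !key %in% taken_keys & !duplicated(key)
    taken_keys <- c(taken_keys, key[ok])
    out_chrom <- c(out_chrom, chroms[ci][ok])
    out_pos <- c(out_pos, pos[ok])
  }
  data.frame(chrom = out_chrom, pos = out_pos, stringsAsFactors = FALSE)
}

.sample_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- bases[sample.int(4L, n, replace = TRUE)]
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  data.frame(ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
}

#' Simulate one patient's multi-region tumor observations
#'
#' Emits a matched normal plus one sample per tumor region. Every germline
#' heterozygous site is observed in every sample (expected allele fraction
#' 0.5 in the normal, purity/copy-number adjusted in tumor regions); every
#' somatic mutation is observed with its true VAF in the regions that carry
#' and detect it, and with expected allele fraction 0 elsewhere. Copy-number
#' segments are emitted per tumor with the exact simulated breakpoints
#' (optionally jittered). The returned truth records the phase of every
#' heterozygous site, the homolog of every CNA, and the per-region somatic
#' assignments, so that every downstream stage can be checked against it.
#'
#' @param config A [simulation_config()].
#' @param patient Patient index (1-based); patient `p` uses seed
#'   `config$seed + p - 1`, so patients are independent but reproducible.
#' @return A list of class `cnaphase_sim` with elements `observations`
#'   (data.frame: `sample_id`, `chrom`, `pos`, `ref`, `alt`, `total_reads`,
#'   `alt_reads`), `segments` (data.frame: `sample_id`, `chrom`, `start`,
#'   `end` 0-based half-open, `n_probes`, `state`), and `truth` (see
#'   [write_truth()]).
#' @export
simulate_patient <- function(config, patient = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  sp <- config$somatic_params
  # reject overlapping CNA specs within a tumor
  for (t in unique(vapply(config$cna_specs, `[[`, 1L, "tumor_id"))) {
    specs <- Filter(function(s) s$tumor_id == t, config$cna_specs)
    for (i in seq_along(specs)) for (j in seq_len(i - 1L)) {
      a <- specs[[i]]; b <- specs[[j]]
      if (a$chrom == b$chrom && a$start < b$end && b$start < a$end)
        stop("overlapping cna_specs for tumor ", t)
    }
  }
  set.seed(config$seed + as.integer(patient) - 1L)

  n_tum <- config$tumors_per_patient
  n_reg <- config$regions_per_tumor
  region_map <- data.frame(
    sample_id = paste0("T", rep(seq_len(n_tum), each = n_reg),
                       "R", rep(seq_len(n_reg), n_tum)),
    tumor_id = rep(seq_len(n_tum), each = n_reg),
    region_id = rep(seq_len(n_reg), n_tum),
    stringsAsFactors = FALSE)
  purity <- rep_len(config$purity_per_region, nrow(region_map))
  region_map$purity <- purity

  het <- .sim_het_sites(config)
  het_keys <- paste(het$chrom, het$pos, sep = ":")

  # somatic mutation catalog: disjoint position pools guarantee that
  # mutations shared across tumors occur only by design, never by collision
  n_trunk <- n_tum * sp$trunk_mutations_per_tumor
  n_priv <- nrow(region_map) * sp$private_mutations_per_region
  n_shared <- sp$cross_tumor_shared
  n_mut <- n_trunk + n_priv + n_shared
  muts <- if (n_mut > 0) {
    loc <- .draw_positions(config$genome, n_mut, het_keys)
    al <- .sample_alleles(n_mut)
    shape_k <- 1 / sp$vaf_dispersion - 1
    data.frame(
      mut_id = paste0("m", seq_len(n_mut)), chrom = loc$chrom, pos = loc$pos,
      ref = al$ref, alt = al$alt,
      class = c(rep("trunk", n_trunk), rep("private", n_priv),
                rep("shared", n_shared)),
      tumor_id = c(rep(seq_len(n_tum), each = sp$trunk_mutations_per_tumor),
                   region_map$tumor_id[rep(seq_len(nrow(region_map)),
                                           each = sp$private_mutations_per_region)],
                   rep(NA_integer_, n_shared)),
      region_id = c(rep(NA_integer_, n_trunk),
                    region_map$region_id[rep(seq_len(nrow(region_map)),
                                             each = sp$private_mutations_per_region)],
                    rep(NA_integer_, n_shared)),
      true_vaf = stats::rbeta(n_mut, sp$vaf_mean * shape_k,
                              (1 - sp$vaf_mean) * shape_k),
      stringsAsFactors = FALSE)
  } else {
    data.frame(mut_id = character(0), chrom = character(0), pos = numeric(0),
               ref = character(0), alt = character(0), class = character(0),
               tumor_id = integer(0), region_id = integer(0),
               true_vaf = numeric(0), stringsAsFactors = FALSE)
  }

  # detection: which mutation is observed (expected AF = true VAF) per region
  detected <- do.call(rbind, lapply(seq_len(nrow(region_map)), function(i) {
    rm <- region_map[i, ]
    pres <- (muts$class == "private" & muts$tumor_id == rm$tumor_id &
               muts$region_id == rm$region_id) |
      (muts$class == "trunk" & muts$tumor_id == rm$tumor_id &
         stats::runif(nrow(muts)) < sp$trunk_detection_prob) |
      (muts$class == "shared" &
         stats::runif(nrow(muts)) < sp$trunk_detection_prob)
    if (!any(pres)) return(NULL)
    data.frame(sample_id = rm$sample_id, mut_id = muts$mut_id[pres],
               stringsAsFactors = FALSE)
  }))
  if (is.null(detected))
    detected <- data.frame(sample_id = character(0), mut_id = character(0),
                           stringsAsFactors = FALSE)

  specs_by_tumor <- split(config$cna_specs,
                          vapply(config$cna_specs, `[[`, 1L, "tumor_id"))
  spec_for_site <- function(tumor_id, chrom, pos) {
    for (s in specs_by_tumor[[as.character(tumor_id)]])
      if (s$chrom == chrom && pos - 1 >= s$start && pos - 1 < s$end) return(s)
    NULL
  }

  obs <- vector("list", nrow(region_map) + 1L)
  # matched normal
  n_af <- c(rep(0.5, nrow(het)), rep(0, nrow(muts)))
  cnts <- sample_read_counts(.apply_error(n_af, config$error_rate),
                             config$mean_depth)
  obs[[1L]] <- data.frame(
    sample_id = rep("N", nrow(het) + nrow(muts)),
    chrom = c(het$chrom, muts$chrom), pos = c(het$pos, muts$pos),
    ref = c(rep("A", nrow(het)), muts$ref),
    alt = c(rep("G", nrow(het)), muts$alt),
    total_reads = cnts$total_reads, alt_reads = cnts$alt_reads,
    stringsAsFactors = FALSE)
  # het sites in the normal use fixed placeholder alleles
  for (i in seq_len(nrow(region_map))) {
    rm <- region_map[i, ]
    het_af <- vapply(seq_len(nrow(het)), function(k) {
      expected_vaf(het$alt_homolog[k],
                   spec_for_site(rm$tumor_id, het$chrom[k], het$pos[k]),
                   purity[i])
    }, 0)
    det <- muts$mut_id %in% detected$mut_id[detected$sample_id == rm$sample_id]
    mut_af <- ifelse(det, muts$true_vaf, 0)
    af <- .apply_error(c(het_af, mut_af), config$error_rate)
    cnts <- sample_read_counts(af, config$mean_depth)
    obs[[i + 1L]] <- data.frame(
      sample_id = rep(rm$sample_id, nrow(het) + nrow(muts)),
      chrom = c(het$chrom, muts$chrom), pos = c(het$pos, muts$pos),
      ref = c(rep("A", nrow(het)), muts$ref),
      alt = c(rep("G", nrow(het)), muts$alt),
      total_reads = cnts$total_reads, alt_reads = cnts$alt_reads,
      stringsAsFactors = FALSE)
  }
  observations <- do.call(rbind, obs)

  segments <- if (length(config$cna_specs) > 0) {
    do.call(rbind, lapply(config$cna_specs, function(s) {
      start <- s$start; end <- s$end
      if (config$breakpoint_jitter_bp > 0) {
        j <- config$breakpoint_jitter_bp
        start <- max(0, start + round(stats::runif(1, -j, j)))
        end <- min(config$genome[[s$chrom]], end + round(stats::runif(1, -j, j)))
      }
      n_probes <- sum(het$chrom == s$chrom & het$pos - 1 >= s$start &
                        het$pos - 1 < s$end)
      data.frame(sample_id = paste0("T", s$tumor_id), chrom = s$chrom,
                 start = start, end = end, n_probes = n_probes,
                 state = if (s$homolog_copies < 1) "loss" else "gain",
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(sample_id = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), n_probes = integer(0),
               state = character(0), stringsAsFactors = FALSE)
  }

  truth <- list(
    patient = as.integer(patient),
    scenario = if (n_shared > 0) "metastasis" else "multi-centric",
    het_sites = het,
    cna_specs = if (length(config$cna_specs) > 0) {
      do.call(rbind, lapply(config$cna_specs, function(s)
        data.frame(tumor_id = s$tumor_id, chrom = s$chrom, start = s$start,
                   end = s$end, affected_homolog = s$affected_homolog,
                   homolog_copies = s$homolog_copies, stringsAsFactors = FALSE)))
    } else {
      data.frame(tumor_id = integer(0), chrom = character(0),
                 start = numeric(0), end = numeric(0),
                 affected_homolog = character(0), homolog_copies = integer(0),
                 stringsAsFactors = FALSE)
    },
    mutations = muts, detected = detected, region_map = region_map)
  structure(list(observations = observations, segments = segments,
                 truth = truth, genome = config$genome),
            class = "cnaphase_sim")
}

#' @export
print.cnaphase_sim <- function(x, ...) {
  cat("Simulated patient", x$truth$patient, sprintf("(%s scenario)\n", x$truth$scenario))
  cat(" ", nrow(x$truth$het_sites), "het sites,",
      nrow(x$truth$mutations), "somatic mutations,",
      nrow(x$segments), "CNA segments,",
      length(unique(x$observations$sample_id)), "samples\n")
  invisible(x)
}
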