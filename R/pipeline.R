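#' Classification thresholds for the origin call
#'
#' There is no sharp recall threshold separating clonally related from
#' independent tumors; the defaults are chosen to separate the regimes
#' typically observed in multi-region data (within-tumor recall well above
#' 50%, cross-tumor recall around or below 10% for independent primaries).
#'
#' @param recall_high Cross-tumor recall at or above which shared clonal
#'   ancestry is called (default 0.5).
#' @param recall_low Cross-tumor recall at or below which mutation evidence
#'   is consistent with independent origin (default 0.15).
#' @param segment_min_length,segment_min_probes Segment validity thresholds,
#'   see [validate_segment()].
#' @param min_reciprocal_overlap See [find_candidate_shared_cnas()].
#' @param breakpoint_tolerance See [compare_breakpoints()].
#' @return An object of class `classify_config`.
#' @export
classify_config <- function(recall_high = 0.5, recall_low = 0.15,
                            segment_min_length = 50000,
                            segment_min_probes = 21L,
                            min_reciprocal_overlap = 0.5,
                            breakpoint_tolerance = 1e6) {
  stopifnot(recall_low <= recall_high, recall_low >= 0, recall_high <= 1)
  structure(list(recall_high = recall_high, recall_low = recall_low,
                 segment_min_length = segment_min_length,
                 segment_min_probes = segment_min_probes,
                 min_reciprocal_overlap = min_reciprocal_overlap,
                 breakpoint_tolerance = breakpoint_tolerance),
            class = "classify_config")
}

#' Classify a tumor pair as common or independent origin
#'
#' Combines the mutation-recall evidence with the per-CNA phasing and
#' breakpoint verdicts. The pair is `common_origin` when cross-tumor
#' recall reaches `recall_high`, or when any shared CNA is both
#' same-homolog and breakpoint-concordant (identical by descent).
#' It is `independent_origin` when cross-tumor recall is at or below
#' `recall_low` and every candidate shared CNA is explained as an
#' independent event (different homolog or discordant breakpoints).
#' Everything else — including missing evidence — is `indeterminate`.
#'
#' @param evidence List with `cross_recall` (numeric or `NA`) and `cnas`
#'   (data.frame with columns `phasing_verdict`, `breakpoint_verdict`, one
#'   row per candidate shared CNA; may have zero rows).
#' @param cfg A [classify_config()].
#' @return List of class `origin_call`: `call` in
#'   `{common_origin, independent_origin, indeterminate}` and
#'   `evidence_lines` (character).
#' @export
classify_origin_pair <- function(evidence, cfg = classify_config()) {
  rec <- evidence$cross_recall
  cnas <- evidence$cnas
  if (is.null(cnas))
    cnas <- data.frame(phasing_verdict = character(0),
                       breakpoint_verdict = character(0))
  lines <- character(0)
  if (is.null(rec) || length(rec) == 0 || is.na(rec)) {
    return(structure(list(call = "indeterminate",
                          evidence_lines = "cross-tumor recall unavailable"),
                     class = "origin_call"))
  }
  lines <- c(lines, sprintf("cross-tumor recall %.3f", rec))
  ibd <- cnas$phasing_verdict == "same_homolog" &
    cnas$breakpoint_verdict == "concordant"
  indep_cna <- cnas$phasing_verdict == "different_homolog" |
    cnas$breakpoint_verdict == "discordant"
  if (nrow(cnas) > 0)
    lines <- c(lines, sprintf(
      "%d candidate shared CNA(s): %d identical-by-descent, %d independent-event",
      nrow(cnas), sum(ibd), sum(indep_cna)))
  call <- if (rec >= cfg$recall_high || any(ibd)) {
    "common_origin"
  } else if (rec <= cfg$recall_low && all(indep_cna)) {
    "independent_origin"
  } else {
    "indeterminate"
  }
  structure(list(call = call, evidence_lines = lines), class = "origin_call")
}

#' @export
print.origin_call <- function(x, ...) {
  cat("Origin call:", x$call, "\n")
  for (l in x$evidence_lines) cat("  -", l, "\n")
  invisible(x)
}

.cfg_from_list <- function(constructor, values) {
  if (is.null(values)) return(constructor())
  do.call(constructor, values)
}

.sim_config_from_list <- function(sim, seed) {
  args <- sim
  if (!is.null(args$genome)) args$genome <- unlist(args$genome)
  if (!is.null(args$cna_specs))
    args$cna_specs <- lapply(args$cna_specs, function(s) do.call(cna_spec, s))
  if (!is.null(args$somatic_params))
    args$somatic_params <- do.call(somatic_params, args$somatic_params)
  if (!is.null(seed)) args$seed <- seed
  do.call(simulation_config, args)
}

#' Run the full classification pipeline
#'
#' Executes simulate (optional) -> somatic filtering -> recall analysis ->
#' segment matching -> chromosome phasing -> origin classification for
#' each patient, and optionally writes all stage outputs (verdict tables,
#' recall matrices, phasing reports, origin calls, summary JSON) to a
#' directory. With a fixed seed the run is fully deterministic.
#'
#' The configuration is a JSON file (or equivalent list) with blocks:
#' \describe{
#'   \item{`seed`}{integer, used by the simulation block.}
#'   \item{`simulation`}{arguments of [simulation_config()]; mutually
#'     exclusive with `inputs`.}
#'   \item{`inputs`}{list of per-patient entries `patient_id`, `vcf`,
#'     `seg`, `normal_sample`, `region_map` (list of
#'     `{sample_id, tumor_id, region_id}`), optional `chrom_lengths`.}
#'   \item{`filters`, `phasing`, `classify`}{threshold overrides for
#'     [filter_config()], [phasing_config()], [classify_config()].}
#' }
#'
#' @param config Path to a JSON configuration file, or the already-parsed
#'   list.
#' @param out_dir Optional output directory (created if needed).
#' @param seed Optional seed overriding the configuration's.
#' @return A list of class `cnaphase_report`: per-patient stage results and
#'   `origin_calls` (data.frame across patients and tumor pairs).
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) {
    jsonlite::read_json(config, simplifyVector = FALSE)
  } else config
  if (is.null(cfg$simulation) && is.null(cfg$inputs))
    stop("config must contain a 'simulation' or an 'inputs' block")
  filters <- .cfg_from_list(filter_config, cfg$filters)
  phasing <- .cfg_from_list(phasing_config, cfg$phasing)
  classify <- .cfg_from_list(classify_config, cfg$classify)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  patients <- list()
  if (!is.null(cfg$simulation)) {
    sim_cfg <- .sim_config_from_list(cfg$simulation,
                                     if (is.null(seed)) cfg$seed else seed)
    for (p in seq_len(sim_cfg$n_patients)) {
      sim <- simulate_patient(sim_cfg, patient = p)
      patients[[p]] <- list(patient_id = paste0("P", p),
                            observations = sim$observations,
                            segments = sim$segments,
                            normal_sample = "N",
                            region_map = sim$truth$region_map,
                            chrom_lengths = sim_cfg$genome,
                            truth = sim$truth)
      if (!is.null(out_dir)) {
        write_patient_vcf(sim$observations,
                          file.path(out_dir, sprintf("P%d.vcf", p)),
                          genome = sim_cfg$genome)
        write_seg(sim$segments, file.path(out_dir, sprintf("P%d.seg", p)))
        write_truth(sim$truth, file.path(out_dir, sprintf("P%d.truth.json", p)))
      }
    }
  } else {
    for (i in seq_along(cfg$inputs)) {
      inp <- cfg$inputs[[i]]
      obs <- read_vcf_observations(inp$vcf)
      lens <- if (!is.null(inp$chrom_lengths)) unlist(inp$chrom_lengths)
      else attr(obs, "contig_lengths")
      rm <- do.call(rbind, lapply(inp$region_map, function(r)
        data.frame(sample_id = r$sample_id, tumor_id = r$tumor_id,
                   region_id = r$region_id, stringsAsFactors = FALSE)))
      patients[[i]] <- list(
        patient_id = if (is.null(inp$patient_id)) paste0("P", i) else inp$patient_id,
        observations = obs, segments = read_seg(inp$seg),
        normal_sample = if (is.null(inp$normal_sample)) "N" else inp$normal_sample,
        region_map = rm, chrom_lengths = lens, truth = NULL)
    }
  }

  results <- lapply(patients, function(pat)
    .analyze_patient(pat, filters, phasing, classify))
  origin_calls <- do.call(rbind, lapply(results, `[[`, "origin_calls"))

  if (!is.null(out_dir)) {
    for (res in results) {
      pid <- res$patient_id
      utils::write.table(res$filter$verdicts,
                         file.path(out_dir, paste0(pid, ".filter_verdicts.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(cbind(region = rownames(res$recall$recall),
                               as.data.frame(round(res$recall$recall * 100, 1))),
                         file.path(out_dir, paste0(pid, ".recall_pct.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(res$phasing_table,
                         file.path(out_dir, paste0(pid, ".phasing.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(origin_calls, file.path(out_dir, "origin_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(origin_calls = origin_calls,
           parameters = list(filters = unclass(filters),
                             phasing = unclass(phasing),
                             classify = unclass(classify))),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(patients = results, origin_calls = origin_calls),
            class = "cnaphase_report")
}

.analyze_patient <- function(pat, filters, phasing, classify) {
  obs <- pat$observations
  rm <- pat$region_map
  flt <- filter_variant_table(obs, normal_sample = pat$normal_sample,
                              cfg = filters)
  regions <- lapply(seq_len(nrow(rm)), function(i) {
    keys <- flt$pass_sets[[rm$sample_id[i]]]
    region_variant_set(pat$patient_id, rm$tumor_id[i], rm$region_id[i],
                       if (is.null(keys)) character(0) else keys)
  })
  rmx <- recall_matrix(regions)
  avg <- average_recalls(rmx)

  segs <- pat$segments
  segs <- segs[validate_segment(segs, classify$segment_min_length,
                                classify$segment_min_probes), , drop = FALSE]
  normal_obs <- obs[obs$sample_id == pat$normal_sample, , drop = FALSE]
  tumor_obs <- obs[obs$sample_id != pat$normal_sample, , drop = FALSE]
  tumors <- sort(unique(rm$tumor_id))

  phasing_rows <- list()
  pair_calls <- list()
  for (i in seq_along(tumors)) for (j in seq_along(tumors)) {
    if (j <= i) next
    ta <- tumors[i]; tb <- tumors[j]
    sa <- paste0("T", ta); sb <- paste0("T", tb)
    matches <- find_candidate_shared_cnas(
      segs[segs$sample_id == sa, , drop = FALSE],
      segs[segs$sample_id == sb, , drop = FALSE],
      classify$min_reciprocal_overlap)
    bp <- compare_breakpoints(matches, classify$breakpoint_tolerance,
                              pat$chrom_lengths)
    cna_rows <- list()
    for (k in seq_len(nrow(matches))) {
      mt <- matches[k, ]
      core <- list(chrom = mt$chrom,
                   start = max(mt$start_a, mt$start_b),
                   end = min(mt$end_a, mt$end_b))
      cna_id <- sprintf("%s:%s-%s:%s", mt$chrom,
                        format(core$start, scientific = FALSE),
                        format(core$end, scientific = FALSE), mt$state)
      sites <- select_polymorphic_sites(normal_obs, core, phasing)
      deltas <- compute_deltas(sites, tumor_obs, rm, phasing)
      dec <- phase_concordance_test(deltas, as.character(ta), as.character(tb),
                                    phasing, cna_id = cna_id)
      cna_rows[[k]] <- data.frame(
        patient_id = pat$patient_id, tumor_a = sa, tumor_b = sb,
        cna_id = cna_id, state = mt$state,
        reciprocal_overlap = mt$reciprocal_overlap,
        breakpoint_verdict = bp[k],
        n_informative_sites = dec$n_informative_sites,
        p_ab = if (is.null(dec$welch_ab)) NA_real_ else dec$welch_ab$p_value,
        p_ba = if (is.null(dec$welch_ba)) NA_real_ else dec$welch_ba$p_value,
        sign_concordant = dec$sign_concordant,
        phasing_verdict = dec$verdict, stringsAsFactors = FALSE)
    }
    cnas <- if (length(cna_rows) > 0) do.call(rbind, cna_rows)
    else data.frame(phasing_verdict = character(0),
                    breakpoint_verdict = character(0))
    phasing_rows[[length(phasing_rows) + 1L]] <- cnas

    info <- rmx$region_info
    ia <- info$tumor_id == as.character(ta)
    ib <- info$tumor_id == as.character(tb)
    cross <- c(rmx$recall[ia, ib], rmx$recall[ib, ia])
    cross <- cross[!is.na(cross)]
    cross_recall <- if (length(cross) == 0) NA_real_ else mean(cross)
    call <- classify_origin_pair(list(cross_recall = cross_recall, cnas = cnas),
                                 classify)
    pair_calls[[length(pair_calls) + 1L]] <- data.frame(
      patient_id = pat$patient_id, tumor_a = sa, tumor_b = sb,
      cross_recall = cross_recall, n_candidate_cnas = nrow(cnas),
      call = call$call, stringsAsFactors = FALSE)
  }
  phasing_table <- if (length(phasing_rows) > 0) {
    nonempty <- Filter(function(d) nrow(d) > 0 && "cna_id" %in% names(d),
                       phasing_rows)
    if (length(nonempty) > 0) do.call(rbind, nonempty)
    else data.frame()
  } else data.frame()
  list(patient_id = pat$patient_id, filter = flt, recall = rmx,
       recall_averages = avg, phasing_table = phasing_table,
       origin_calls = do.call(rbind, pair_calls), truth = pat$truth)
}

#' @export
print.cnaphase_report <- function(x, ...) {
  cat("cnaphase pipeline report:", length(x$patients), "patient(s)\n")
  print(x$origin_calls)
  invisible(x)
}
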