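#' Write simulated observations as a multi-sample VCF 4.2
#'
#' One row per variant site, one genotype column per sample, with FORMAT
#' fields `DP` (total depth) and `AD` (ref,alt depths). Positions are
#' emitted 1-based as VCF requires.
#'
#' @param observations Data.frame with columns `sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `total_reads`, `alt_reads` (one row per site per sample).
#' @param path Output file path.
#' @param genome Optional named vector of chromosome lengths for `##contig`
#'   header lines.
#' @return `path`, invisibly.
#' @export
write_patient_vcf <- function(observations, path, genome = NULL) {
  req <- c("sample_id", "chrom", "pos", "ref", "alt", "total_reads", "alt_reads")
  stopifnot(all(req %in% names(observations)))
  samples <- unique(observations$sample_id)
  key <- paste(observations$chrom, observations$pos, observations$ref,
               observations$alt, sep = ":")
  sites <- observations[!duplicated(key), c("chrom", "pos", "ref", "alt")]
  skey <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
  chrom_order <- if (!is.null(genome)) names(genome) else unique(sites$chrom)
  o <- order(match(sites$chrom, chrom_order), sites$pos)
  sites <- sites[o, ]; skey <- skey[o]

  gt <- matrix(".", nrow = nrow(sites), ncol = length(samples),
               dimnames = list(NULL, samples))
  for (s in samples) {
    rows <- observations$sample_id == s
    i <- match(key[rows], skey)
    ref_reads <- observations$total_reads[rows] - observations$alt_reads[rows]
    gt[i, s] <- sprintf("%d:%d,%d", observations$total_reads[rows],
                        ref_reads, observations$alt_reads[rows])
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cnaphase",
    if (!is.null(genome))
      sprintf("##contig=<ID=%s,length=%d>", names(genome), as.integer(genome)),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- paste(sites$chrom, format(sites$pos, scientific = FALSE, trim = TRUE),
                ".", sites$ref, sites$alt, ".", ".", ".", "DP:AD",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read per-sample read counts from a multi-sample VCF
#'
#' Parses a VCF 4.2 file (via \pkg{vcfR}) carrying `DP` and `AD` genotype
#' fields and returns the long observation table used throughout the
#' package. Sites with missing genotypes in a sample are omitted for that
#' sample. Multi-allelic records are not supported.
#'
#' @param path VCF file path.
#' @return A data.frame with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `total_reads`, `alt_reads`, plus an attribute `contig_lengths`
#'   (named vector, if `##contig` header lines are present).
#' @export
read_vcf_observations <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE)))
    stop("multi-allelic VCF records are not supported")
  dp <- vcfR::extract.gt(vcf, "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(vcf, "AD")
  alt <- vcfR::masplit(ad, record = 2L, sort = FALSE)
  samples <- colnames(dp)
  out <- do.call(rbind, lapply(samples, function(s) {
    keep <- !is.na(dp[, s]) & !is.na(alt[, s])
    data.frame(sample_id = s, chrom = fix[keep, "CHROM"],
               pos = as.numeric(fix[keep, "POS"]),
               ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
               total_reads = as.integer(dp[keep, s]),
               alt_reads = as.integer(alt[keep, s]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  meta <- vcf@meta
  contig <- grep("^##contig=", meta, value = TRUE)
  if (length(contig) > 0) {
    ids <- sub(".*ID=([^,>]+).*", "\\1", contig)
    lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", contig)))
    attr(out, "contig_lengths") <- stats::setNames(lens, ids)
  }
  out
}

#' Write copy-number segments as a SEG table
#'
#' Tab-separated with columns `sample`, `chrom`, `start`, `end`,
#' `n_probes`, `state`. Internal 0-based half-open coordinates are
#' converted to 1-based inclusive on output; [read_seg()] converts back.
#'
#' @param segments Data.frame with columns `sample_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `n_probes`, `state`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path) {
  out <- data.frame(sample = segments$sample_id, chrom = segments$chrom,
                    start = format(segments$start + 1, scientific = FALSE, trim = TRUE),
                    end = format(segments$end, scientific = FALSE, trim = TRUE),
                    n_probes = segments$n_probes, state = segments$state,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SEG table written by [write_seg()]
#'
#' @param path SEG file path (1-based inclusive coordinates).
#' @return Data.frame with 0-based half-open `start`/`end`.
#' @export
read_seg <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  data.frame(sample_id = x$sample, chrom = x$chrom, start = x$start - 1,
             end = x$end, n_probes = as.integer(x$n_probes), state = x$state,
             stringsAsFactors = FALSE)
}

#' Write and read simulation ground truth as JSON
#'
#' The truth bundle (site phases, CNA homolog labels, somatic assignments,
#' region map, scenario label) round-trips losslessly:
#' `read_truth(write_truth(truth, path))` reproduces `truth`.
#'
#' @param truth The `truth` element of a [simulate_patient()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_df <- function(d, template) {
    d <- as.data.frame(d, stringsAsFactors = FALSE)
    if (nrow(d) == 0 || ncol(d) == 0) return(template)
    for (col in names(template)) {
      cast <- switch(class(template[[col]]),
                     integer = as.integer, numeric = as.numeric, as.character)
      d[[col]] <- cast(d[[col]])
    }
    d[names(template)]
  }
  empty <- function(...) data.frame(..., stringsAsFactors = FALSE)
  x$het_sites <- as_df(x$het_sites, empty(chrom = character(0), pos = integer(0),
                                          alt_homolog = character(0)))
  x$cna_specs <- as_df(x$cna_specs, empty(tumor_id = integer(0), chrom = character(0),
                                          start = numeric(0), end = numeric(0),
                                          affected_homolog = character(0),
                                          homolog_copies = integer(0)))
  x$mutations <- as_df(x$mutations, empty(mut_id = character(0), chrom = character(0),
                                          pos = numeric(0), ref = character(0),
                                          alt = character(0), class = character(0),
                                          tumor_id = integer(0), region_id = integer(0),
                                          true_vaf = numeric(0)))
  x$detected <- as_df(x$detected, empty(sample_id = character(0), mut_id = character(0)))
  x$region_map <- as_df(x$region_map, empty(sample_id = character(0),
                                            tumor_id = integer(0),
                                            region_id = integer(0),
                                            purity = numeric(0)))
  x$patient <- as.integer(x$patient)
  x
}
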