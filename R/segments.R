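#' Validate copy-number segments against size and probe-support thresholds
#'
#' Only segments larger than `min_length` (strict) with at least
#' `min_probes` supporting probes are considered for analysis; smaller or
#' weakly supported calls are typically array/exome segmentation noise.
#'
#' @param segments Segment data.frame (`chrom`, `start`, `end` 0-based
#'   half-open, `n_probes`, ...).
#' @param min_length Minimum segment length in bp, exclusive (default 50 kb).
#' @param min_probes Minimum probe support, inclusive (default 21).
#' @return Logical vector: `TRUE` for valid segments.
#' @export
validate_segment <- function(segments, min_length = 50000, min_probes = 21L) {
  (segments$end - segments$start) > min_length & segments$n_probes >= min_probes
}

#' Find candidate shared CNAs between two tumors
#'
#' Pairs segments from two tumors that sit on the same chromosome, have the
#' same state (gain/loss) and reciprocally overlap by at least
#' `min_reciprocal_overlap`, where reciprocal overlap is
#' `|intersection| / max(|a|, |b|)` (the stricter, max-denominator form).
#' Such pairs are candidates for being identical by descent and are passed
#' to breakpoint comparison and the phasing test.
#'
#' @param segs_a,segs_b Validated segment data.frames for the two tumors.
#' @param min_reciprocal_overlap Overlap threshold in `[0, 1]` (default 0.5).
#' @return Data.frame of matches: `chrom`, `state`, `start_a`, `end_a`,
#'   `start_b`, `end_b`, `n_probes_a`, `n_probes_b`, `reciprocal_overlap`.
#' @export
find_candidate_shared_cnas <- function(segs_a, segs_b,
                                       min_reciprocal_overlap = 0.5) {
  out <- list()
  for (i in seq_len(nrow(segs_a))) for (j in seq_len(nrow(segs_b))) {
    a <- segs_a[i, ]; b <- segs_b[j, ]
    if (a$chrom != b$chrom || a$state != b$state) next
    ov <- max(0, min(a$end, b$end) - max(a$start, b$start))
    ro <- ov / max(a$end - a$start, b$end - b$start)
    if (ro >= min_reciprocal_overlap)
      out[[length(out) + 1L]] <- data.frame(
        chrom = a$chrom, state = a$state,
        start_a = a$start, end_a = a$end, start_b = b$start, end_b = b$end,
        n_probes_a = a$n_probes, n_probes_b = b$n_probes,
        reciprocal_overlap = ro, stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), state = character(0),
                      start_a = numeric(0), end_a = numeric(0),
                      start_b = numeric(0), end_b = numeric(0),
                      n_probes_a = integer(0), n_probes_b = integer(0),
                      reciprocal_overlap = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Compare breakpoints of matched segments
#'
#' Two segments are breakpoint-concordant when both their starts and their
#' ends agree within `tolerance` bp (boundary inclusive). An end at which
#' both segments reach a chromosome boundary (telomere-bounded, e.g. a
#' terminal q-arm loss running to the chromosome end) is compared as
#' automatically concordant at that end: the shared boundary carries no
#' information about where the events began. Discordant breakpoints argue
#' that two otherwise similar CNAs arose as independent mutation events.
#'
#' @param matches Data.frame from [find_candidate_shared_cnas()].
#' @param tolerance Breakpoint tolerance in bp (default 1 Mb, reflecting
#'   coarse array/exome segment resolution).
#' @param chrom_lengths Optional named vector of chromosome lengths,
#'   enabling the telomere-bounded rule at the right end (position 0 serves
#'   at the left end).
#' @return Character vector: `"concordant"` or `"discordant"` per match.
#' @export
compare_breakpoints <- function(matches, tolerance = 1e6, chrom_lengths = NULL) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  if (nrow(matches) == 0) return(character(0))
  start_tel <- matches$start_a == 0 & matches$start_b == 0
  end_tel <- rep(FALSE, nrow(matches))
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[matches$chrom]
    end_tel <- !is.na(len) & matches$end_a == len & matches$end_b == len
  }
  start_ok <- start_tel | abs(matches$start_a - matches$start_b) <= tolerance
  end_ok <- end_tel | abs(matches$end_a - matches$end_b) <= tolerance
  unname(ifelse(start_ok & end_ok, "concordant", "discordant"))
}
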