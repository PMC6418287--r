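#' Region variant set
#'
#' The somatic mutations detected in one tumor region, keyed by
#' `chrom:pos:ref:alt`. Duplicate keys are collapsed.
#'
#' @param patient_id,tumor_id,region_id Labels placing the region.
#' @param keys Character vector of mutation keys.
#' @return An object of class `region_variant_set`.
#' @export
region_variant_set <- function(patient_id, tumor_id, region_id, keys) {
  structure(list(patient_id = patient_id, tumor_id = tumor_id,
                 region_id = region_id, keys = unique(as.character(keys))),
            class = "region_variant_set")
}

#' Number of somatic mutations shared by two regions
#'
#' @param a,b [region_variant_set()] objects.
#' @return Integer: size of the key intersection.
#' @export
shared_count <- function(a, b) length(intersect(a$keys, b$keys))

#' Directional recall rate of one region's mutations in another
#'
#' The fraction of `a`'s mutations also detected in `b`:
#' `|a intersect b| / |a|`. The measure is directional, so
#' `recall_rate(a, b)` and `recall_rate(b, a)` generally differ when the
#' two regions have unequal mutation burdens.
#'
#' @param a,b [region_variant_set()] objects.
#' @param metric `"recall"` (default) or `"jaccard"`
#'   (`|intersection| / |union|`, symmetric).
#' @return Fraction in `[0, 1]`, or `NA` when undefined (empty denominator).
#' @export
recall_rate <- function(a, b, metric = c("recall", "jaccard")) {
  metric <- match.arg(metric)
  if (metric == "jaccard") {
    u <- length(union(a$keys, b$keys))
    return(if (u == 0) NA_real_ else shared_count(a, b) / u)
  }
  if (length(a$keys) == 0) return(NA_real_)
  shared_count(a, b) / length(a$keys)
}

#' Pairwise shared-mutation and recall matrices across regions
#'
#' Computes, for every ordered pair of regions, the number of shared
#' somatic mutations and the directional recall rate. The shared-count
#' matrix is symmetric; the recall matrix generally is not.
#'
#' @param regions List of [region_variant_set()] objects with unique
#'   region labels.
#' @param metric Passed to [recall_rate()].
#' @return An object of class `recall_matrix`: list with `shared_counts`
#'   (integer matrix), `recall` (numeric matrix), and `region_info`
#'   (data.frame of patient/tumor/region labels in matrix order).
#' @export
recall_matrix <- function(regions, metric = "recall") {
  stopifnot(length(regions) >= 2)
  ids <- vapply(regions, function(r)
    paste(r$patient_id, r$tumor_id, r$region_id, sep = "/"), "")
  if (anyDuplicated(ids)) stop("duplicate region ids")
  n <- length(regions)
  shared <- matrix(0L, n, n, dimnames = list(ids, ids))
  rec <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shared[i, j] <- shared_count(regions[[i]], regions[[j]])
    rec[i, j] <- recall_rate(regions[[i]], regions[[j]], metric = metric)
  }
  info <- data.frame(
    id = ids,
    patient_id = vapply(regions, function(r) as.character(r$patient_id), ""),
    tumor_id = vapply(regions, function(r) as.character(r$tumor_id), ""),
    region_id = vapply(regions, function(r) as.character(r$region_id), ""),
    n_mutations = vapply(regions, function(r) length(r$keys), 0L),
    stringsAsFactors = FALSE)
  structure(list(shared_counts = shared, recall = rec, region_info = info),
            class = "recall_matrix")
}

#' @export
print.recall_matrix <- function(x, ...) {
  cat("Recall matrix over", nrow(x$region_info), "regions\n")
  print(round(x$recall, 3))
  invisible(x)
}

#' Within-tumor and cross-tumor average recall
#'
#' Averages the off-diagonal recall entries over ordered region pairs from
#' the same tumor (within) and from different tumors (cross). Undefined
#' recalls (empty source sets) are excluded; if no pair qualifies the
#' average is `NA`, never 0.
#'
#' @param mat A [recall_matrix()].
#' @param tumor_assignment Optional character vector of tumor labels per
#'   region (in matrix order); defaults to the `tumor_id` recorded in the
#'   matrix, combined with `patient_id` so tumors of different patients are
#'   never "within".
#' @return List with `within_tumor_avg` and `cross_tumor_avg`.
#' @export
average_recalls <- function(mat, tumor_assignment = NULL) {
  stopifnot(inherits(mat, "recall_matrix"))
  info <- mat$region_info
  tum <- if (is.null(tumor_assignment))
    paste(info$patient_id, info$tumor_id, sep = "/") else tumor_assignment
  stopifnot(length(tum) == nrow(info))
  n <- length(tum)
  same <- outer(tum, tum, "==")
  offdiag <- !diag(TRUE, n)
  within <- mat$recall[same & offdiag]
  cross <- mat$recall[!same]
  mean_or_na <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  list(within_tumor_avg = mean_or_na(within), cross_tumor_avg = mean_or_na(cross))
}
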