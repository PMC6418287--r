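#' Phasing-test configuration
#'
#' @param het_band Allele-fraction interval (inclusive) within which a site
#'   counts as heterozygous in the normal; default `[0.35, 0.65]`.
#' @param min_depth Minimum read depth (normal and tumor) for a site to be
#'   used; default 10, mirroring the normal-depth exclusion filter.
#' @param min_shift Minimum absolute allele-frequency delta for a site to be
#'   informative about homolog identity; default 0.05 suppresses near-zero
#'   noise deltas.
#' @param min_informative_sites Minimum number of matched informative sites
#'   required for a verdict; below it the decision is `inconclusive`
#'   (default 10).
#' @param alpha Significance level of the Welch test (default 0.05).
#' @param welch_values What the Welch test compares across tumors at the
#'   matched haplotype sites: `"af"` (default) uses the tumors' raw allele
#'   fractions, `"delta"` the tumor-minus-normal differences. Haplotype
#'   grouping and the sign guard always use the deltas; the test itself
#'   defaults to AF values because both tumors' deltas at a site share the
#'   same normal-sample noise term, which makes an unpaired comparison of
#'   deltas conservative (correlated samples), while raw tumor AFs are
#'   independent across tumors.
#' @return An object of class `phasing_config`.
#' @export
phasing_config <- function(het_band = c(0.35, 0.65), min_depth = 10L,
                           min_shift = 0.05, min_informative_sites = 10L,
                           alpha = 0.05, welch_values = c("af", "delta")) {
  stopifnot(length(het_band) == 2, het_band[1] < het_band[2],
            het_band[1] > 0, het_band[2] < 1,
            min_depth >= 0, min_shift >= 0, min_informative_sites >= 0)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(het_band = het_band, min_depth = min_depth,
                 min_shift = min_shift,
                 min_informative_sites = as.integer(min_informative_sites),
                 alpha = alpha, welch_values = match.arg(welch_values)),
            class = "phasing_config")
}

#' Select polymorphic (heterozygous) sites from the matched normal
#'
#' Keeps sites whose normal-sample allele fraction lies in the
#' heterozygous band and whose normal depth meets `min_depth`, optionally
#' restricted to a candidate CNA interval. These are the sites whose AF
#' shifts in the tumors carry the phasing signal.
#'
#' @param normal_obs Observation data.frame for the normal sample.
#' @param segment Optional single segment (list/row with `chrom`, `start`,
#'   `end`, 0-based half-open) to restrict to.
#' @param cfg A [phasing_config()].
#' @return Data.frame `chrom`, `pos`, `af_normal`, `depth_normal`, sorted
#'   by position; zero rows when nothing qualifies.
#' @export
select_polymorphic_sites <- function(normal_obs, segment = NULL,
                                     cfg = phasing_config()) {
  x <- normal_obs
  if (!is.null(segment)) {
    stopifnot(segment$start < segment$end)
    x <- x[x$chrom == segment$chrom & x$pos - 1 >= segment$start &
             x$pos - 1 < segment$end, , drop = FALSE]
  }
  af <- ifelse(x$total_reads > 0, x$alt_reads / x$total_reads, NA_real_)
  keep <- !is.na(af) & x$total_reads >= cfg$min_depth &
    af >= cfg$het_band[1] & af <= cfg$het_band[2]
  out <- data.frame(chrom = x$chrom[keep], pos = x$pos[keep],
                    af_normal = af[keep], depth_normal = x$total_reads[keep],
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Compute per-tumor allele-frequency deltas at heterozygous sites
#'
#' Pools read counts across regions of the same tumor (summing ALT and
#' total depths), computes the tumor allele fraction at each selected site
#' and its signed delta from the normal AF. Sites missing or unsequenced
#' (zero or sub-threshold pooled depth) in a tumor are dropped for that
#' tumor.
#'
#' @param sites Output of [select_polymorphic_sites()].
#' @param tumor_obs Observation data.frame for tumor samples.
#' @param region_map Optional data.frame (`sample_id`, `tumor_id`) mapping
#'   region samples to tumors; by default each `sample_id` is its own tumor.
#' @param cfg A [phasing_config()].
#' @return Data.frame `tumor_id`, `chrom`, `pos`, `af_normal`,
#'   `depth_normal`, `af_tumor`, `depth_tumor`, `delta` (one row per site
#'   per tumor).
#' @export
compute_deltas <- function(sites, tumor_obs, region_map = NULL,
                           cfg = phasing_config()) {
  if (nrow(sites) == 0)
    return(data.frame(tumor_id = character(0), chrom = character(0),
                      pos = numeric(0), af_normal = numeric(0),
                      depth_normal = integer(0), af_tumor = numeric(0),
                      depth_tumor = integer(0), delta = numeric(0),
                      stringsAsFactors = FALSE))
  tumor <- if (is.null(region_map)) {
    transform(tumor_obs, tumor_id = sample_id)
  } else {
    merge(tumor_obs, region_map[, c("sample_id", "tumor_id")], by = "sample_id")
  }
  site_key <- paste(sites$chrom, sites$pos, sep = ":")
  tumor <- tumor[paste(tumor$chrom, tumor$pos, sep = ":") %in% site_key, ,
                 drop = FALSE]
  agg <- stats::aggregate(cbind(alt_reads, total_reads) ~ tumor_id + chrom + pos,
                          data = tumor, FUN = sum)
  m <- match(paste(agg$chrom, agg$pos, sep = ":"), site_key)
  out <- data.frame(
    tumor_id = as.character(agg$tumor_id), chrom = agg$chrom, pos = agg$pos,
    af_normal = sites$af_normal[m], depth_normal = sites$depth_normal[m],
    af_tumor = ifelse(agg$total_reads > 0, agg$alt_reads / agg$total_reads, NA),
    depth_tumor = agg$total_reads, stringsAsFactors = FALSE)
  out <- out[!is.na(out$af_tumor) & out$depth_tumor >= cfg$min_depth, ,
             drop = FALSE]
  out$delta <- out$af_tumor - out$af_normal
  out <- out[order(out$tumor_id, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Infer haplotype groups from the direction of AF shift
#'
#' Inside a copy-number alteration the two parental homolog haplotypes
#' separate: heterozygous sites whose ALT allele sits on the gained (or
#' retained) homolog shift positively, the others negatively. Sites are
#' grouped by the sign of their delta in a chosen reference tumor: `H1`
#' for deltas above `+min_shift`, `H2` below `-min_shift`, `uninformative`
#' otherwise. Labels are arbitrary up to a global H1/H2 swap.
#'
#' @param deltas Output of [compute_deltas()].
#' @param reference_tumor Tumor id whose deltas define the grouping.
#' @param cfg A [phasing_config()].
#' @return Data.frame `chrom`, `pos`, `label` with attribute
#'   `reference_tumor`.
#' @export
infer_haplotypes <- function(deltas, reference_tumor, cfg = phasing_config()) {
  d <- deltas[deltas$tumor_id == reference_tumor, , drop = FALSE]
  label <- ifelse(d$delta > cfg$min_shift, "H1",
                  ifelse(d$delta < -cfg$min_shift, "H2", "uninformative"))
  out <- data.frame(chrom = d$chrom, pos = d$pos, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "reference_tumor") <- reference_tumor
  out
}

#' Welch two-sample t-test
#'
#' Unequal-variance two-sample t-test with Welch–Satterthwaite degrees of
#' freedom and a two-sided p-value:
#' `t = (mean_x - mean_y) / sqrt(var_x/n_x + var_y/n_y)`,
#' `df = (var_x/n_x + var_y/n_y)^2 /
#'       ((var_x/n_x)^2/(n_x-1) + (var_y/n_y)^2/(n_y-1))`,
#' using unbiased sample variances. Degenerate inputs are defined rather
#' than errors: two constant samples with equal means give `t = 0, p = 1`;
#' constant samples with unequal means give `p = 0` with a warning.
#'
#' @param xs,ys Numeric vectors, each of length >= 2.
#' @return A list of class `welch_test`: `mean_x`, `mean_y`, `var_x`,
#'   `var_y`, `n_x`, `n_y`, `t_statistic`, `df`, `p_value`.
#' @export
welch_t_test <- function(xs, ys) {
  n_x <- length(xs); n_y <- length(ys)
  if (n_x < 2 || n_y < 2) stop("welch_t_test requires at least 2 observations per sample")
  mean_x <- mean(xs); mean_y <- mean(ys)
  var_x <- stats::var(xs); var_y <- stats::var(ys)
  se2 <- var_x / n_x + var_y / n_y
  if (se2 == 0) {
    if (mean_x == mean_y) {
      t <- 0; df <- NA_real_; p <- 1
    } else {
      warning("degenerate data: zero variance in both samples, unequal means")
      t <- sign(mean_x - mean_y) * Inf; df <- NA_real_; p <- 0
    }
  } else {
    t <- (mean_x - mean_y) / sqrt(se2)
    df <- se2^2 / ((var_x / n_x)^2 / (n_x - 1) + (var_y / n_y)^2 / (n_y - 1))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(mean_x = mean_x, mean_y = mean_y, var_x = var_x,
                 var_y = var_y, n_x = n_x, n_y = n_y, t_statistic = t,
                 df = df, p_value = p),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch two-sample t-test: t = %.4g, df = %.4g, p = %.4g\n",
              x$t_statistic, x$df, x$p_value))
  cat(sprintf("  x: n = %d, mean = %.4g, var = %.4g\n", x$n_x, x$mean_x, x$var_x))
  cat(sprintf("  y: n = %d, mean = %.4g, var = %.4g\n", x$n_y, x$mean_y, x$var_y))
  invisible(x)
}

.phase_direction <- function(deltas, ref, other, cfg) {
  hap <- infer_haplotypes(deltas, ref, cfg)
  h1 <- hap[hap$label == "H1", c("chrom", "pos")]
  dref <- deltas[deltas$tumor_id == ref, , drop = FALSE]
  doth <- deltas[deltas$tumor_id == other, , drop = FALSE]
  key <- function(d) paste(d$chrom, d$pos, sep = ":")
  hk <- key(h1)
  # matched informative set: H1 in the reference, shifted beyond min_shift
  # in the other tumor as well
  ok <- key(doth) %in% hk & abs(doth$delta) > cfg$min_shift
  matched <- key(doth)[ok]
  iref <- match(matched, key(dref))
  col <- if (cfg$welch_values == "af") "af_tumor" else "delta"
  xs <- dref[[col]][iref]
  ys <- doth[[col]][ok]
  # the sign guard always reads the signed shifts
  list(n = length(matched), xs = xs, ys = ys,
       dx = dref$delta[iref], dy = doth$delta[ok],
       welch = if (length(matched) >= 2) welch_t_test(xs, ys) else NULL)
}

#' Test whether a shared CNA hit the same homolog in two tumors
#'
#' The core clonality inference. Heterozygous sites inside a candidate CNA
#' are grouped into haplotypes by the direction of their AF shift in a
#' reference tumor; at the H1 sites informative in both tumors, the two
#' tumors' AF values (or deltas, per `welch_values`) are compared by a
#' Welch two-sample t-test, and the procedure is repeated with the roles
#' swapped so the result does not depend on tumor order. The null
#' hypothesis is that the CNA occurred on the same homologous chromosome
#' in both tumors.
#'
#' The verdict is `different_homolog` when both directional tests reject
#' at `alpha` and the matched sites' mean deltas have opposite signs in
#' the two tumors; it is `same_homolog` when the signs agree and neither
#' test rejects; anything else (including fewer than
#' `min_informative_sites` matched sites in either direction) is
#' `inconclusive`. The sign guard prevents a purity difference between
#' tumors carrying the same-homolog event — which shifts delta magnitudes
#' but not their direction — from being mistaken for a different-homolog
#' signal.
#'
#' @param deltas Output of [compute_deltas()] restricted to the candidate
#'   CNA (as produced with `segment =` in site selection).
#' @param tumor_a,tumor_b Tumor ids to compare.
#' @param cfg A [phasing_config()].
#' @param cna_id Optional label carried into the decision.
#' @return An object of class `phasing_decision`: `cna_id`, `tumor_pair`,
#'   `welch_ab`, `welch_ba` (both directional [welch_t_test()] results),
#'   `sign_concordant`, `n_informative_sites`, `alpha`, `verdict`.
#' @export
phase_concordance_test <- function(deltas, tumor_a, tumor_b,
                                   cfg = phasing_config(), cna_id = NULL) {
  dir_ab <- .phase_direction(deltas, tumor_a, tumor_b, cfg)
  dir_ba <- .phase_direction(deltas, tumor_b, tumor_a, cfg)
  n_inf <- min(dir_ab$n, dir_ba$n)
  sign_concordant <- NA
  verdict <- "inconclusive"
  if (n_inf >= max(2L, cfg$min_informative_sites)) {
    sign_concordant <-
      sign(mean(dir_ab$dx)) == sign(mean(dir_ab$dy)) &&
      sign(mean(dir_ba$dx)) == sign(mean(dir_ba$dy))
    p_ab <- dir_ab$welch$p_value
    p_ba <- dir_ba$welch$p_value
    if (p_ab < cfg$alpha && p_ba < cfg$alpha && !sign_concordant) {
      verdict <- "different_homolog"
    } else if (sign_concordant && p_ab >= cfg$alpha && p_ba >= cfg$alpha) {
      verdict <- "same_homolog"
    }
  }
  structure(list(cna_id = cna_id, tumor_pair = c(tumor_a, tumor_b),
                 welch_ab = dir_ab$welch, welch_ba = dir_ba$welch,
                 sign_concordant = sign_concordant,
                 n_informative_sites = n_inf, alpha = cfg$alpha,
                 verdict = verdict),
            class = "phasing_decision")
}

#' @export
print.phasing_decision <- function(x, ...) {
  cat(sprintf("Phasing decision%s: tumors %s vs %s -> %s\n",
              if (is.null(x$cna_id)) "" else paste0(" [", x$cna_id, "]"),
              x$tumor_pair[1], x$tumor_pair[2], x$verdict))
  cat(sprintf("  matched informative sites: %d; sign concordant: %s\n",
              x$n_informative_sites, format(x$sign_concordant)))
  if (!is.null(x$welch_ab))
    cat(sprintf("  %s-referenced: t = %.3g, df = %.3g, p = %.3g\n",
                x$tumor_pair[1], x$welch_ab$t_statistic, x$welch_ab$df,
                x$welch_ab$p_value))
  if (!is.null(x$welch_ba))
    cat(sprintf("  %s-referenced: t = %.3g, df = %.3g, p = %.3g\n",
                x$tumor_pair[2], x$welch_ba$t_statistic, x$welch_ba$df,
                x$welch_ba$p_value))
  invisible(x)
}
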