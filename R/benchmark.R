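# Precision/recall/FDR benchmarking within confidence regions, plus the
# summary-statistics calculators behind headline comparisons.

#' Benchmark a call set against a truth set within confidence regions
#'
#' Small-variant matching requires identical (chrom, start, ref, alt)
#' after normalisation and, in genotype-aware mode, identical unordered
#' genotypes for every shared sample. All counts are restricted to
#' variants falling entirely within the confidence regions. Results are
#' optionally stratified easy/difficult and restricted to a subset of
#' sites (e.g. singletons).
#'
#' @param test,truth panels: list(sites, h1, h2); sites need chrom,
#'   start, ref, alt (end is derived from the ref allele).
#' @param regions optional confidence-region interval table.
#' @param strat optional \code{\link{region_stratification}} for
#'   easy/difficult breakdown.
#' @param genotype_aware require matching genotypes, not just matching
#'   alleles (default TRUE).
#' @param subset_test,subset_truth optional logical vectors selecting
#'   the sites eligible on each side (e.g. truth singletons).
#' @return data.frame with one row per stratum (plus "all"): TP, FP, FN,
#'   precision, recall, FDR.
#' @export
benchmark_calls <- function(test, truth, regions = NULL, strat = NULL,
                            genotype_aware = TRUE,
                            subset_test = NULL, subset_truth = NULL) {
  span <- function(p) genomic_intervals(p$sites$chrom, p$sites$start,
                                        p$sites$start + nchar(p$sites$ref))
  keep_in <- function(p, sel) {
    keep <- if (is.null(sel)) rep(TRUE, nrow(p$sites)) else sel
    if (!is.null(regions)) {
      gv <- as_gr(span(p))
      keep <- keep & IRanges::overlapsAny(gv, as_gr(regions, min_width1 = FALSE),
                                          type = "within")
    }
    keep
  }
  kt <- keep_in(test, subset_test)
  ku <- keep_in(truth, subset_truth)
  t_sites <- test$sites[kt, , drop = FALSE]
  u_sites <- truth$sites[ku, , drop = FALSE]
  if (nrow(u_sites) == 0L)
    return(data.frame(stratum = "all", TP = NA, FP = NA, FN = NA,
                      precision = NA, recall = NA, fdr = NA))
  key <- function(s) paste(s$chrom, s$start, s$ref, s$alt)
  mi <- match(key(t_sites), key(u_sites))
  matched <- !is.na(mi)
  if (genotype_aware && any(matched)) {
    shared <- intersect(colnames(test$h1), colnames(truth$h1))
    ti <- which(kt)[matched]; ui <- which(ku)[mi[matched]]
    gt_ok <- rep(TRUE, sum(matched))
    for (smp in shared) {
      a <- match(smp, colnames(test$h1)); b <- match(smp, colnames(truth$h1))
      eq <- gt_equal(test$h1[ti, a], test$h2[ti, a],
                     truth$h1[ui, b], truth$h2[ui, b])
      gt_ok <- gt_ok & !is.na(eq) & eq
    }
    matched[matched] <- gt_ok
  }
  truth_hit <- rep(FALSE, nrow(u_sites))
  truth_hit[mi[matched]] <- TRUE

  score <- function(sel_t, sel_u) {
    tp <- sum(matched & sel_t)
    fp <- sum(!matched & sel_t)
    fn <- sum(!truth_hit & sel_u)
    data.frame(TP = tp, FP = fp, FN = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_)
  }
  out <- cbind(stratum = "all",
               score(rep(TRUE, nrow(t_sites)), rep(TRUE, nrow(u_sites))))
  if (!is.null(strat)) {
    cls_t <- classify_region(span(list(sites = t_sites)), strat)
    cls_u <- classify_region(span(list(sites = u_sites)), strat)
    for (cl in c("easy", "difficult"))
      out <- rbind(out, cbind(stratum = cl, score(cls_t == cl, cls_u == cl)))
  }
  out
}

#' Fold change, rounded to the conventional two decimals
#'
#' @param a,b numerator and denominator counts (b > 0).
#' @return a / b rounded to 2 decimal places.
#' @export
fold_change <- function(a, b) {
  if (any(b <= 0)) stop("fold change requires a positive denominator")
  round(a / b, 2)
}

#' Percentage fraction, rounded to one decimal
#'
#' @param a,b numerator and denominator counts (b > 0).
#' @return 100 a / b rounded to 1 decimal place.
#' @export
fraction_percent <- function(a, b) {
  if (any(b <= 0)) stop("fraction requires a positive denominator")
  round(100 * a / b, 1)
}

#' Exact integer sum of category counts
#'
#' @param ... integer counts.
#' @return their exact sum.
#' @export
category_sum <- function(...) sum(vapply(list(...), as.integer, integer(1)))
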