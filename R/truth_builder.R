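# Dual-genotyper SV truth-set construction: integrate two independent
# genotypers, match truth sites to a panel, compute concordance and
# non-reference precision, and finalise the truth set.

#' Integrate genotypes from two independent SV genotypers
#'
#' Genotyper A contributes genotypes only at calls with genotype quality
#' at or above \code{gq_min}; genotyper B contributes only PASS-filtered
#' sites. Where both contribute and agree (unordered genotype), the
#' integrated genotype is kept; on disagreement, or when either side is
#' filtered or absent, it is missing (intersection semantics). Sites
#' missing across all samples are dropped.
#'
#' @param a list: allele matrices \code{h1}, \code{h2} and \code{gq}
#'   matrix (per sample).
#' @param b list: allele matrices \code{h1}, \code{h2} and per-site
#'   \code{filter} character vector.
#' @param sites site table aligned with both genotypers' rows.
#' @param gq_min genotype-quality cutoff for A (default 200).
#' @return list: \code{sites} (kept rows), \code{h1}, \code{h2},
#'   \code{kept} logical over input rows.
#' @export
integrate_dual_genotypes <- function(a, b, sites, gq_min = 200) {
  stopifnot(all(dim(a$h1) == dim(b$h1)))
  a_ok <- !is.na(a$h1) & !is.na(a$gq) & a$gq >= gq_min
  b_ok <- !is.na(b$h1) & (b$filter == "PASS")
  agree <- gt_equal(a$h1, a$h2, b$h1, b$h2)
  use <- a_ok & b_ok & !is.na(agree) & agree
  h1 <- ifelse(use, a$h1, NA_integer_)
  h2 <- ifelse(use, a$h2, NA_integer_)
  dimnames(h1) <- dimnames(h2) <- dimnames(a$h1)
  kept <- rowSums(!is.na(h1)) > 0L
  list(sites = sites[kept, , drop = FALSE],
       h1 = h1[kept, , drop = FALSE], h2 = h2[kept, , drop = FALSE],
       kept = kept)
}

#' Match SV sites between two call sets
#'
#' Two same-type records match when their closed +/- window-sized start
#' windows intersect (|delta start| <= 2 x half-width) and the length
#' ratio (shorter / longer) reaches the minimum. Matching is one-to-one
#' and greedy by smallest start distance, ties broken by larger length
#' ratio.
#'
#' @param set1,set2 record data.frames (id, chrom, start, svtype,
#'   svlen).
#' @param window start-window half-width in bp (default 50).
#' @param min_ratio minimum shorter/longer length ratio (default 0.80).
#' @return data.frame of matched pairs: id1, id2, start_distance,
#'   length_ratio.
#' @export
match_sv_sites <- function(set1, set2, window = 50L, min_ratio = 0.80) {
  stopifnot(window >= 0, min_ratio > 0, min_ratio <= 1)
  cand <- list()
  for (tp in intersect(unique(set1$svtype), unique(set2$svtype))) {
    for (ch in intersect(unique(set1$chrom), unique(set2$chrom))) {
      i1 <- which(set1$svtype == tp & set1$chrom == ch)
      i2 <- which(set2$svtype == tp & set2$chrom == ch)
      if (!length(i1) || !length(i2)) next
      g1 <- GenomicRanges::GRanges(ch, IRanges::IRanges(set1$start[i1] + 1L,
                                                        set1$start[i1] + 1L))
      g2 <- GenomicRanges::GRanges(ch, IRanges::IRanges(set2$start[i2] + 1L,
                                                        set2$start[i2] + 1L))
      hits <- GenomicRanges::findOverlaps(g1, g2, maxgap = 2L * window)
      if (!length(hits)) next
      q <- i1[S4Vectors::queryHits(hits)]; s <- i2[S4Vectors::subjectHits(hits)]
      ratio <- pmin(set1$svlen[q], set2$svlen[s]) / pmax(set1$svlen[q], set2$svlen[s])
      d <- abs(set1$start[q] - set2$start[s])
      ok <- d <= 2L * window & ratio >= min_ratio
      if (any(ok))
        cand[[length(cand) + 1L]] <- data.frame(
          i1 = q[ok], i2 = s[ok], start_distance = d[ok],
          length_ratio = ratio[ok])
    }
  }
  empty <- data.frame(id1 = character(), id2 = character(),
                      start_distance = integer(), length_ratio = numeric())
  if (!length(cand)) return(empty)
  cc <- do.call(rbind, cand)
  cc <- cc[order(cc$start_distance, -cc$length_ratio), , drop = FALSE]
  used1 <- logical(nrow(set1)); used2 <- logical(nrow(set2))
  keep <- logical(nrow(cc))
  for (k in seq_len(nrow(cc))) {
    if (!used1[cc$i1[k]] && !used2[cc$i2[k]]) {
      keep[k] <- TRUE
      used1[cc$i1[k]] <- TRUE; used2[cc$i2[k]] <- TRUE
    }
  }
  cc <- cc[keep, , drop = FALSE]
  data.frame(id1 = set1$id[cc$i1], id2 = set2$id[cc$i2],
             start_distance = cc$start_distance,
             length_ratio = cc$length_ratio, stringsAsFactors = FALSE)
}

#' Genotype concordance and non-reference precision
#'
#' Concordance is the number of correct test genotypes divided by the
#' number of non-missing genotypes in the validation set (a missing test
#' call at a validated genotype counts against concordance).
#' Non-reference precision is the number of correct heterozygous plus
#' correct homozygous-alternate calls divided by all non-reference
#' genotypes called in the test set (over validated entries).
#'
#' @param test,validation lists with allele matrices \code{h1},
#'   \code{h2} over aligned sites and samples.
#' @return data.frame: counts, \code{concordance}, \code{nrp} (NA on an
#'   empty validation set).
#' @export
truth_metrics <- function(test, validation) {
  gv <- gt_dosage(validation$h1, validation$h2)
  gt <- gt_dosage(test$h1, test$h2)
  valid <- !is.na(gv)
  n_valid <- sum(valid)
  if (n_valid == 0L)
    return(data.frame(n_validation = 0L, n_correct = NA, concordance = NA_real_,
                      n_nonref_test = NA, n_nonref_correct = NA, nrp = NA_real_))
  eq <- gt_equal(test$h1, test$h2, validation$h1, validation$h2)
  correct <- valid & !is.na(eq) & eq
  nonref_test <- valid & !is.na(gt) & gt > 0
  data.frame(n_validation = n_valid, n_correct = sum(correct),
             concordance = sum(correct) / n_valid,
             n_nonref_test = sum(nonref_test),
             n_nonref_correct = sum(nonref_test & correct),
             nrp = sum(nonref_test & correct) / sum(nonref_test))
}

#' Finalise an SV truth set
#'
#' Drops monomorphic sites and sites deviating from Hardy-Weinberg
#' equilibrium (exact-test p-value below the threshold), and reports
#' per-type site counts.
#'
#' @param truth list: \code{sites} (with svtype), \code{h1}, \code{h2}.
#' @param hwe_p_min exclusion threshold (default 1e-10; sites with
#'   p < threshold are removed).
#' @return list: filtered \code{sites}/\code{h1}/\code{h2},
#'   \code{type_counts}, \code{kept}.
#' @export
finalize_truth_set <- function(truth, hwe_p_min = 1e-10) {
  st <- site_allele_stats(truth$h1, truth$h2)
  poly <- st$AC > 0L & st$AC < st$AN
  g <- gt_class(truth$h1, truth$h2)
  p <- hwe_exact_p(rowSums(g == 0L, na.rm = TRUE),
                   rowSums(g == 1L, na.rm = TRUE),
                   rowSums(g == 2L, na.rm = TRUE))
  kept <- poly & p >= hwe_p_min
  sites <- truth$sites[kept, , drop = FALSE]
  list(sites = sites,
       h1 = truth$h1[kept, , drop = FALSE], h2 = truth$h2[kept, , drop = FALSE],
       type_counts = table(sites$svtype), kept = kept)
}
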