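# Phasing-accuracy statistics: switch error rate against a truth panel,
# SV flip rate against SV/flanking-SNV pairs, and trio-based parental
# flip rate.

#' Switch error rate against a truth panel
#'
#' Assessed sites are heterozygous and phased in both panels. Walking
#' consecutive assessed heterozygous sites per chromosome, a switch is
#' counted at every junction where the relative phase orientation
#' changes; SER = switches / junctions. A single-site flip therefore
#' contributes two switches (plain junction-count convention). Samples
#' with fewer than two assessed sites get NA, never 0.
#'
#' @param test,truth phased panels: lists with allele matrices \code{h1},
#'   \code{h2} over the same sites and samples.
#' @param sites site table (chromosome grouping; must match matrix rows).
#' @param samples samples to assess (default: all shared columns).
#' @param maf optional per-site minor allele frequencies for MAF-bin
#'   stratification; junctions are binned by their right-hand site.
#' @param maf_bins MAF bin edges.
#' @return list: \code{per_sample}, \code{by_chrom}, and (when maf is
#'   given) \code{by_maf} data.frames with switches, pairs and SER.
#' @export
switch_error_rate <- function(test, truth, sites,
                              samples = intersect(colnames(test$h1), colnames(truth$h1)),
                              maf = NULL,
                              maf_bins = c(0, 0.001, 0.01, 0.1, 0.5)) {
  per_sample <- list(); by_chrom <- list(); by_maf <- list()
  for (smp in samples) {
    st <- match(smp, colnames(test$h1)); su <- match(smp, colnames(truth$h1))
    g_test <- test$h1[, st] + test$h2[, st]
    g_truth <- truth$h1[, su] + truth$h2[, su]
    for (ch in unique(sites$chrom)) {
      rows <- which(sites$chrom == ch & g_test == 1L & g_truth == 1L)
      nj <- max(0L, length(rows) - 1L)
      if (nj == 0L) {
        by_chrom[[length(by_chrom) + 1L]] <- data.frame(
          sample = smp, chrom = ch, n_switches = NA_integer_, n_pairs = 0L,
          ser = NA_real_, stringsAsFactors = FALSE)
        next
      }
      ori <- test$h1[rows, st] == truth$h1[rows, su]
      sw <- ori[-1L] != ori[-length(ori)]
      by_chrom[[length(by_chrom) + 1L]] <- data.frame(
        sample = smp, chrom = ch, n_switches = sum(sw), n_pairs = nj,
        ser = sum(sw) / nj, stringsAsFactors = FALSE)
      if (!is.null(maf)) {
        bin <- cut(pmin(maf[rows[-1L]], 1 - maf[rows[-1L]]), maf_bins,
                   include.lowest = FALSE)
        by_maf[[length(by_maf) + 1L]] <- data.frame(
          sample = smp, bin = as.character(bin), switch = sw,
          stringsAsFactors = FALSE)
      }
    }
  }
  bc <- do.call(rbind, by_chrom)
  ps <- do.call(rbind, lapply(split(bc, bc$sample), function(d) {
    np <- sum(d$n_pairs); ns <- sum(d$n_switches, na.rm = TRUE)
    data.frame(sample = d$sample[1L], n_switches = ns, n_pairs = np,
               ser = if (np > 0L) ns / np else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(ps) <- NULL
  out <- list(per_sample = ps, by_chrom = bc)
  if (!is.null(maf) && length(by_maf)) {
    bm <- do.call(rbind, by_maf)
    out$by_maf <- do.call(rbind, lapply(split(bm, bm$bin), function(d)
      data.frame(bin = d$bin[1L], n_switches = sum(d$switch),
                 n_pairs = nrow(d), ser = mean(d$switch),
                 stringsAsFactors = FALSE)))
    rownames(out$by_maf) <- NULL
  }
  out
}

# haplotype index (1 or 2) carrying the alt allele of a het call
alt_hap <- function(h1, h2) ifelse(h1 == 1L, 1L, 2L)

#' SV flip rate against SV/flanking-SNV pairs
#'
#' For every SV heterozygous and phased in both panels, the cis/trans
#' relationship with its nearest phased heterozygous flanking SNVs
#' (within a search window on each side) is compared between test and
#' truth; the SV is flipped iff the relationship is inverted. When both
#' flanks are available and disagree, the nearer flank decides. The
#' assessment is restricted to SVs matched to the truth set: deletions
#' with 100% reciprocal overlap and insertions with exactly matching
#' breakpoint position (i.e. identical coordinates per type).
#'
#' @param sv_test,sv_truth SV panels: list(records, h1, h2); records
#'   need chrom, start, end, svtype.
#' @param snv_test,snv_truth small-variant panels over the same samples:
#'   list(sites, h1, h2).
#' @param window flanking-SNV search window in bp (default 50 kb).
#' @return list: \code{per_type} breakdown (assessed, flipped, flip
#'   rate, assessed fraction of het SVs) and \code{overall}.
#' @export
sv_flip_rate <- function(sv_test, sv_truth, snv_test, snv_truth, window = 50000L) {
  rt <- sv_test$records %||% sv_test$sites
  ru <- sv_truth$records %||% sv_truth$sites
  key_t <- paste(rt$chrom, rt$start, rt$end, rt$svtype)
  key_u <- paste(ru$chrom, ru$start, ru$end, ru$svtype)
  mi <- match(key_t, key_u)  # exact-coordinate truth match
  samples <- intersect(colnames(sv_test$h1), colnames(sv_truth$h1))
  snv_sites <- snv_test$sites
  res <- list()
  for (smp in samples) {
    i_t <- match(smp, colnames(sv_test$h1)); i_u <- match(smp, colnames(sv_truth$h1))
    j_t <- match(smp, colnames(snv_test$h1)); j_u <- match(smp, colnames(snv_truth$h1))
    g_sv_t <- sv_test$h1[, i_t] + sv_test$h2[, i_t]
    g_sv_u <- sv_truth$h1[, i_u] + sv_truth$h2[, i_u]
    snv_het <- which(snv_test$h1[, j_t] + snv_test$h2[, j_t] == 1L &
                     snv_truth$h1[, j_u] + snv_truth$h2[, j_u] == 1L)
    snv_het <- snv_het[order(snv_sites$chrom[snv_het], snv_sites$start[snv_het])]
    het_by_chrom <- split(snv_het, snv_sites$chrom[snv_het])
    het_sv <- which(g_sv_t == 1L)
    for (k in het_sv) {
      type <- rt$svtype[k]
      entry <- list(sample = smp, svtype = type, assessed = FALSE, flipped = NA)
      if (!is.na(mi[k]) && g_sv_u[mi[k]] == 1L) {
        cand <- het_by_chrom[[rt$chrom[k]]]  # site rows are position-sorted
        pos <- snv_sites$start[cand]
        li <- findInterval(rt$start[k] - 1L, pos)  # nearest het SNV strictly left
        flanks <- c(if (length(cand) && li >= 1L && rt$start[k] - pos[li] <= window)
                      cand[li],
                    if (length(cand) && li < length(cand) &&
                        pos[li + 1L] - rt$start[k] <= window) cand[li + 1L])
        if (length(flanks)) {
          sv_cis_t <- alt_hap(sv_test$h1[k, i_t], sv_test$h2[k, i_t]) ==
            alt_hap(snv_test$h1[flanks, j_t], snv_test$h2[flanks, j_t])
          sv_cis_u <- alt_hap(sv_truth$h1[mi[k], i_u], sv_truth$h2[mi[k], i_u]) ==
            alt_hap(snv_truth$h1[flanks, j_u], snv_truth$h2[flanks, j_u])
          inconsistent <- sv_cis_t != sv_cis_u
          entry$assessed <- TRUE
          entry$flipped <- if (length(flanks) == 2L && inconsistent[1L] != inconsistent[2L]) {
            d <- abs(snv_sites$start[flanks] - rt$start[k])
            inconsistent[which.min(d)]
          } else all(inconsistent)
        }
      }
      res[[length(res) + 1L]] <- as.data.frame(entry, stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(list(per_type = NULL,
                overall = data.frame(n_het = 0L, n_assessed = 0L, n_flipped = 0L,
                                     flip_rate = NA_real_, assessed_fraction = NA_real_)))
  d <- do.call(rbind, res)
  agg <- function(dd) data.frame(
    n_het = nrow(dd), n_assessed = sum(dd$assessed),
    n_flipped = sum(dd$flipped[dd$assessed]),
    flip_rate = if (sum(dd$assessed)) sum(dd$flipped[dd$assessed]) / sum(dd$assessed)
                else NA_real_,
    assessed_fraction = mean(dd$assessed))
  per_type <- do.call(rbind, lapply(split(d, d$svtype), agg))
  per_type <- cbind(svtype = rownames(per_type), per_type)
  rownames(per_type) <- NULL
  list(per_type = per_type, overall = agg(d))
}

#' Trio-based parental flip rate of a child's phased genotypes
#'
#' At sites with unambiguous trio phase (excluding sites where child,
#' father and mother are all heterozygous, and de novo sites), duo/trio
#' logic determines which parent contributed the child's alternate
#' allele. One haplotype-to-parent orientation is chosen per chromosome
#' per child by majority vote; the flip rate is the fraction of assessed
#' sites inconsistent with that orientation.
#'
#' @param panel phased panel (sites, h1, h2) containing child and parent
#'   columns.
#' @param ped a \code{\link{pedigree}}.
#' @return data.frame per (child, chromosome): assessed count, flips,
#'   flip rate (NA when nothing is assessable).
#' @export
parental_flip_rate <- function(panel, ped) {
  tr <- ped$trios
  ids <- colnames(panel$h1)
  out <- list()
  for (i in seq_len(nrow(tr))) {
    ci <- match(tr$child[i], ids); fi <- match(tr$father[i], ids)
    mi <- match(tr$mother[i], ids)
    if (anyNA(c(ci, fi, mi))) stop("trio members absent from panel: ", tr$child[i])
    gc_ <- panel$h1[, ci] + panel$h2[, ci]
    gf <- panel$h1[, fi] + panel$h2[, fi]
    gm <- panel$h1[, mi] + panel$h2[, mi]
    het <- !is.na(gc_) & gc_ == 1L & !is.na(gf) & !is.na(gm)
    all_het <- gf == 1L & gm == 1L
    denovo <- gf == 0L & gm == 0L
    father_can <- gf > 0L & gm < 2L   # father donates alt, mother the ref
    mother_can <- gm > 0L & gf < 2L
    unamb <- het & !all_het & !denovo & (father_can != mother_can)
    paternal_alt <- father_can  # valid where unamb
    for (ch in unique(panel$sites$chrom)) {
      rows <- which(unamb & panel$sites$chrom == ch)
      if (!length(rows)) {
        out[[length(out) + 1L]] <- data.frame(
          child = tr$child[i], chrom = ch, n_assessed = 0L, n_flips = NA_integer_,
          flip_rate = NA_real_, stringsAsFactors = FALSE)
        next
      }
      # orientation A: child's h1 is the paternal haplotype
      alt_on_h1 <- panel$h1[rows, ci] == 1L
      consistent_A <- alt_on_h1 == paternal_alt[rows]
      flips <- min(sum(consistent_A), sum(!consistent_A))
      out[[length(out) + 1L]] <- data.frame(
        child = tr$child[i], chrom = ch, n_assessed = length(rows),
        n_flips = flips, flip_rate = flips / length(rows),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
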