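# Imputation performance evaluation: dosages, info score, hard-calling,
# genotype discordance, and info/MAF-binned variant counting.

#' Expected alternate-allele dosage of a genotype-probability table
#'
#' @param gp a \code{gp_table} (matrices p0, p1, p2).
#' @return numeric matrix of dosages p_het + 2 p_homalt in [0, 2].
#' @export
gp_dosage <- function(gp) gp$p1 + 2 * gp$p2

#' Validate a genotype-probability table
#'
#' Checks that probability triples are non-negative and sum to 1 within
#' tolerance.
#'
#' @param gp a \code{gp_table}.
#' @param tol sum tolerance (default 1e-6).
#' @return invisibly TRUE; errors on malformed triples.
#' @export
validate_gp <- function(gp, tol = 1e-6) {
  s <- gp$p0 + gp$p1 + gp$p2
  if (any(abs(s - 1) > tol, na.rm = TRUE) ||
      any(gp$p0 < 0 | gp$p1 < 0 | gp$p2 < 0, na.rm = TRUE))
    stop("malformed genotype-probability triples (must be >= 0 and sum to 1)")
  invisible(TRUE)
}

#' IMPUTE-style info score per site
#'
#' Variance-ratio formulation: with per-sample expected dosage
#' e_i = p_het + 2 p_homalt and second moment f_i = p_het + 4 p_homalt,
#' info = 1 - sum(f_i - e_i^2) / (2 N theta (1 - theta)) where
#' theta = sum(e_i) / (2N) is the expected allele frequency. Monomorphic
#' sites (theta 0 or 1) return 1 by convention.
#'
#' @param gp a \code{gp_table}.
#' @return numeric vector of per-site info scores in [0, 1].
#' @export
info_score <- function(gp) {
  validate_gp(gp)
  e <- gp$p1 + 2 * gp$p2
  f <- gp$p1 + 4 * gp$p2
  n <- ncol(e)
  theta <- rowSums(e) / (2 * n)
  denom <- 2 * n * theta * (1 - theta)
  info <- ifelse(denom > 0, 1 - rowSums(f - e^2) / denom, 1)
  pmin(1, pmax(0, info))
}

#' Hard-call genotypes from probability triples
#'
#' The genotype is the arg-max class when the maximum probability
#' reaches the threshold (0.90 is not below 0.90); otherwise missing.
#' Ties at the maximum above threshold are set missing with a warning
#' (defensive: impossible above 0.5).
#'
#' @param gp a \code{gp_table}.
#' @param threshold genotype-probability threshold (default 0.90).
#' @return integer matrix of genotype classes (0, 1, 2, NA missing).
#' @export
hard_call <- function(gp, threshold = 0.90) {
  validate_gp(gp)
  p <- cbind(as.vector(gp$p0), as.vector(gp$p1), as.vector(gp$p2))
  mx <- pmax(p[, 1L], p[, 2L], p[, 3L])
  call <- max.col(p, ties.method = "first") - 1L
  tie <- rowSums(p == mx) > 1L & mx >= threshold
  if (any(tie)) warning("tied maximum probabilities at threshold; set missing")
  call[mx < threshold | tie] <- NA_integer_
  matrix(call, nrow(gp$p0), ncol(gp$p0), dimnames = dimnames(gp$p0))
}

#' Per-sample genotype discordance of hard calls against truth
#'
#' Discordance = 1 - (matching non-missing hard calls / non-missing hard
#' calls), optionally restricted to a shared-site subset.
#'
#' @param calls integer genotype-class matrix from
#'   \code{\link{hard_call}}.
#' @param truth integer truth genotype-class matrix.
#' @param sites_keep optional logical vector restricting rows (e.g.
#'   sites shared across the panels under comparison).
#' @return data.frame per sample: non-missing count, matches,
#'   discordance (NA when no non-missing calls).
#' @export
gt_discordance <- function(calls, truth, sites_keep = NULL) {
  if (!is.null(sites_keep)) {
    calls <- calls[sites_keep, , drop = FALSE]
    truth <- truth[sites_keep, , drop = FALSE]
  }
  ok <- !is.na(calls) & !is.na(truth)
  n_call <- colSums(ok)
  n_match <- colSums(ok & calls == truth)
  data.frame(sample = colnames(calls), n_calls = n_call, n_match = n_match,
             discordance = ifelse(n_call > 0L, 1 - n_match / n_call, NA_real_),
             stringsAsFactors = FALSE)
}

#' Mean dosage r-squared per allele-frequency bin
#'
#' Squared Pearson correlation between imputed and truth dosages.
#' Default aggregation computes one r-squared per sample across the
#' sites of each AF bin and averages over samples; sites (or samples)
#' with zero dosage variance on either side are undefined and excluded
#' from means, with the exclusion count reported. AF for binning should
#' come from the reference panel (unrelated-sample AF).
#'
#' @param imputed,truth dosage matrices (sites x samples).
#' @param af per-site allele frequencies used for binning.
#' @param bins AF bin edges.
#' @param by \code{"sample"} (r2 per sample within bin, then averaged)
#'   or \code{"site"} (r2 per site across samples, then averaged).
#' @return data.frame per bin: mean r2, number of contributing units,
#'   number excluded as undefined.
#' @export
dosage_r2 <- function(imputed, truth, af,
                      bins = c(0, 0.005, 0.05, 0.5, 1),
                      by = c("sample", "site")) {
  by <- match.arg(by)
  stopifnot(all(dim(imputed) == dim(truth)), length(af) == nrow(imputed))
  bin <- cut(af, bins, include.lowest = TRUE)
  out <- lapply(levels(bin), function(bl) {
    rows <- which(bin == bl)
    if (!length(rows)) return(data.frame(bin = bl, mean_r2 = NA_real_,
                                         n = 0L, n_undefined = 0L))
    r2 <- if (by == "sample") {
      vapply(seq_len(ncol(imputed)), function(s) {
        x <- imputed[rows, s]; y <- truth[rows, s]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < 2L || stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0)
          return(NA_real_)
        stats::cor(x[ok], y[ok])^2
      }, 0)
    } else {
      vapply(rows, function(i) {
        x <- imputed[i, ]; y <- truth[i, ]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < 2L || stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0)
          return(NA_real_)
        stats::cor(x[ok], y[ok])^2
      }, 0)
    }
    data.frame(bin = bl, mean_r2 = mean(r2, na.rm = TRUE),
               n = sum(!is.na(r2)), n_undefined = sum(is.na(r2)))
  })
  do.call(rbind, out)
}

#' Count imputed variants by info cutoff and MAF bin
#'
#' Counts per (info threshold, MAF bin) cell with strict \code{>} at the
#' thresholds; a site exceeding the higher cutoff is counted under every
#' lower cutoff too, so counts are nested. MAF here is the imputed-set
#' minor allele frequency.
#'
#' @param info per-site info scores.
#' @param maf per-site minor allele frequencies.
#' @param thresholds info cutoffs (default 0.4 and 0.8).
#' @param bins MAF bin edges (default very rare < 0.5%, rare 0.5-5%,
#'   common >= 5%).
#' @return integer matrix, thresholds x bins.
#' @export
count_by_info_and_maf <- function(info, maf, thresholds = c(0.4, 0.8),
                                  bins = c(0, 0.005, 0.05, 0.5)) {
  bin <- cut(maf, bins, include.lowest = TRUE, right = FALSE)
  levels(bin) <- c("very_rare", "rare", "common")[seq_along(levels(bin))]
  out <- t(vapply(thresholds, function(th)
    table(bin[info > th]), integer(nlevels(bin))))
  rownames(out) <- paste0("info>", thresholds)
  out
}
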