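# Haplotype-panel site filtering: Hardy-Weinberg tests, the
# PASS/missingness/HWE/MER/MAC cascade, and male-X ploidy correction.

#' Hardy-Weinberg exact test p-value
#'
#' Two-sided exact conditional test on genotype counts: given the sample
#' size and minor-allele count, the p-value is the sum of probabilities
#' of all heterozygote counts whose conditional probability does not
#' exceed that of the observed configuration (Wigginton-style, not
#' mid-p). Monomorphic sites return 1 by convention.
#'
#' @param hom_ref,het,hom_alt genotype counts (vectorised).
#' @return p-values in (0, 1].
#' @export
hwe_exact_p <- function(hom_ref, het, hom_alt) {
  mapply(hwe_exact_p1, hom_ref, het, hom_alt)
}

hwe_exact_p1 <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n < 1L) stop("at least one individual required")
  n_a <- 2L * n_aa + n_ab
  n_b <- 2L * n_bb + n_ab
  rare <- min(n_a, n_b)
  if (rare == 0L) return(1)
  # het counts share the parity of the rare-allele count
  hets <- seq(rare %% 2L, rare, by = 2L)
  logp <- hets * log(2) - lfactorial((rare - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (rare + hets) / 2) +
    lfactorial(n_a) + lfactorial(n_b) - lfactorial(2L * n) + lfactorial(n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_ab, hets)]
  min(1, sum(p[p <= obs + 1e-12]))
}

#' Hardy-Weinberg 1-df chi-square test p-value
#'
#' Chi-square goodness-of-fit of the genotype counts against
#' Hardy-Weinberg expectations from the sample allele frequency.
#' Monomorphic sites (any expected cell 0) return 1 by convention with a
#' warning.
#'
#' @inheritParams hwe_exact_p
#' @return p-values in (0, 1].
#' @export
hwe_chisq_p <- function(hom_ref, het, hom_alt) {
  mapply(function(n0, n1, n2) {
    n <- n0 + n1 + n2
    if (n < 1L) stop("at least one individual required")
    p <- (2 * n2 + n1) / (2 * n)
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    if (any(e == 0)) {
      warning("expected genotype count of zero; returning p = 1")
      return(1)
    }
    x2 <- sum((c(n0, n1, n2) - e)^2 / e)
    stats::pchisq(x2, df = 1L, lower.tail = FALSE)
  }, hom_ref, het, hom_alt)
}

#' Apply the haplotype-panel site-filter cascade
#'
#' A site is retained iff all criteria hold: VCF FILTER is PASS,
#' genotype missingness < 5%, Hardy-Weinberg exact-test p-value > 1e-10
#' in at least one super-population, Mendelian error rate <= 5%, and
#' minor allele count >= 2 (singletons are uninformative for phasing).
#' Verdicts are computed independently and conjoined, so the retained
#' set is order-free; the reported first-failing criterion follows the
#' order above.
#'
#' @param panel list with \code{sites} and allele matrices \code{h1},
#'   \code{h2}.
#' @param ped a \code{\link{pedigree}} carrying super-population labels.
#' @param max_missing,min_hwe_p,max_mer,min_mac thresholds (strict
#'   inequalities exactly as stated above).
#' @param hwe_test \code{"exact"} or \code{"chisq"}.
#' @param mer optional precomputed \code{\link{mendelian_error_rate}}
#'   result; computed from the panel when NULL.
#' @return list: \code{retained} logical vector, \code{decisions}
#'   data.frame (per-criterion verdicts and \code{first_fail}).
#' @export
apply_panel_filters <- function(panel, ped, max_missing = 0.05,
                                min_hwe_p = 1e-10, max_mer = 0.05,
                                min_mac = 2L, hwe_test = c("exact", "chisq"),
                                mer = NULL) {
  hwe_test <- match.arg(hwe_test)
  s <- panel$sites; h1 <- panel$h1; h2 <- panel$h2
  samp <- ped$samples
  if (!all(colnames(h1) %in% samp$id))
    stop("panel samples missing from pedigree")
  sp <- samp$superpop[match(colnames(h1), samp$id)]
  if (any(!is.na(sp) & !sp %in% superpops()))
    stop("unknown super-population label: ",
         setdiff(unique(sp), superpops())[1L])

  pass <- !is.na(s$filter) & s$filter == "PASS"
  miss <- rowMeans(is.na(h1))
  miss_ok <- miss < max_missing

  hwe_fun <- if (hwe_test == "exact") hwe_exact_p else hwe_chisq_p
  hwe_ok <- rep(FALSE, nrow(s))
  for (pop in unique(sp[!is.na(sp)])) {
    ii <- which(sp == pop)
    g <- gt_class(h1[, ii, drop = FALSE], h2[, ii, drop = FALSE])
    n0 <- rowSums(g == 0L, na.rm = TRUE)
    n1 <- rowSums(g == 1L, na.rm = TRUE)
    n2 <- rowSums(g == 2L, na.rm = TRUE)
    nonzero <- (n0 + n1 + n2) > 0L
    p <- rep(1, nrow(s))
    p[nonzero] <- hwe_fun(n0[nonzero], n1[nonzero], n2[nonzero])
    hwe_ok <- hwe_ok | (p > min_hwe_p)
  }

  if (is.null(mer)) mer <- mendelian_error_rate(h1, h2, ped)
  mer_ok <- is.na(mer$mer) | mer$mer <= max_mer  # undefined MER passes through

  stats_ <- site_allele_stats(h1, h2)
  mac <- pmin(stats_$AC, stats_$AN - stats_$AC)
  mac_ok <- mac >= min_mac

  verdicts <- unname(cbind(filter_pass = pass, missingness = miss_ok,
                           hwe = hwe_ok, mer = mer_ok, mac = mac_ok))
  colnames(verdicts) <- c("filter_pass", "missingness", "hwe", "mer", "mac")
  retained <- rowSums(!verdicts) == 0L
  first_fail <- apply(verdicts, 1L, function(v)
    if (all(v)) NA_character_ else colnames(verdicts)[which(!v)[1L]])
  decisions <- data.frame(site = s$id %||% seq_len(nrow(s)), verdicts,
                          retained = retained, first_fail = first_fail,
                          stringsAsFactors = FALSE)
  list(retained = retained, decisions = decisions)
}

#' Re-apply the minor-allele-count filter after phasing
#'
#' Phasing-side edits can leave sites below the informative MAC bound;
#' this removes sites whose MAC has dropped under the threshold.
#'
#' @param panel panel list (sites, h1, h2).
#' @param min_mac minimum minor allele count (default 2).
#' @return logical vector of sites kept.
#' @export
recheck_mac <- function(panel, min_mac = 2L) {
  stats_ <- site_allele_stats(panel$h1, panel$h2)
  mac <- pmin(stats_$AC, stats_$AN - stats_$AC)
  mac >= min_mac
}

#' Convert male chromosome-X genotypes to haploid outside the PARs
#'
#' In non-pseudoautosomal regions of chromosome X, male diploid
#' genotypes containing an alternate allele become haploid \code{"1"}
#' and \code{"0|0"}/\code{"0/0"} become haploid \code{"0"}. PAR regions
#' and female samples are untouched; already-haploid calls are a no-op.
#'
#' @param panel panel list (sites, h1, h2) with chrX records.
#' @param ped a \code{\link{pedigree}} (source of sample sex).
#' @param par_intervals PAR interval table (default GRCh38).
#' @param x_chrom chromosome-X name (default "chrX").
#' @return the panel with corrected h1/h2 (haploid: h2 = NA).
#' @export
fix_male_x_ploidy <- function(panel, ped, par_intervals = par_regions_grch38(),
                              x_chrom = "chrX") {
  s <- panel$sites
  on_x <- s$chrom == x_chrom
  if (!any(on_x)) return(panel)
  gr_x <- as_gr(s[on_x, , drop = FALSE])
  in_par <- IRanges::overlapsAny(gr_x, as_gr(par_intervals, min_width1 = FALSE))
  target <- which(on_x)[!in_par]
  males <- which(ped$samples$sex[match(colnames(panel$h1), ped$samples$id)] == "male")
  for (m in males) {
    h1 <- panel$h1[target, m]; h2 <- panel$h2[target, m]
    dip <- !is.na(h1) & !is.na(h2)
    panel$h1[target[dip], m] <- pmax(h1[dip], h2[dip])  # any alt -> "1"
    panel$h2[target[dip], m] <- NA_integer_
  }
  panel
}
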