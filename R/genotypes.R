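# Genotype representation
#
# Internally a genotype matrix is a pair of integer allele matrices
# (h1, h2), sites x samples. Conventions:
#   - h1 = NA and h2 = NA          -> missing call
#   - h1 set,  h2 = NA             -> haploid call (male non-PAR X, chrY)
#   - both set                     -> diploid call
# In phased panels h1/h2 are ordered haplotypes; for trio children the
# convention is h1 = paternal, h2 = maternal. Missing is a distinct state
# and is never conflated with homozygous reference.

#' Decompose VCF-style genotype strings into allele matrices
#'
#' @param gt character vector or matrix of GT strings such as
#'   \code{"0/1"}, \code{"1|0"}, \code{"1"} (haploid) or \code{"./."}.
#' @return list with integer components \code{h1}, \code{h2} (allele
#'   indices, \code{NA} for missing; \code{h2} \code{NA} for haploid
#'   calls) and logical \code{phased}, all shaped like \code{gt}.
#' @export
gt_decompose <- function(gt) {
  u <- unique(as.vector(gt))
  parse1 <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(c(NA, NA, 0L))
    phased <- grepl("|", g, fixed = TRUE)
    parts <- strsplit(g, "[/|]")[[1]]
    a <- suppressWarnings(as.integer(parts))
    if (length(a) == 1L) return(c(a, NA, as.integer(phased)))
    if (anyNA(a)) return(c(NA, NA, 0L))  # half-missing treated as missing
    c(a[1L], a[2L], as.integer(phased))
  }
  tab <- vapply(u, parse1, numeric(3))
  idx <- match(as.vector(gt), u)
  shape <- function(x) {
    if (is.matrix(gt)) matrix(x, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    else unname(x)
  }
  list(h1 = shape(as.integer(tab[1L, idx])),
       h2 = shape(as.integer(tab[2L, idx])),
       phased = shape(tab[3L, idx] == 1))
}

#' Compose genotype strings from allele matrices
#'
#' @param h1,h2 integer allele matrices (see \code{\link{gt_decompose}}).
#' @param phased logical scalar or matrix; phased genotypes use
#'   \code{"|"}, unphased \code{"/"}.
#' @return character object shaped like \code{h1}.
#' @export
gt_compose <- function(h1, h2, phased = TRUE) {
  sep <- ifelse(phased, "|", "/")
  out <- ifelse(is.na(h1), "./.",
         ifelse(is.na(h2), as.character(h1),
                paste0(h1, sep, h2)))
  if (is.matrix(h1)) out <- matrix(out, nrow(h1), ncol(h1), dimnames = dimnames(h1))
  out
}

#' Alternate-allele dosage from allele matrices
#'
#' Haploid calls contribute their single allele; missing calls give NA.
#'
#' @inheritParams gt_compose
#' @return numeric object shaped like \code{h1} with values in [0, 2]
#'   (diploid) or [0, 1] (haploid).
#' @export
gt_dosage <- function(h1, h2) {
  d <- h1 + ifelse(is.na(h2) & !is.na(h1), 0L, h2)
  d
}

# diploid genotype class: 0 hom-ref, 1 het, 2 hom-alt, NA missing/haploid
gt_class <- function(h1, h2) {
  g <- h1 + h2
  g[is.na(h2) & !is.na(h1)] <- NA_integer_  # haploid excluded from diploid counts
  g
}

# genotype counts (hom-ref, het, hom-alt) over diploid biallelic calls
genotype_counts <- function(h1, h2) {
  g <- gt_class(h1, h2)
  c(hom_ref = sum(g == 0L, na.rm = TRUE),
    het = sum(g == 1L, na.rm = TRUE),
    hom_alt = sum(g == 2L, na.rm = TRUE))
}

# unordered genotype equality ("0/1" == "1/0"); haploid compares its allele
gt_equal <- function(h1a, h2a, h1b, h2b) {
  lo_a <- pmin(h1a, h2a); hi_a <- pmax(h1a, h2a)
  lo_b <- pmin(h1b, h2b); hi_b <- pmax(h1b, h2b)
  hap_a <- is.na(h2a) & !is.na(h1a)
  hap_b <- is.na(h2b) & !is.na(h1b)
  out <- lo_a == lo_b & hi_a == hi_b
  out[hap_a & hap_b] <- (h1a == h1b)[hap_a & hap_b]
  out[hap_a != hap_b] <- FALSE
  out[is.na(h1a) | is.na(h1b)] <- NA
  out
}

#' Per-site allele count, allele number and frequency
#'
#' Computed over all samples (related included), counting haploid calls
#' once and skipping missing calls.
#'
#' @inheritParams gt_compose
#' @return data.frame with columns AC, AN, AF (one row per site).
#' @export
site_allele_stats <- function(h1, h2) {
  ac <- rowSums(h1 > 0L, na.rm = TRUE) + rowSums(h2 > 0L, na.rm = TRUE)
  an <- rowSums(!is.na(h1)) + rowSums(!is.na(h2))
  af <- ifelse(an > 0L, ac / an, NA_real_)
  data.frame(AC = ac, AN = an, AF = af)
}
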