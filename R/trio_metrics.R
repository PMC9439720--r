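# Trio-based quality metrics: Mendelian error rate, de novo and
# inheritance rates, parental transmission, singleton stratification.

# Mendelian compatibility over diploid genotype classes (0 hom-ref,
# 1 het, 2 hom-alt): child must draw one allele from each parent.
# Precomputed 3x3x3 lookup [father, mother, child].
mendel_comp_table <- local({
  alleles <- list(`0` = 0L, `1` = c(0L, 1L), `2` = 1L)  # possible gametes
  gametes <- function(g) alleles[[as.character(g)]]
  arr <- array(FALSE, c(3L, 3L, 3L))
  for (gf in 0:2) for (gm in 0:2) for (gc in 0:2) {
    pair <- if (gc == 1L) list(c(0L, 1L), c(1L, 0L)) else list(c(gc / 2L, gc / 2L))
    ok <- any(vapply(pair, function(p)
      p[1L] %in% gametes(gf) && p[2L] %in% gametes(gm), TRUE))
    arr[gf + 1L, gm + 1L, gc + 1L] <- ok
  }
  arr
})

# compatibility of one trio's calls at a vector of sites; haploid child
# calls (male non-PAR X) must draw their single allele from the mother
trio_compatible <- function(c1, c2, f1, f2, m1, m2) {
  out <- rep(NA, length(c1))
  hap_c <- !is.na(c1) & is.na(c2)
  complete <- !is.na(c1) & !is.na(f1) & !is.na(m1)
  dip <- complete & !hap_c & !is.na(c2) & !is.na(f2) & !is.na(m2)
  out[dip] <- mendel_comp_table[cbind(f1[dip] + f2[dip] + 1L,
                                      m1[dip] + m2[dip] + 1L,
                                      c1[dip] + c2[dip] + 1L)]
  hap <- complete & hap_c
  if (any(hap)) {  # haploid child on X: the single allele must be maternal
    m_has <- (m1[hap] == c1[hap]) | (!is.na(m2[hap]) & m2[hap] == c1[hap])
    out[hap] <- m_has
  }
  hap_f <- complete & !hap_c & !is.na(c2) & is.na(f2) & !is.na(m2)
  if (any(hap_f)) {  # haploid father (X), diploid daughter
    in_m <- function(a, i) (m1[i] == a) | (m2[i] == a)
    out[hap_f] <- (c1[hap_f] == f1[hap_f] & in_m(c2[hap_f], hap_f)) |
                  (c2[hap_f] == f1[hap_f] & in_m(c1[hap_f], hap_f))
  }
  out
}

#' Per-site Mendelian error rate over complete trios
#'
#' A trio is an error at a site when the child's genotype cannot be
#' formed by drawing one allele from each parent. Trios with any missing
#' member are excluded from that site's denominator; sites with zero
#' complete trios get \code{NA} (undefined, never 0).
#'
#' @param h1,h2 cohort allele matrices (sites x samples).
#' @param ped a \code{\link{pedigree}}.
#' @return data.frame per site: \code{n_complete}, \code{n_error},
#'   \code{mer}.
#' @export
mendelian_error_rate <- function(h1, h2, ped) {
  tr <- ped$trios
  n <- nrow(h1)
  n_complete <- integer(n); n_error <- integer(n)
  ids <- colnames(h1)
  for (i in seq_len(nrow(tr))) {
    ci <- match(tr$child[i], ids); fi <- match(tr$father[i], ids)
    mi <- match(tr$mother[i], ids)
    ok <- trio_compatible(h1[, ci], h2[, ci], h1[, fi], h2[, fi],
                          h1[, mi], h2[, mi])
    comp <- !is.na(ok)
    n_complete <- n_complete + comp
    n_error <- n_error + (comp & !ok)
  }
  data.frame(site = rownames(h1) %||% seq_len(n),
             n_complete = n_complete, n_error = n_error,
             mer = ifelse(n_complete > 0L, n_error / n_complete, NA_real_))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' De novo and inheritance rates per trio child
#'
#' The child inheritance rate is the fraction of the child's
#' non-reference variants present (non-reference) in at least one
#' parent; the de novo rate is its complement.
#'
#' @param h1,h2 cohort allele matrices.
#' @param ped a \code{\link{pedigree}}; every trio child is assessed.
#' @return list: \code{per_child} data.frame and \code{overall}
#'   (pooled counts and rates).
#' @export
trio_inheritance <- function(h1, h2, ped) {
  tr <- ped$trios
  if (nrow(tr) == 0L) stop("no complete trios in pedigree")
  ids <- colnames(h1)
  g <- gt_dosage(h1, h2)
  rows <- lapply(seq_len(nrow(tr)), function(i) {
    ci <- match(tr$child[i], ids); fi <- match(tr$father[i], ids)
    mi <- match(tr$mother[i], ids)
    nonref <- which(g[, ci] > 0)
    inh <- sum(g[nonref, fi] > 0 | g[nonref, mi] > 0, na.rm = TRUE)
    data.frame(child = tr$child[i], n_nonref = length(nonref), n_inherited = inh,
               stringsAsFactors = FALSE)
  })
  pc <- do.call(rbind, rows)
  pc$inheritance_rate <- ifelse(pc$n_nonref > 0, pc$n_inherited / pc$n_nonref, NA)
  pc$denovo_rate <- 1 - pc$inheritance_rate
  tot_nonref <- sum(pc$n_nonref); tot_inh <- sum(pc$n_inherited)
  list(per_child = pc,
       overall = data.frame(n_nonref = tot_nonref, n_inherited = tot_inh,
                            inheritance_rate = tot_inh / tot_nonref,
                            denovo_rate = 1 - tot_inh / tot_nonref))
}

#' Parental transmission rate over informative sites
#'
#' Informative sites are heterozygous in exactly one parent and absent
#' (reference) in the other; the transmission rate is the fraction of
#' such variants observed in the child, expected 0.5 under Mendelian
#' segregation.
#'
#' @param h1,h2 cohort allele matrices.
#' @param ped a \code{\link{pedigree}}.
#' @return list: \code{per_trio} data.frame and \code{overall} pooled
#'   rate.
#' @export
parental_transmission <- function(h1, h2, ped) {
  tr <- ped$trios
  ids <- colnames(h1)
  g <- gt_dosage(h1, h2)
  rows <- lapply(seq_len(nrow(tr)), function(i) {
    ci <- match(tr$child[i], ids); fi <- match(tr$father[i], ids)
    mi <- match(tr$mother[i], ids)
    info <- which((g[, fi] == 1 & g[, mi] == 0) | (g[, mi] == 1 & g[, fi] == 0))
    data.frame(child = tr$child[i], n_informative = length(info),
               n_transmitted = sum(g[info, ci] > 0, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  pt <- do.call(rbind, rows)
  pt$transmission_rate <- ifelse(pt$n_informative > 0,
                                 pt$n_transmitted / pt$n_informative, NA)
  list(per_trio = pt,
       overall = data.frame(n_informative = sum(pt$n_informative),
                            n_transmitted = sum(pt$n_transmitted),
                            transmission_rate = sum(pt$n_transmitted) /
                              sum(pt$n_informative)))
}

#' Singleton profile per sample, stratified by pedigree role
#'
#' Singletons are alleles with cohort-wide allele count exactly 1
#' (computed over all samples, related included). Also reports
#' within-family private-variant counts at cohort AC 2-4 and the
#' role-stratified mean singleton counts with the arithmetic consistency
#' check mean(parent) vs (mean(child) + mean(unrelated)) / 2. Duo
#' children are excluded from the child stratum and reported separately.
#'
#' @param h1,h2 cohort allele matrices.
#' @param ped a \code{\link{pedigree}}.
#' @return list: \code{per_sample}, \code{family_private},
#'   \code{role_means}.
#' @export
singleton_profile <- function(h1, h2, ped) {
  s <- ped$samples
  g <- gt_dosage(h1, h2)
  ac <- rowSums(g, na.rm = TRUE)
  single <- which(ac == 1)
  counts <- setNames(integer(ncol(g)), colnames(g))
  if (length(single)) {
    hit <- which(g[single, , drop = FALSE] > 0, arr.ind = TRUE)
    tab <- table(colnames(g)[hit[, 2L]])
    counts[names(tab)] <- as.integer(tab)
  }
  per_sample <- data.frame(id = names(counts), singletons = as.integer(counts),
                           role = s$role[match(names(counts), s$id)],
                           duo = s$duo[match(names(counts), s$id)],
                           stringsAsFactors = FALSE)

  tr <- ped$trios
  fam <- lapply(seq_len(nrow(tr)), function(i) {
    idx <- match(c(tr$father[i], tr$mother[i], tr$child[i]), colnames(g))
    fam_ac <- rowSums(g[, idx, drop = FALSE], na.rm = TRUE)
    priv <- ac %in% 2:4 & fam_ac == ac
    data.frame(child = tr$child[i],
               private_ac2 = sum(priv & ac == 2), private_ac3 = sum(priv & ac == 3),
               private_ac4 = sum(priv & ac == 4), stringsAsFactors = FALSE)
  })
  family_private <- if (length(fam)) do.call(rbind, fam) else NULL

  strat <- function(rl, drop_duo = FALSE) {
    ii <- per_sample$role == rl
    if (drop_duo) ii <- ii & !per_sample$duo
    mean(per_sample$singletons[ii])
  }
  m_child <- strat("child", drop_duo = TRUE)
  m_parent <- strat("parent")
  m_unrel <- mean(per_sample$singletons[per_sample$role == "unrelated" & !per_sample$duo])
  role_means <- data.frame(mean_child = m_child, mean_parent = m_parent,
                           mean_unrelated = m_unrel,
                           midpoint_child_unrelated = (m_child + m_unrel) / 2,
                           mean_duo_child = mean(per_sample$singletons[per_sample$duo]))
  list(per_sample = per_sample, family_private = family_private,
       role_means = role_means)
}
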