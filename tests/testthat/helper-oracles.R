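# Independent brute-force oracles used across the suite. These
# deliberately avoid the package's own code paths: naive loops, direct
# counting, exhaustive enumeration.

# reciprocal overlap computed naively for one pair
oracle_ro <- function(s1, e1, s2, e2) {
  ov <- min(e1, e2) - max(s1, s2)
  if (ov <= 0) return(0)
  min(ov / (e1 - s1), ov / (e2 - s2))
}

# concordance decision straight from the stated rules
oracle_concordant <- function(a, b) {
  if (a$svtype == "INS") return(abs(a$start - b$start) <= 100)
  ro <- oracle_ro(a$start, a$end, b$start, b$end)
  cut <- if (max(a$svlen, b$svlen) > 5000) 0.5 else 0.1
  ro >= cut
}

# single-linkage components by repeated breadth-first search over the
# all-pairs concordance graph
oracle_cluster <- function(rec) {
  n <- nrow(rec)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    if (rec$chrom[i] != rec$chrom[j] || rec$svtype[i] != rec$svtype[j]) next
    if (oracle_concordant(rec[i, ], rec[j, ])) adj[i, j] <- adj[j, i] <- TRUE
  }
  comp <- rep(NA_integer_, n); k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    frontier <- i
    while (length(frontier)) {
      comp[frontier] <- k
      frontier <- setdiff(which(rowSums(adj[, frontier, drop = FALSE]) > 0),
                          which(!is.na(comp)))
    }
  }
  comp
}

# exact HWE p-value by independent subset counting: choose h het
# individuals, orient each het, choose the minor-homozygous individuals
oracle_hwe_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  na <- min(2 * n0 + n1, 2 * n2 + n1)
  if (na == 0) return(1)
  hets <- seq(na %% 2, na, by = 2)
  logc <- lchoose(n, hets) + hets * log(2) +
    lchoose(n - hets, (na - hets) / 2) - lchoose(2 * n, na)
  p <- exp(logc - max(logc)); p <- p / sum(p)
  obs <- p[match(n1, hets)]
  min(1, sum(p[p <= obs + 1e-12]))
}

# fully exhaustive HWE distribution for tiny n: place the na minor
# alleles into the 2n allele slots in every possible way, pair
# consecutive slots into individuals, tally heterozygote counts
oracle_hwe_p_tiny <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  na <- min(2 * n0 + n1, 2 * n2 + n1)
  if (na == 0) return(1)
  slots <- utils::combn(2 * n, na)
  hets <- apply(slots, 2, function(ss) {
    x <- integer(2 * n); x[ss] <- 1L
    sum(x[seq(1, 2 * n, 2)] != x[seq(2, 2 * n, 2)])
  })
  tab <- table(hets) / length(hets)
  obs <- tab[as.character(n1)]
  sum(tab[tab <= obs + 1e-12])
}

# Mendelian compatibility by enumerating every parental gamete pair
oracle_mendel <- function(gc, gf, gm) {
  alleles <- function(g) switch(as.character(g), `0` = 0L, `1` = 0:1, `2` = 1L)
  child <- switch(as.character(gc), `0` = c(0L, 0L), `1` = c(0L, 1L), `2` = c(1L, 1L))
  for (fa in alleles(gf)) for (ma in alleles(gm))
    if (identical(sort(c(fa, ma)), sort(child))) return(TRUE)
  FALSE
}

# switch errors by explicit pairwise cis/trans comparison of every
# consecutive assessed heterozygous pair
oracle_switch_count <- function(t1, t2, u1, u2) {
  het <- which(t1 + t2 == 1L & u1 + u2 == 1L)
  if (length(het) < 2) return(c(switches = NA, pairs = max(0, length(het) - 1)))
  sw <- 0L
  for (k in seq_len(length(het) - 1L)) {
    i <- het[k]; j <- het[k + 1L]
    cis_t <- t1[i] == t1[j]
    cis_u <- u1[i] == u1[j]
    if (cis_t != cis_u) sw <- sw + 1L
  }
  c(switches = sw, pairs = length(het) - 1L)
}

# naive one-to-one greedy SV matching re-implementation
oracle_match <- function(set1, set2, window = 50, min_ratio = 0.8) {
  pairs <- list()
  for (i in seq_len(nrow(set1))) for (j in seq_len(nrow(set2))) {
    if (set1$svtype[i] != set2$svtype[j] || set1$chrom[i] != set2$chrom[j]) next
    d <- abs(set1$start[i] - set2$start[j])
    r <- min(set1$svlen[i], set2$svlen[j]) / max(set1$svlen[i], set2$svlen[j])
    if (d <= 2 * window && r >= min_ratio)
      pairs[[length(pairs) + 1L]] <- data.frame(i = i, j = j, d = d, r = r)
  }
  if (!length(pairs)) return(NULL)
  pp <- do.call(rbind, pairs)
  pp <- pp[order(pp$d, -pp$r), ]
  u1 <- logical(nrow(set1)); u2 <- logical(nrow(set2)); out <- list()
  for (k in seq_len(nrow(pp))) {
    if (u1[pp$i[k]] || u2[pp$j[k]]) next
    u1[pp$i[k]] <- u2[pp$j[k]] <- TRUE
    out[[length(out) + 1L]] <- pp[k, ]
  }
  do.call(rbind, out)
}

# random SV record table for clustering / matching oracles
random_sv_records <- function(n, chroms = "chr1", max_pos = 100000,
                              types = c("DEL", "INS", "DUP")) {
  svtype <- sample(types, n, replace = TRUE)
  start <- sample.int(max_pos, n, replace = TRUE)
  svlen <- pmax(50L, round(stats::rlnorm(n, log(500), 1.2)))
  end <- ifelse(svtype == "INS", start, start + svlen)
  data.frame(id = sprintf("r%04d", seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             start = start, end = as.integer(end), svtype = svtype,
             svlen = as.integer(svlen), stringsAsFactors = FALSE)
}

# tiny phased panel builder
tiny_panel <- function(h1, h2, chrom = "chr1", start = NULL) {
  n <- nrow(h1)
  if (is.null(start)) start <- seq_len(n) * 100L
  if (is.null(colnames(h1))) colnames(h1) <- colnames(h2) <- sprintf("S%02d", seq_len(ncol(h1)))
  list(sites = data.frame(id = sprintf("site%03d", seq_len(n)),
                          chrom = chrom, start = start,
                          ref = "A", alt = "T", filter = "PASS",
                          stringsAsFactors = FALSE),
       h1 = h1, h2 = h2, phased = TRUE)
}

# small default cohort shared by several tests (cached per session)
cached_cohort <- local({
  env <- new.env()
  function() {
    if (is.null(env$co)) {
      env$cfg <- sim_config(n_trios = 20L, n_unrelated = 40L,
                            n_sites = 600L, n_sv = 200L, seed = 11L)
      env$co <- simulate_cohort(env$cfg)
    }
    env$co
  }
})

# full study-scale cohort under the generator's default conditions
cached_default_cohort <- local({
  env <- new.env()
  function() {
    if (is.null(env$co)) env$co <- simulate_cohort(sim_config(seed = 101L))
    env$co
  }
})
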