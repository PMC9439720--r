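test_that("pedigree roles follow the trio definition", {
  ped <- pedigree(data.frame(id = c("F", "M", "C"),
                             father = c(NA, NA, "F"), mother = c(NA, NA, "M"),
                             sex = c("male", "female", "female")))
  expect_equal(nrow(ped$trios), 1L)
  roles <- setNames(ped$samples$role, ped$samples$id)
  expect_equal(roles[["F"]], "parent")
  expect_equal(roles[["M"]], "parent")
  expect_equal(roles[["C"]], "child")

  solo <- pedigree(data.frame(id = "X", father = NA, mother = NA, sex = "male"))
  expect_equal(solo$samples$role, "unrelated")

  expect_error(pedigree(data.frame(id = c("A", "A"), father = NA, mother = NA,
                                   sex = "male")), "duplicate")
  expect_error(pedigree(data.frame(id = c("A", "B"), father = c("B", "A"),
                                   mother = NA, sex = "male")), "ancestor")
})

test_that("a large cohort PED with trios, duos and singletons is classified correctly", {
  # 602 trios + 6 duos + 20 singletons, written as PED and read back
  rows <- character(0)
  for (i in 1:602)
    rows <- c(rows, sprintf("fam%d\tF%d\t0\t0\t1\t0", i, i),
                    sprintf("fam%d\tM%d\t0\t0\t2\t0", i, i),
                    sprintf("fam%d\tC%d\tF%d\tM%d\t1\t0", i, i, i, i))
  for (i in 1:6)  # duo: only one parent present in cohort
    rows <- c(rows, sprintf("duo%d\tDP%d\t0\t0\t1\t0", i, i),
                    sprintf("duo%d\tDC%d\tDP%d\tEXTM%d\t2\t0", i, i, i, i))
  for (i in 1:20)
    rows <- c(rows, sprintf("s%d\tS%d\t0\t0\t1\t0", i, i))
  path <- withr::local_tempfile(fileext = ".ped")
  writeLines(rows, path)
  ped <- read_pedigree(path)
  expect_equal(nrow(ped$trios), 602L)
  duo_children <- ped$samples[startsWith(ped$samples$id, "DC"), ]
  expect_true(all(duo_children$duo))
  expect_true(all(duo_children$role == "unrelated"))
  expect_equal(sum(ped$samples$role == "child"), 602L)
})

test_that("region classification handles SNVs, contained and border-spanning variants", {
  strat <- region_stratification(
    easy = genomic_intervals("chr1", c(0L, 2000L), c(1000L, 3000L)),
    difficult = genomic_intervals("chr1", 1000L, 2000L))
  expect_equal(classify_region(genomic_intervals("chr1", 500L, 501L), strat), "easy")
  expect_equal(classify_region(genomic_intervals("chr1", 1200L, 1210L), strat), "difficult")
  # 10-bp deletion straddling the easy/difficult border
  expect_equal(classify_region(genomic_intervals("chr1", 995L, 1005L), strat), "difficult")
  expect_error(classify_region(genomic_intervals("chr2", 10L, 11L), strat), "chr2")
  expect_error(region_stratification(
    easy = genomic_intervals("chr1", 0L, 1500L),
    difficult = genomic_intervals("chr1", 1000L, 2000L)), "disjoint")
})

test_that("region classification agrees with a per-base membership scan", {
  set.seed(42)
  # random disjoint easy/difficult tiling of [0, 10000)
  edges <- sort(sample(1:9999, 30))
  bounds <- c(0L, edges, 10000L)
  cls <- rep(c("easy", "difficult"), length.out = length(bounds) - 1L)
  easy <- genomic_intervals("chr1", bounds[-length(bounds)][cls == "easy"],
                            bounds[-1][cls == "easy"])
  diff_ <- genomic_intervals("chr1", bounds[-length(bounds)][cls == "difficult"],
                             bounds[-1][cls == "difficult"])
  strat <- region_stratification(easy, diff_)
  base_class <- rep(cls, times = diff(bounds))  # per-base lookup table
  n <- 10000L
  start <- sample(0:9989, n, replace = TRUE)
  width <- sample(1:10, n, replace = TRUE)
  v <- genomic_intervals("chr1", start, pmin(start + width, 10000L))
  got <- classify_region(v, strat)
  expected <- vapply(seq_len(n), function(i) {
    bases <- base_class[(v$start[i] + 1L):v$end[i]]
    if (any(bases == "difficult")) "difficult" else "easy"
  }, "")
  expect_identical(got, expected)
})

test_that("multiallelic splitting recodes genotypes and conserves allele counts", {
  sites <- data.frame(chrom = "chr1", start = 99L, ref = "A", alt = "C,T",
                      filter = "PASS", stringsAsFactors = FALSE)
  h1 <- matrix(1L, 1, 2); h2 <- matrix(2L, 1, 2)
  colnames(h1) <- colnames(h2) <- c("s1", "s2")
  sp <- split_multiallelics(sites, h1, h2)
  expect_equal(nrow(sp$sites), 2L)
  expect_equal(sp$sites$alt, c("C", "T"))
  # GT 1/2 -> (1,0) against C and (0,1) against T
  expect_equal(unname(sp$h1[1, ]), c(1L, 1L))
  expect_equal(unname(sp$h2[1, ]), c(0L, 0L))
  expect_equal(unname(sp$h1[2, ]), c(0L, 0L))
  expect_equal(unname(sp$h2[2, ]), c(1L, 1L))
  # summed alt counts over split records equal the source AC vector
  ac_split <- rowSums(sp$h1) + rowSums(sp$h2)
  expect_equal(unname(ac_split), c(2L, 2L))

  biallelic <- data.frame(chrom = "chr1", start = 10L, ref = "G", alt = "T",
                          filter = "PASS", stringsAsFactors = FALSE)
  sp2 <- split_multiallelics(biallelic, matrix(0L, 1, 1), matrix(1L, 1, 1))
  expect_equal(sp2$sites$ref, "G")
  expect_equal(sp2$sites$start, 10L)

  symbolic <- data.frame(chrom = "chr1", start = 5L, ref = "N", alt = "<DEL>",
                         filter = "PASS", stringsAsFactors = FALSE)
  expect_error(split_multiallelics(symbolic, matrix(0L, 1, 1), matrix(0L, 1, 1)),
               "SV")
})

test_that("INDEL left-normalisation matches exhaustive shared-base trimming", {
  # oracle: repeatedly strip one shared suffix base, then one shared
  # prefix base, until none remains (keeping at least one base each)
  oracle_trim <- function(ref, alt, pos) {
    repeat {
      rn <- nchar(ref); an <- nchar(alt)
      if (rn > 1 && an > 1 && substr(ref, rn, rn) == substr(alt, an, an)) {
        ref <- substr(ref, 1, rn - 1); alt <- substr(alt, 1, an - 1); next
      }
      if (rn > 1 && an > 1 && substr(ref, 1, 1) == substr(alt, 1, 1)) {
        ref <- substr(ref, 2, rn); alt <- substr(alt, 2, an); pos <- pos + 1; next
      }
      break
    }
    list(ref = ref, alt = alt, start = pos)
  }
  nz <- normalize_allele_pair("CAA", "CA", 100L)
  expect_equal(nz, oracle_trim("CAA", "CA", 100L))
  expect_equal(nz$ref, "CA"); expect_equal(nz$alt, "C")
  set.seed(7)
  for (k in 1:200) {
    ref <- paste(sample(c("A", "C"), sample(1:6, 1), replace = TRUE), collapse = "")
    alt <- paste(sample(c("A", "C"), sample(1:6, 1), replace = TRUE), collapse = "")
    expect_equal(normalize_allele_pair(ref, alt, 50L), oracle_trim(ref, alt, 50L))
  }
})

test_that("VCF round-trip preserves coordinates, genotypes and INFO", {
  co <- cached_cohort()
  path <- withr::local_tempfile(fileext = ".vcf")
  write_small_vcf(co$smallvar, path)
  rt <- read_small_vcf(path)
  expect_equal(rt$sites$chrom, co$smallvar$sites$chrom)
  expect_equal(rt$sites$start, co$smallvar$sites$start)
  expect_equal(rt$sites$ref, co$smallvar$sites$ref)
  expect_identical(unname(rt$h1), unname(co$smallvar$h1))
  expect_identical(unname(rt$h2), unname(co$smallvar$h2))
  st <- site_allele_stats(co$smallvar$h1, co$smallvar$h2)
  expect_equal(rt$sites$AC, st$AC)
  expect_equal(rt$sites$AF, st$AF, tolerance = 1e-6)

  svp <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(co$sv, svp)
  rs <- read_sv_vcf(svp)
  expect_equal(rs$records$start, co$sv$records$start)
  expect_equal(rs$records$end, co$sv$records$end)
  expect_equal(rs$records$svtype, co$sv$records$svtype)
  expect_equal(rs$records$svlen, co$sv$records$svlen)
  expect_identical(unname(rs$h1), unname(co$sv$h1))
  expect_equal(unname(rs$evidence$sr), unname(co$sv$evidence$sr))
})

test_that("genotype decomposition keeps haploid and missing calls distinct", {
  dec <- gt_decompose(c("0/1", "1|0", "1", "0", "./.", "."))
  expect_equal(dec$h1, c(0L, 1L, 1L, 0L, NA, NA))
  expect_equal(dec$h2, c(1L, 0L, NA, NA, NA, NA))
  expect_equal(dec$phased, c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(gt_compose(1L, NA_integer_), "1")
  expect_equal(gt_compose(NA_integer_, NA_integer_), "./.")
  # haploid dosage is the single allele; missing propagates
  expect_equal(gt_dosage(1L, NA_integer_), 1L)
  expect_true(is.na(gt_dosage(NA_integer_, NA_integer_)))
})
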