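trio_panel <- function(gts) {
  # gts: matrix of genotype classes (0/1/2/NA), one column per sample
  h1 <- (gts == 2L) * 1L
  h2 <- (gts >= 1L) * 1L
  h1[is.na(gts)] <- NA_integer_; h2[is.na(gts)] <- NA_integer_
  colnames(h1) <- colnames(h2) <- colnames(gts)
  list(h1 = h1, h2 = h2)
}

simple_ped <- function() pedigree(data.frame(
  id = c("F", "M", "C"), father = c(NA, NA, "F"), mother = c(NA, NA, "M"),
  sex = c("male", "female", "female")))

test_that("Mendelian error rate counts incompatible complete trios only", {
  ped <- pedigree(data.frame(
    id = c("F1", "M1", "C1", "F2", "M2", "C2"),
    father = c(NA, NA, "F1", NA, NA, "F2"),
    mother = c(NA, NA, "M1", NA, NA, "M2"),
    sex = c("male", "female", "male", "male", "female", "female")))
  # site 1: trio1 error (0/0 x 0/0 -> 0/1), trio2 consistent -> MER 0.5
  # site 2: all consistent -> 0; site 3: trio1 missing -> only trio2 counted
  gts <- matrix(c(1L, 0L, 0L,  1L, 1L, 0L,
                  0L, 0L, 0L,  1L, 1L, 1L,
                  NA, 0L, 0L,  2L, 1L, 1L),
                3, 6, byrow = TRUE,
                dimnames = list(NULL, c("C1", "F1", "M1", "C2", "F2", "M2")))
  tp <- trio_panel(gts)
  mer <- mendelian_error_rate(tp$h1, tp$h2, ped)
  expect_equal(mer$mer, c(0.5, 0, 0))
  expect_equal(mer$n_complete, c(2L, 2L, 1L))
  # zero complete trios -> NA, not 0
  gts_na <- matrix(NA_integer_, 1, 6, dimnames = list(NULL, colnames(gts)))
  tpn <- trio_panel(gts_na)
  expect_true(is.na(mendelian_error_rate(tpn$h1, tpn$h2, ped)$mer))
})

test_that("Mendelian calls match gamete enumeration over random trios", {
  ped <- simple_ped()
  set.seed(15)
  n <- 1200L
  gc_ <- sample(0:2, n, TRUE); gf <- sample(0:2, n, TRUE); gm <- sample(0:2, n, TRUE)
  gts <- cbind(C = gc_, F = gf, M = gm)
  tp <- trio_panel(gts)
  mer <- mendelian_error_rate(tp$h1, tp$h2, ped)
  want <- !vapply(seq_len(n), function(i) oracle_mendel(gc_[i], gf[i], gm[i]), TRUE)
  expect_equal(mer$n_error == 1L, want)
})

test_that("haploid X logic requires the maternal allele", {
  ped <- pedigree(data.frame(id = c("F", "M", "C"), father = c(NA, NA, "F"),
                             mother = c(NA, NA, "M"), sex = c("male", "female", "male")))
  # son haploid: allele must come from mother, father irrelevant
  h1 <- matrix(c(1L, 1L, 0L,   # C=1, F=1, M=0/0 -> error
                 1L, 0L, 1L,   # C=1, F=0, M=1/0 -> fine
                 0L, 1L, 1L),  # C=0, F=1, M=1/1 -> error
               3, 3, byrow = TRUE, dimnames = list(NULL, c("C", "F", "M")))
  h2 <- matrix(c(NA, NA, 0L,
                 NA, NA, 0L,
                 NA, NA, 1L), 3, 3, byrow = TRUE, dimnames = dimnames(h1))
  mer <- mendelian_error_rate(h1, h2, ped)
  expect_equal(mer$n_error, c(1L, 0L, 1L))
})

test_that("inheritance and de novo rates are complementary and correct", {
  ped <- simple_ped()
  # child carries 10 variants, 9 seen in a parent
  h1 <- matrix(0L, 12, 3, dimnames = list(NULL, c("F", "M", "C")))
  h2 <- h1
  h1[1:10, "C"] <- 1L
  h1[1:5, "F"] <- 1L; h1[6:9, "M"] <- 1L
  ti <- trio_inheritance(h1, h2, ped)
  expect_equal(ti$per_child$inheritance_rate, 0.9)
  expect_equal(ti$per_child$denovo_rate, 0.1)
  expect_equal(ti$per_child$inheritance_rate + ti$per_child$denovo_rate, 1)
  expect_error(trio_inheritance(h1, h2,
    pedigree(data.frame(id = "X", father = NA, mother = NA, sex = "male"))),
    "no complete trios")
})

test_that("SV de novo rate configured at 3.5% is recovered within 3 binomial sd", {
  cfg <- sim_config(n_trios = 40L, n_unrelated = 20L, n_sites = 50L,
                    n_sv = 1500L, sv_denovo_rate = 0.035, seed = 33L)
  co <- simulate_cohort(cfg)
  ti <- trio_inheritance(co$sv$h1, co$sv$h2, co$pedigree)
  n <- ti$overall$n_nonref
  expect_gt(n, 2000)
  expect_lt(abs(ti$overall$denovo_rate - 0.035), 3 * sqrt(0.035 * 0.965 / n))
})

test_that("transmission rate uses informative sites and approaches one half", {
  ped <- simple_ped()
  # 4 informative sites (father het, mother ref), 2 transmitted;
  # a hom-alt parent site and a double-het site must be excluded
  h1 <- matrix(c(1L, 0L, 1L,
                 1L, 0L, 1L,
                 1L, 0L, 0L,
                 1L, 0L, 0L,
                 1L, 1L, 1L,   # hom-alt father -> not informative
                 1L, 1L, 1L),  # both het -> not informative
               6, 3, byrow = TRUE, dimnames = list(NULL, c("F", "M", "C")))
  h2 <- matrix(c(0L, 0L, 0L,
                 0L, 0L, 0L,
                 0L, 0L, 0L,
                 0L, 0L, 0L,
                 1L, 0L, 0L,
                 0L, 1L, 0L), 6, 3, byrow = TRUE, dimnames = dimnames(h1))
  pt <- parental_transmission(h1, h2, ped)
  expect_equal(pt$per_trio$n_informative, 4L)
  expect_equal(pt$overall$transmission_rate, 0.5)

  co <- cached_default_cohort()
  # de-novo-free segregation check needs a clean cohort
  cfg0 <- co$config; cfg0$denovo_rate <- 0; cfg0$seed <- 55L
  cfg0$n_sites <- 1500L
  co0 <- simulate_cohort(cfg0)
  pt0 <- parental_transmission(co0$smallvar$h1, co0$smallvar$h2, co0$pedigree)
  n <- pt0$overall$n_informative
  expect_gt(n, 5000)
  expect_lt(abs(pt0$overall$transmission_rate - 0.5), 3 * sqrt(0.25 / n))
})

test_that("singleton profile assigns singletons and family-private variants", {
  ped <- pedigree(data.frame(
    id = c("F", "M", "C", "U"),
    father = c(NA, NA, "F", NA), mother = c(NA, NA, "M", NA),
    sex = c("male", "female", "female", "male")))
  h1 <- matrix(0L, 3, 4, dimnames = list(NULL, c("F", "M", "C", "U")))
  h2 <- h1
  h1[1, "C"] <- 1L; h1[1, "F"] <- 1L    # AC 2, family-private, no singleton
  h1[2, "U"] <- 1L                       # U's singleton
  h1[3, "M"] <- 1L                       # M's singleton
  sp <- singleton_profile(h1, h2, ped)
  counts <- setNames(sp$per_sample$singletons, sp$per_sample$id)
  expect_equal(unname(counts[c("F", "M", "C", "U")]), c(0L, 1L, 0L, 1L))
  expect_equal(sp$family_private$private_ac2, 1L)
})

test_that("parent singleton mean sits midway between child and unrelated means", {
  # family-private variants split 50/50 between the parents by
  # construction in the generator, so parents accumulate roughly half
  # the untransmitted private variation
  co <- cached_default_cohort()
  sp <- singleton_profile(co$smallvar$h1, co$smallvar$h2, co$pedigree)
  rm_ <- sp$role_means
  expect_lt(rm_$mean_child, rm_$mean_parent)
  expect_lt(rm_$mean_parent, rm_$mean_unrelated)
  spread <- rm_$mean_unrelated - rm_$mean_child
  expect_lt(abs(rm_$mean_parent - rm_$midpoint_child_unrelated), spread / 2)
})
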