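# Synthetic trio-cohort generator. Produces Mendelian-consistent phased
# truth data plus controlled corruptions (caller errors, phasing errors,
# imputation noise) with machine-readable injection logs, so downstream
# metrics can be checked against known truth.

#' Simulation configuration
#'
#' All rates are per-event probabilities in [0, 1]. The de novo rate is
#' the expected fraction of a child's non-reference variants that are de
#' novo (absent from both parents). Evidence-feature distributions for
#' true versus false SVs are well separated by default (split-read mean 8
#' vs 1) so the boost model is learnable at small n; the separation is a
#' knob for probing threshold selection.
#'
#' @param n_trios number of father-mother-child trios.
#' @param n_unrelated number of unrelated samples.
#' @param n_sites number of small-variant sites.
#' @param n_sv number of true SV loci.
#' @param chroms,chrom_len chromosome names and common length (bp).
#' @param singleton_mass probability a site is drawn as a cohort
#'   singleton (one founder haplotype carries the allele).
#' @param af_beta shape parameters of the Beta component of the allele
#'   frequency spectrum for non-singleton sites.
#' @param pop_af_sd sd of the per-super-population logit-AF jitter.
#' @param indel_fraction fraction of small-variant sites that are INDELs.
#' @param fail_filter_rate fraction of sites marked FILTER=FAIL.
#' @param denovo_rate small-variant de novo rate per child.
#' @param sv_denovo_rate SV de novo rate per child.
#' @param sv_type_probs named sampling weights for DEL/INS/DUP/INV.
#' @param callers named list; per caller: \code{fp_rate}, \code{fn_rate},
#'   \code{jitter_sd} (bp).
#' @param sr_mean_true,pe_mean_true,sr_mean_false,pe_mean_false Poisson
#'   means of split-read / pair-end evidence for true and false SVs.
#' @param switch_rate per-junction haplotype switch-error rate.
#' @param pointflip_rate per-site isolated flip rate.
#' @param gp_noise imputation genotype-probability noise level in [0, 1].
#' @param seed integer random seed; same seed + config gives identical
#'   output.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_trios = 50L, n_unrelated = 100L,
                       n_sites = 3000L, n_sv = 600L,
                       chroms = c("chr1", "chr2"), chrom_len = 5e7,
                       singleton_mass = 0.10, af_beta = c(0.3, 1.5),
                       pop_af_sd = 0.3, indel_fraction = 0.15,
                       fail_filter_rate = 0.02,
                       denovo_rate = 0.003, sv_denovo_rate = 0.005,
                       sv_type_probs = c(DEL = 0.5, INS = 0.3, DUP = 0.15, INV = 0.05),
                       callers = list(
                         callerA = list(fp_rate = 0.05, fn_rate = 0.05, jitter_sd = 10),
                         callerB = list(fp_rate = 0.10, fn_rate = 0.05, jitter_sd = 10)),
                       sr_mean_true = 8, pe_mean_true = 6,
                       sr_mean_false = 1, pe_mean_false = 1,
                       switch_rate = 0.01, pointflip_rate = 0.01,
                       gp_noise = 0.05, seed = 1L) {
  cfg <- as.list(environment())
  rates <- c(cfg$singleton_mass, cfg$fail_filter_rate, cfg$denovo_rate,
             cfg$sv_denovo_rate, cfg$switch_rate, cfg$pointflip_rate,
             cfg$gp_noise,
             unlist(lapply(cfg$callers, function(k) c(k$fp_rate, k$fn_rate))))
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (any(vapply(cfg$callers, function(k) k$jitter_sd, 0) < 0))
    stop("jitter sd must be >= 0")
  if (cfg$n_trios + cfg$n_unrelated <= 0L) stop("cohort must contain at least one sample")
  structure(cfg, class = "sim_config")
}

superpops <- function() c("AFR", "EUR", "EAS", "SAS", "AMR")

# pedigree for n trios + n unrelated; super-populations round-robin
sim_pedigree <- function(n_trios, n_unrelated) {
  sp <- superpops()
  rows <- list()
  for (i in seq_len(n_trios)) {
    p <- sp[(i - 1L) %% 5L + 1L]
    f <- sprintf("F%04d", i); m <- sprintf("M%04d", i); c <- sprintf("C%04d", i)
    rows[[i]] <- data.frame(
      id = c(f, m, c), father = c(NA, NA, f), mother = c(NA, NA, m),
      sex = c("male", "female", c("male", "female")[i %% 2L + 1L]),
      pop = p, superpop = p, stringsAsFactors = FALSE)
  }
  if (n_unrelated > 0L) {
    i <- seq_len(n_unrelated)
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("U%04d", i), father = NA_character_, mother = NA_character_,
      sex = c("male", "female")[i %% 2L + 1L],
      pop = sp[(i - 1L) %% 5L + 1L], superpop = sp[(i - 1L) %% 5L + 1L],
      stringsAsFactors = FALSE)
  }
  pedigree(do.call(rbind, rows))
}

# founder haplotypes at one site: per-pop allele frequency with logit jitter
sim_founder_haps <- function(p_base, pops, pop_af_sd, singleton) {
  n <- length(pops)
  if (singleton) {
    h1 <- integer(n); h2 <- integer(n)
    hap <- sample.int(2L * n, 1L)
    if (hap <= n) h1[hap] <- 1L else h2[hap - n] <- 1L
    return(cbind(h1, h2))
  }
  sp <- superpops()
  p_pop <- stats::plogis(stats::qlogis(p_base) + stats::rnorm(5L, 0, pop_af_sd))
  p <- p_pop[match(pops, sp)]
  cbind(stats::rbinom(n, 1L, p), stats::rbinom(n, 1L, p))
}

# inherit founder haplotypes into children; h1 = paternal, h2 = maternal
inherit_children <- function(h1, h2, ped) {
  tr <- ped$trios
  ids <- colnames(h1)
  for (i in seq_len(nrow(tr))) {
    f <- match(tr$father[i], ids); m <- match(tr$mother[i], ids)
    c_ <- match(tr$child[i], ids)
    n <- nrow(h1)
    from_f <- stats::rbinom(n, 1L, 0.5)
    from_m <- stats::rbinom(n, 1L, 0.5)
    h1[, c_] <- ifelse(from_f == 0L, h1[, f], h2[, f])
    h2[, c_] <- ifelse(from_m == 0L, h1[, m], h2[, m])
  }
  list(h1 = h1, h2 = h2)
}

# inject de novo alleles into children at trio-hom-ref sites so that the
# expected fraction of each child's non-reference variants that are de
# novo equals `rate`; returns updated haplotypes + draw log
inject_denovo <- function(h1, h2, ped, rate) {
  log_rows <- list()
  ids <- colnames(h1)
  tr <- ped$trios
  for (i in seq_len(nrow(tr))) {
    f <- match(tr$father[i], ids); m <- match(tr$mother[i], ids)
    c_ <- match(tr$child[i], ids)
    gp <- (h1[, f] + h2[, f] + h1[, m] + h2[, m])
    eligible <- which(gp == 0L)
    n_nonref <- sum(h1[, c_] + h2[, c_] > 0L)
    if (rate > 0 && n_nonref > 0L && length(eligible) > 0L) {
      d <- stats::rbinom(1L, n_nonref, min(1, rate / (1 - rate)))
      d <- min(d, length(eligible))
      if (d > 0L) {
        at <- sample(eligible, d)
        hap <- stats::rbinom(d, 1L, 0.5)
        h1[at[hap == 0L], c_] <- 1L
        h2[at[hap == 1L], c_] <- 1L
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(child = tr$child[i], site = at, hap = hap + 1L,
                     stringsAsFactors = FALSE)
      }
    }
  }
  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(child = character(), site = integer(), hap = integer())
  list(h1 = h1, h2 = h2, log = log)
}

random_small_alleles <- function(n, indel_fraction) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  is_indel <- stats::runif(n) < indel_fraction
  ins <- is_indel & stats::runif(n) < 0.5
  extra <- vapply(seq_len(n), function(i)
    paste(sample(bases, 1L + stats::rpois(1L, 1), replace = TRUE), collapse = ""), "")
  ref[is_indel & !ins] <- paste0(ref[is_indel & !ins], extra[is_indel & !ins])
  alt[is_indel & !ins] <- substr(ref[is_indel & !ins], 1L, 1L)
  alt[ins] <- paste0(ref[ins], extra[ins])
  list(ref = ref, alt = alt)
}

#' Simulate a trio-structured cohort with phased truth data
#'
#' Children's genotypes are Mendelian-consistent with their parents
#' except at de novo sites drawn at the configured rate; truth
#' haplotypes record parental origin (child h1 = paternal, h2 =
#' maternal). SV evidence features (depth ratio, flank depth, split-read
#' and pair-end counts) are drawn from the true-SV distributions.
#'
#' @param config a \code{\link{sim_config}}.
#' @return object of class \code{sim_cohort}: \code{pedigree},
#'   \code{smallvar} (sites, h1, h2, phased), \code{sv} (an
#'   \code{\link{sv_callset}}), \code{denovo_log}, \code{sv_denovo_log},
#'   \code{config}.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ped <- sim_pedigree(config$n_trios, config$n_unrelated)
  samp <- ped$samples
  founders <- samp$id[samp$role != "child"]
  children <- samp$id[samp$role == "child"]
  n_all <- nrow(samp)

  ## ----- small variants -----
  n <- config$n_sites
  chrom <- sort(sample(config$chroms, n, replace = TRUE))
  start <- unlist(lapply(split(seq_len(n), chrom), function(ii)
    sort(sample.int(config$chrom_len, length(ii)))), use.names = FALSE)
  alle <- random_small_alleles(n, config$indel_fraction)
  filter <- ifelse(stats::runif(n) < config$fail_filter_rate, "FAIL", "PASS")
  sites <- data.frame(id = sprintf("snv%05d", seq_len(n)), chrom = chrom,
                      start = start, ref = alle$ref, alt = alle$alt,
                      filter = filter, stringsAsFactors = FALSE)
  h1 <- matrix(0L, n, n_all, dimnames = list(sites$id, samp$id))
  h2 <- h1
  singleton <- stats::runif(n) < config$singleton_mass
  p_base <- pmin(0.999, pmax(0.001, stats::rbeta(n, config$af_beta[1], config$af_beta[2])))
  fpops <- samp$superpop[samp$role != "child"]
  fidx <- match(founders, samp$id)
  for (i in seq_len(n)) {
    hp <- sim_founder_haps(p_base[i], fpops, config$pop_af_sd, singleton[i])
    h1[i, fidx] <- hp[, 1L]; h2[i, fidx] <- hp[, 2L]
  }
  inh <- inherit_children(h1, h2, ped)
  dn <- inject_denovo(inh$h1, inh$h2, ped, config$denovo_rate)

  ## ----- SVs -----
  m <- config$n_sv
  svtype <- sample(names(config$sv_type_probs), m, replace = TRUE,
                   prob = config$sv_type_probs)
  sv_chrom <- sort(sample(config$chroms, m, replace = TRUE))
  sv_start <- unlist(lapply(split(seq_len(m), sv_chrom), function(ii)
    sort(sample.int(config$chrom_len, length(ii)))), use.names = FALSE)
  svlen <- integer(m)
  body <- svtype %in% c("DEL", "DUP", "INV")
  svlen[body] <- pmin(100000L, pmax(50L, round(stats::rlnorm(sum(body), log(800), 1.1))))
  svlen[!body] <- pmin(6000L, pmax(50L, round(stats::rlnorm(sum(!body), log(300), 0.8))))
  sv_end <- ifelse(svtype == "INS", sv_start, sv_start + svlen)
  context <- sample(c("short-repeat", "segmental-duplication", "repeat-masked", "unique"),
                    m, replace = TRUE, prob = c(0.15, 0.10, 0.35, 0.40))
  svdf <- data.frame(id = sprintf("sv%05d", seq_len(m)), chrom = sv_chrom,
                     start = sv_start, end = as.integer(sv_end),
                     svtype = svtype, svlen = svlen, context = context,
                     stringsAsFactors = FALSE)
  sh1 <- matrix(0L, m, n_all, dimnames = list(svdf$id, samp$id))
  sh2 <- sh1
  sv_singleton <- stats::runif(m) < config$singleton_mass
  sv_p <- pmin(0.5, pmax(0.002, stats::rbeta(m, 0.2, 2)))
  for (i in seq_len(m)) {
    hp <- sim_founder_haps(sv_p[i], fpops, config$pop_af_sd, sv_singleton[i])
    sh1[i, fidx] <- hp[, 1L]; sh2[i, fidx] <- hp[, 2L]
  }
  sinh <- inherit_children(sh1, sh2, ped)
  sdn <- inject_denovo(sinh$h1, sinh$h2, ped, config$sv_denovo_rate)
  ev <- sim_sv_evidence(svdf, sdn$h1 + sdn$h2, config, truth = TRUE)

  structure(list(
    pedigree = ped,
    smallvar = list(sites = sites, h1 = dn$h1, h2 = dn$h2, phased = TRUE),
    sv = sv_callset(svdf, h1 = sdn$h1, h2 = sdn$h2, evidence = ev, phased = TRUE),
    denovo_log = dn$log, sv_denovo_log = sdn$log,
    config = config), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort:", nrow(x$pedigree$samples), "samples (",
      nrow(x$pedigree$trios), "trios ),", nrow(x$smallvar$sites),
      "small-variant sites,", nrow(x$sv$records), "SV loci\n")
  invisible(x)
}

# evidence matrices for an SV genotype matrix; truth records follow the
# true-SV feature distributions, FP records the false distribution
sim_sv_evidence <- function(svdf, gmat, config, truth) {
  n <- nrow(gmat); k <- ncol(gmat)
  carrier <- gmat > 0L
  sr_mean <- if (truth) config$sr_mean_true else config$sr_mean_false
  pe_mean <- if (truth) config$pe_mean_true else config$pe_mean_false
  sr <- matrix(stats::rpois(n * k, 0.2), n, k, dimnames = dimnames(gmat))
  pe <- matrix(stats::rpois(n * k, 0.2), n, k, dimnames = dimnames(gmat))
  sr[carrier] <- stats::rpois(sum(carrier), sr_mean)
  pe[carrier] <- stats::rpois(sum(carrier), pe_mean)
  depth <- matrix(1 + stats::rnorm(n * k, 0, 0.05), n, k, dimnames = dimnames(gmat))
  if (truth) {
    shift <- matrix(0, n, k)
    shift[svdf$svtype == "DEL", ] <- -0.25
    shift[svdf$svtype == "DUP", ] <- 0.25
    depth <- depth + shift * gmat
  }
  flank <- matrix(stats::rnorm(n * k, 30, 2), n, k, dimnames = dimnames(gmat))
  list(depth = depth, flank_depth = flank, pe = pe, sr = sr)
}

#' Derive per-caller corrupted SV call sets from a truth cohort
#'
#' Each caller's output is the truth set minus false-negative draws, with
#' breakpoints jittered N(0, sd), plus false-positive records whose
#' evidence features follow the false-SV distributions. A machine-readable
#' injection log records the truth id (or FP status) of every emitted
#' record.
#'
#' @param cohort a \code{\link{simulate_cohort}} result.
#' @param config simulation config (defaults to the cohort's own).
#' @param seed seed for the corruption draws.
#' @return list: \code{callsets} (named list of \code{\link{sv_callset}}),
#'   \code{injection_log} data.frame (caller, id, truth_id, is_fp).
#' @export
corrupt_callsets <- function(cohort, config = cohort$config, seed = config$seed + 1L) {
  set.seed(seed)
  truth <- cohort$sv
  n <- nrow(truth$records)
  samp_ids <- colnames(truth$h1)
  callsets <- list(); logs <- list()
  for (cl in names(config$callers)) {
    par <- config$callers[[cl]]
    keep <- which(stats::runif(n) >= par$fn_rate)
    rec <- truth$records[keep, , drop = FALSE]
    js <- round(stats::rnorm(nrow(rec), 0, par$jitter_sd))
    je <- round(stats::rnorm(nrow(rec), 0, par$jitter_sd))
    ins <- rec$svtype == "INS"
    rec$start <- pmax(0L, rec$start + as.integer(js))
    rec$end <- ifelse(ins, rec$start,
                      pmax(rec$start + 50L, rec$end + as.integer(je)))
    rec$svlen <- ifelse(ins, pmax(50L, rec$svlen + as.integer(je)),
                        rec$end - rec$start)
    h1 <- truth$h1[keep, , drop = FALSE]
    h2 <- truth$h2[keep, , drop = FALSE]
    ev <- lapply(truth$evidence, function(mm) mm[keep, , drop = FALSE])

    n_fp <- stats::rbinom(1L, n, par$fp_rate)
    if (n_fp > 0L) {
      fp_type <- sample(names(config$sv_type_probs), n_fp, replace = TRUE,
                        prob = config$sv_type_probs)
      fp_chrom <- sample(config$chroms, n_fp, replace = TRUE)
      fp_start <- sample.int(config$chrom_len, n_fp)
      fp_len <- pmin(50000L, pmax(50L, round(stats::rlnorm(n_fp, log(500), 1))))
      fp_rec <- data.frame(id = sprintf("fp_%s_%04d", cl, seq_len(n_fp)),
                           chrom = fp_chrom, start = fp_start,
                           end = as.integer(ifelse(fp_type == "INS", fp_start, fp_start + fp_len)),
                           svtype = fp_type, svlen = fp_len,
                           context = sample(c("short-repeat", "repeat-masked", "unique"),
                                            n_fp, replace = TRUE, prob = c(0.45, 0.35, 0.20)),
                           stringsAsFactors = FALSE)
      fh1 <- matrix(stats::rbinom(n_fp * length(samp_ids), 1L, 0.03),
                    n_fp, length(samp_ids), dimnames = list(fp_rec$id, samp_ids))
      fh2 <- matrix(stats::rbinom(n_fp * length(samp_ids), 1L, 0.03),
                    n_fp, length(samp_ids), dimnames = list(fp_rec$id, samp_ids))
      carrier_any <- rowSums(fh1 + fh2) == 0L
      if (any(carrier_any)) {  # guarantee at least one carrier per FP record
        at <- sample(length(samp_ids), sum(carrier_any), replace = TRUE)
        fh1[cbind(which(carrier_any), at)] <- 1L
      }
      fev <- sim_sv_evidence(fp_rec, fh1 + fh2, config, truth = FALSE)
      rec <- rbind(rec, fp_rec)
      h1 <- rbind(h1, fh1); h2 <- rbind(h2, fh2)
      ev <- Map(rbind, ev, fev)
    }
    truth_id <- c(truth$records$id[keep], rep(NA_character_, n_fp))
    rec_caller_id <- paste0(cl, ":", rec$id)
    logs[[cl]] <- data.frame(caller = cl, id = rec_caller_id, truth_id = truth_id,
                             is_fp = is.na(truth_id), stringsAsFactors = FALSE)
    rec$id <- rec_caller_id
    rec$caller <- cl
    ord <- order(rec$chrom, rec$start, rec$end, rec$id)
    callsets[[cl]] <- sv_callset(rec[ord, , drop = FALSE],
                                 h1 = h1[ord, , drop = FALSE],
                                 h2 = h2[ord, , drop = FALSE],
                                 evidence = lapply(ev, function(mm) mm[ord, , drop = FALSE]),
                                 phased = FALSE)
  }
  log <- do.call(rbind, logs); rownames(log) <- NULL
  # sanity check: warn if jitter destroys concordance of true pairs
  check_jitter_concordance(callsets, log)
  list(callsets = callsets, injection_log = log)
}

check_jitter_concordance <- function(callsets, log) {
  if (length(callsets) < 2L) return(invisible())
  a <- callsets[[1L]]; b <- callsets[[2L]]
  la <- log[log$caller == names(callsets)[1L] & !log$is_fp, ]
  lb <- log[log$caller == names(callsets)[2L] & !log$is_fp, ]
  common <- intersect(la$truth_id, lb$truth_id)
  if (length(common) < 10L) return(invisible())
  common <- head(common, 500L)
  ia <- match(la$id[match(common, la$truth_id)], a$records$id)
  ib <- match(lb$id[match(common, lb$truth_id)], b$records$id)
  conc <- mapply(function(i, j)
    sv_concordant(a$records[i, ], b$records[j, ])$concordant, ia, ib)
  if (mean(conc) < 0.5)
    warning("breakpoint jitter is large enough that >50% of true SV pairs fail concordance")
  invisible()
}

#' Corrupt phased haplotypes with switch and flip errors
#'
#' Switch errors are injected as Markov orientation flips at each
#' heterozygous junction (per chromosome, per sample) at the configured
#' rate; isolated single-site flips are injected independently. All
#' injection positions are logged.
#'
#' @param h1,h2 phased allele matrices (sites x samples).
#' @param sites site table (used for chromosome grouping).
#' @param switch_rate per-junction switch probability.
#' @param pointflip_rate per-het-site isolated flip probability.
#' @param seed random seed.
#' @return list: corrupted \code{h1}, \code{h2}, and \code{log} with
#'   \code{switches} and \code{flips} data.frames.
#' @export
corrupt_phasing <- function(h1, h2, sites, switch_rate, pointflip_rate = 0,
                            seed = 1L) {
  if (switch_rate < 0 || switch_rate > 1 || pointflip_rate < 0 || pointflip_rate > 1)
    stop("error rates must lie in [0, 1]")
  set.seed(seed)
  sw_log <- list(); fl_log <- list()
  for (s in seq_len(ncol(h1))) {
    for (ch in unique(sites$chrom)) {
      rows <- which(sites$chrom == ch)
      het <- rows[which(h1[rows, s] + h2[rows, s] == 1L)]
      nh <- length(het)
      if (nh == 0L) next
      state <- integer(nh)
      if (nh > 1L) {
        sw <- stats::rbinom(nh - 1L, 1L, switch_rate)
        state <- c(0L, cumsum(sw)) %% 2L
        if (any(sw == 1L))
          sw_log[[length(sw_log) + 1L]] <- data.frame(
            sample = colnames(h1)[s], chrom = ch,
            left_site = het[which(sw == 1L)], stringsAsFactors = FALSE)
      }
      fl <- stats::rbinom(nh, 1L, pointflip_rate)
      if (any(fl == 1L))
        fl_log[[length(fl_log) + 1L]] <- data.frame(
          sample = colnames(h1)[s], chrom = ch, site = het[fl == 1L],
          stringsAsFactors = FALSE)
      state <- (state + fl) %% 2L
      swap <- het[state == 1L]
      if (length(swap)) {
        tmp <- h1[swap, s]
        h1[swap, s] <- h2[swap, s]
        h2[swap, s] <- tmp
      }
    }
  }
  empty_sw <- data.frame(sample = character(), chrom = character(), left_site = integer())
  empty_fl <- data.frame(sample = character(), chrom = character(), site = integer())
  list(h1 = h1, h2 = h2,
       log = list(switches = if (length(sw_log)) do.call(rbind, sw_log) else empty_sw,
                  flips = if (length(fl_log)) do.call(rbind, fl_log) else empty_fl))
}

#' Simulate imputation-style genotype probabilities
#'
#' Emits per site x sample probability triples (p_homref, p_het,
#' p_homalt) concentrated on the truth genotype: with noise level e the
#' triple is (1 - e) on the truth plus e times a Dirichlet(1,1,1) draw.
#' Noise 0 gives degenerate triples.
#'
#' @param h1,h2 truth allele matrices (diploid).
#' @param noise noise level in [0, 1].
#' @param seed random seed.
#' @return object of class \code{gp_table}: matrices \code{p0},
#'   \code{p1}, \code{p2}.
#' @export
simulate_imputation_output <- function(h1, h2, noise, seed = 1L) {
  if (noise < 0 || noise > 1) stop("noise must lie in [0, 1]")
  set.seed(seed)
  g <- as.vector(h1 + h2)
  n <- length(g)
  dir <- matrix(stats::rgamma(3L * n, 1), n, 3L)
  dir <- dir / rowSums(dir)
  p <- (1 - noise) * cbind(g == 0L, g == 1L, g == 2L) + noise * dir
  shape <- function(x) matrix(x, nrow(h1), ncol(h1), dimnames = dimnames(h1))
  structure(list(p0 = shape(p[, 1L]), p1 = shape(p[, 2L]), p2 = shape(p[, 3L])),
            class = "gp_table")
}
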