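# Ensemble SV call-set integration: concordance rules, cross-caller
# clustering, boost-score model, FDR-driven threshold, retention of
# caller-specific loci and final record selection.

#' Construct an SV call set
#'
#' @param records data.frame with columns id, chrom, start, end (0-based
#'   half-open; \code{end == start} for insertions), svtype (DEL, DUP,
#'   mCNV, INS, INV, CPX, CTX), svlen (bp; inserted-sequence length for
#'   INS) and optionally caller, context, filter.
#' @param h1,h2 integer allele matrices (records x samples).
#' @param evidence optional list of per-sample matrices: \code{depth}
#'   (local depth ratio), \code{flank_depth}, \code{pe}, \code{sr}.
#' @param phased logical; TRUE when h1/h2 are ordered haplotypes.
#' @return object of class \code{sv_callset}.
#' @export
sv_callset <- function(records, h1, h2, evidence = NULL, phased = FALSE) {
  stopifnot(all(c("id", "chrom", "start", "end", "svtype", "svlen") %in% names(records)))
  if (anyDuplicated(records$id)) stop("duplicate SV record id")
  if (any(records$svlen <= 0L)) stop("svlen must be > 0")
  body <- records$svtype %in% c("DEL", "DUP", "INV")
  if (any(records$end[body] - records$start[body] != records$svlen[body]))
    stop("for DEL/DUP/INV, svlen must equal end - start")
  if (any(records$end[records$svtype == "INS"] != records$start[records$svtype == "INS"]))
    stop("insertions must carry a point coordinate (end == start)")
  stopifnot(nrow(h1) == nrow(records), all(dim(h1) == dim(h2)))
  rownames(h1) <- rownames(h2) <- records$id
  structure(list(records = records, h1 = h1, h2 = h2,
                 evidence = evidence, phased = phased),
            class = "sv_callset")
}

#' @export
print.sv_callset <- function(x, ...) {
  cat("sv_callset:", nrow(x$records), "records x", ncol(x$h1), "samples (",
      paste(names(sort(-table(x$records$svtype))), collapse = ", "), ")\n")
  invisible(x)
}

# pair-level size class: the 50% reciprocal-overlap rule applies to SVs
# larger than 5 kb, the 10% rule to those under 5 kb; a pair is assessed
# under the large-class rule when its larger member exceeds 5 kb
sv_ro_cutoff <- function(len_a, len_b) ifelse(pmax(len_a, len_b) > 5000L, 0.5, 0.1)

#' Concordance of two SV records
#'
#' Insertions are concordant iff their insertion points lie within 100
#' bp. Other types require reciprocal overlap of at least 50% (pairs
#' whose larger member exceeds 5 kb) or 10% (smaller pairs). Comparing
#' records of different SV types or chromosomes is an error.
#'
#' @param a,b single-row record data.frames (id, chrom, start, end,
#'   svtype, svlen).
#' @return list: \code{concordant} logical and \code{pair} data.frame
#'   (ids, svtype, reciprocal overlap or NA for INS, breakpoint
#'   distance).
#' @export
sv_concordant <- function(a, b) {
  if (a$svtype != b$svtype) stop("cannot compare SVs of different types (",
                                 a$svtype, " vs ", b$svtype, ")")
  if (a$chrom != b$chrom) stop("cannot compare SVs on different chromosomes")
  dist <- abs(a$start - b$start)
  if (a$svtype == "INS") {
    ro <- NA_real_
    conc <- dist <= 100L
  } else {
    ro <- reciprocal_overlap(a$start, a$end, b$start, b$end)
    conc <- !is.na(ro) && ro >= sv_ro_cutoff(a$svlen, b$svlen)
  }
  list(concordant = conc,
       pair = data.frame(id_a = a$id, id_b = b$id, svtype = a$svtype,
                         reciprocal_overlap = ro, breakpoint_distance = dist,
                         stringsAsFactors = FALSE))
}

# vectorised concordance for candidate index pairs within one
# (chromosome, svtype) group
concordant_pairs <- function(rec, i, j) {
  if (length(i) == 0L) return(logical(0))
  if (rec$svtype[1L] == "INS") {
    abs(rec$start[i] - rec$start[j]) <= 100L
  } else {
    ro <- reciprocal_overlap(rec$start[i], rec$end[i], rec$start[j], rec$end[j])
    !is.na(ro) & ro >= sv_ro_cutoff(rec$svlen[i], rec$svlen[j])
  }
}

uf_new <- function(n) seq_len(n)
uf_find <- function(parent, x) {
  while (parent[x] != x) x <- parent[x]
  x
}

#' Cluster SV records across call sets
#'
#' Single-linkage clustering under the pairwise concordance rule, per
#' chromosome and SV type. Records are first put in canonical order
#' (chrom, start, end, id) so the result is invariant to input file
#' order. Each locus is labelled by the set of contributing call sets:
#' stratum \code{"shared"} when two or more callers contribute, otherwise
#' \code{"<caller>-only"}.
#'
#' @param callsets named list of \code{\link{sv_callset}} objects (>= 2)
#'   over the same samples.
#' @return list: \code{combined} (merged \code{sv_callset} with a
#'   \code{locus} column in records) and \code{loci} summary data.frame.
#' @export
cluster_across_callsets <- function(callsets) {
  if (length(callsets) < 2L) stop("need at least two call sets")
  if (is.null(names(callsets))) names(callsets) <- paste0("caller", seq_along(callsets))
  recs <- do.call(rbind, lapply(names(callsets), function(nm) {
    r <- callsets[[nm]]$records
    if (is.null(r$caller)) r$caller <- nm
    r[, c("id", "chrom", "start", "end", "svtype", "svlen", "caller",
          intersect("context", names(r)))]
  }))
  h1 <- do.call(rbind, lapply(callsets, function(x) x$h1))
  h2 <- do.call(rbind, lapply(callsets, function(x) x$h2))
  ev_names <- names(callsets[[1L]]$evidence)
  ev <- if (!is.null(ev_names)) {
    setNames(lapply(ev_names, function(k)
      do.call(rbind, lapply(callsets, function(x) x$evidence[[k]]))), ev_names)
  } else NULL

  ord <- order(recs$chrom, recs$start, recs$end, recs$id)
  recs <- recs[ord, , drop = FALSE]
  h1 <- h1[ord, , drop = FALSE]; h2 <- h2[ord, , drop = FALSE]
  if (!is.null(ev)) ev <- lapply(ev, function(mm) mm[ord, , drop = FALSE])
  rownames(recs) <- NULL
  n <- nrow(recs)

  parent <- uf_new(n)
  for (grp in split(seq_len(n), list(recs$chrom, recs$svtype), drop = TRUE)) {
    sub <- recs[grp, , drop = FALSE]
    gr <- GenomicRanges::GRanges(sub$chrom,
            IRanges::IRanges(sub$start + 1L, pmax(sub$end, sub$start + 1L)))
    maxgap <- if (sub$svtype[1L] == "INS") 100L else -1L
    hits <- GenomicRanges::findOverlaps(gr, maxgap = maxgap,
                                        drop.self = TRUE, drop.redundant = TRUE)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ok <- concordant_pairs(sub, qi, si)
    for (k in which(ok)) {
      ra <- uf_find(parent, grp[qi[k]]); rb <- uf_find(parent, grp[si[k]])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), function(x) uf_find(parent, x), 0L)
  locus <- match(root, sort(unique(root)))
  recs$locus <- sprintf("locus%05d", locus)

  loci <- do.call(rbind, lapply(split(seq_len(n), recs$locus), function(ii) {
    cls <- sort(unique(recs$caller[ii]))
    data.frame(locus = recs$locus[ii[1L]], chrom = recs$chrom[ii[1L]],
               svtype = recs$svtype[ii[1L]],
               start = min(recs$start[ii]), end = max(recs$end[ii]),
               n_records = length(ii),
               callers = paste(cls, collapse = ","),
               stratum = if (length(cls) >= 2L) "shared" else paste0(cls, "-only"),
               stringsAsFactors = FALSE)
  }))
  rownames(loci) <- NULL
  combined <- sv_callset(recs, h1, h2, evidence = ev, phased = FALSE)
  list(combined = combined, loci = loci)
}

# ---------------------------------------------------------------------------
# Boost model: per-SV-per-genome quality score.

context_levels <- function()
  c("short-repeat", "segmental-duplication", "repeat-masked", "unique")

#' Build the per-SV-per-genome feature table for the boost model
#'
#' One row per (record, carrier sample): local depth ratio, 1-kb flank
#' depth, pair-end count within 150 bp, split-read count within 100 bp of
#' each breakpoint, SV size (log10 bp), cohort allele fraction,
#' genomic-context class and the fraction of offspring harbouring the SV
#' de novo among trios in which it is observed.
#'
#' @param callset an \code{\link{sv_callset}} with evidence matrices.
#' @param ped a \code{\link{pedigree}}.
#' @return data.frame of features keyed by \code{id} and \code{sample}.
#' @export
build_sv_features <- function(callset, ped) {
  g <- callset$h1 + callset$h2
  carrier <- which(g > 0L, arr.ind = TRUE)
  af <- site_allele_stats(callset$h1, callset$h2)$AF
  dnf <- sv_denovo_fraction(callset, ped)
  rec <- carrier[, 1L]; smp <- carrier[, 2L]
  ctx <- if (!is.null(callset$records$context)) callset$records$context[rec]
         else rep("unique", length(rec))
  data.frame(
    id = callset$records$id[rec],
    sample = colnames(g)[smp],
    depth = callset$evidence$depth[carrier],
    flank_depth = callset$evidence$flank_depth[carrier],
    pe = callset$evidence$pe[carrier],
    sr = callset$evidence$sr[carrier],
    size = log10(callset$records$svlen[rec]),
    allele_fraction = af[rec],
    context = match(ctx, context_levels()),
    denovo_fraction = dnf[rec],
    stringsAsFactors = FALSE)
}

# per record: fraction of offspring with a de novo genotype among trios
# in which the SV is observed
sv_denovo_fraction <- function(callset, ped) {
  g <- callset$h1 + callset$h2
  tr <- ped$trios
  if (nrow(tr) == 0L) return(rep(0, nrow(g)))
  ci <- match(tr$child, colnames(g)); fi <- match(tr$father, colnames(g))
  mi <- match(tr$mother, colnames(g))
  gc <- g[, ci, drop = FALSE] > 0L
  gf <- g[, fi, drop = FALSE] > 0L
  gm <- g[, mi, drop = FALSE] > 0L
  observed <- gc | gf | gm
  denovo <- gc & !gf & !gm
  n_obs <- rowSums(observed)
  ifelse(n_obs > 0L, rowSums(denovo) / n_obs, 0)
}

#' Label training truth for the boost model
#'
#' The positive class is SVs that are uni-parentally inherited, shared
#' across call sets, and carry both orthogonal support flags; the
#' negative class is SVs appearing de novo in offspring, discovered by a
#' single caller, with neither support flag. Everything else is
#' unlabelled (NA).
#'
#' @param clustered result of \code{\link{cluster_across_callsets}}.
#' @param ped a \code{\link{pedigree}}.
#' @param support_flags data.frame with columns \code{id},
#'   \code{support_a}, \code{support_b} (per-record orthogonal support;
#'   in synthetic mode these stand in for long-read and assembly
#'   support).
#' @return logical vector along the combined records: TRUE (positive),
#'   FALSE (negative) or NA (unlabelled).
#' @export
label_training_truth <- function(clustered, ped, support_flags) {
  cs <- clustered$combined
  rec <- cs$records
  shared <- clustered$loci$stratum[match(rec$locus, clustered$loci$locus)] == "shared"
  g <- cs$h1 + cs$h2
  tr <- ped$trios
  ci <- match(tr$child, colnames(g)); fi <- match(tr$father, colnames(g))
  mi <- match(tr$mother, colnames(g))
  gc <- g[, ci, drop = FALSE] > 0L
  gf <- g[, fi, drop = FALSE] > 0L
  gm <- g[, mi, drop = FALSE] > 0L
  uniparental <- rowSums(gc & (gf != gm)) > 0L   # inherited from exactly one parent
  denovo <- rowSums(gc & !gf & !gm) > 0L
  sa <- support_flags$support_a[match(rec$id, support_flags$id)]
  sb <- support_flags$support_b[match(rec$id, support_flags$id)]
  lab <- rep(NA, nrow(rec))
  lab[shared & uniparental & sa & sb] <- TRUE
  lab[!shared & denovo & !sa & !sb] <- FALSE
  lab
}

#' Train a boost-score model for one SV class
#'
#' Gradient-boosted trees (\pkg{xgboost}) by default, with a logistic
#' regression fallback for dependency-light use. Deterministic under a
#' fixed seed (single thread).
#'
#' @param features feature data.frame from
#'   \code{\link{build_sv_features}} (rows to train on).
#' @param labels logical vector, one per feature row; both classes must
#'   be present.
#' @param method \code{"xgboost"} or \code{"logistic"}.
#' @param nrounds,max_depth,eta gradient-boosting hyper-parameters.
#' @param seed random seed.
#' @return object of class \code{boost_model} with a \code{predict}
#'   method returning scores in [0, 1].
#' @export
train_boost_model <- function(features, labels, method = c("xgboost", "logistic"),
                              nrounds = 60L, max_depth = 3L, eta = 0.3, seed = 1L) {
  method <- match.arg(method)
  if (length(unique(labels)) < 2L)
    stop("training data must contain both classes")
  fn <- boost_feature_names()
  x <- as.matrix(features[, fn])
  y <- as.numeric(labels)
  set.seed(seed)
  if (method == "xgboost") {
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = max_depth,
                    eta = eta, nthread = 1L, seed = seed),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
      nrounds = nrounds)
  } else {
    d <- as.data.frame(x); d$y <- y
    fit <- stats::glm(y ~ ., data = d, family = stats::binomial())
  }
  structure(list(method = method, fit = fit, feature_names = fn),
            class = "boost_model")
}

boost_feature_names <- function()
  c("depth", "flank_depth", "pe", "sr", "size", "allele_fraction",
    "context", "denovo_fraction")

#' @export
predict.boost_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$feature_names])
  if (object$method == "xgboost") {
    as.numeric(stats::predict(object$fit, xgboost::xgb.DMatrix(x, nthread = 1L)))
  } else {
    as.numeric(stats::predict(object$fit, as.data.frame(x), type = "response"))
  }
}

#' Select the boost-score decision threshold at a target FDR
#'
#' Returns the smallest threshold t such that the estimated FDR among
#' validation records scoring strictly above t is below the target. The
#' estimate is the point false fraction by default; setting
#' \code{conf_level} (e.g. 0.95) replaces it with the upper bound of a
#' Clopper-Pearson binomial confidence interval, so the target is met
#' with confidence rather than only in expectation -- appropriate when
#' the validation set is large. Without labels the published default
#' 0.448 is returned.
#'
#' @param scores numeric validation scores in [0, 1].
#' @param labels logical truth labels (TRUE = real SV); NULL for the
#'   default.
#' @param target_fdr target false discovery rate (default 0.05).
#' @param conf_level 0 for the point estimate (default), or a
#'   confidence level for the conservative upper bound.
#' @return numeric threshold; calls with score strictly greater than it
#'   PASS.
#' @export
select_threshold <- function(scores, labels = NULL, target_fdr = 0.05,
                             conf_level = 0) {
  if (is.null(labels)) return(0.448)
  stopifnot(length(scores) == length(labels))
  keep <- !is.na(labels) & !is.na(scores)
  scores <- scores[keep]; labels <- labels[keep]
  cand <- sort(unique(c(0, scores)))
  for (t in cand) {
    called <- scores > t
    if (!any(called)) break
    n <- sum(called); x <- sum(!labels[called])
    fdr <- if (conf_level > 0) stats::qbeta(conf_level, x + 1, n - x) else x / n
    if (fdr < target_fdr) return(t)
  }
  stop("no threshold achieves the target FDR with at least one passing record")
}

#' Retention rule for caller-specific SV loci
#'
#' A caller-specific SV is included in the final integrated call set iff
#' it failed the boost model in less than 48% of examined samples, where
#' examined samples are those carrying a non-reference genotype.
#'
#' @param pass logical vector, one per examined sample (TRUE = boost
#'   PASS).
#' @param max_fail_fraction exclusion boundary (default 0.48, strict
#'   comparison).
#' @return TRUE to include, FALSE to exclude.
#' @export
retention_rule <- function(pass, max_fail_fraction = 0.48) {
  if (length(pass) == 0L) {
    warning("no examined samples for caller-specific locus; excluding")
    return(FALSE)
  }
  mean(!pass) < max_fail_fraction
}

#' Select the final record for a clustered locus
#'
#' Per sample, the member with the greatest split-read count wins, ties
#' broken by higher boost score; the locus winner is the record winning
#' in the greatest number of samples (ties by higher carrier support,
#' then lexicographic id). For shared insertion loci the record from the
#' designated higher-precision caller is retained instead.
#'
#' @param members data.frame of the locus records (id, svtype, caller).
#' @param sr,boost,carrier matrices (records x samples) of split-read
#'   counts, boost scores, and carrier status for the members.
#' @param ins_preferred_caller caller name whose records win shared INS
#'   loci (NULL to disable).
#' @return the winning record id.
#' @export
select_final_record <- function(members, sr, boost, carrier,
                                ins_preferred_caller = NULL) {
  if (nrow(members) == 1L) return(members$id[1L])
  if (!is.null(ins_preferred_caller) && members$svtype[1L] == "INS" &&
      length(unique(members$caller)) >= 2L &&
      ins_preferred_caller %in% members$caller) {
    members <- members[members$caller == ins_preferred_caller, , drop = FALSE]
    keep <- match(members$id, rownames(sr))
    sr <- sr[keep, , drop = FALSE]; boost <- boost[keep, , drop = FALSE]
    carrier <- carrier[keep, , drop = FALSE]
    if (nrow(members) == 1L) return(members$id[1L])
  }
  wins <- setNames(integer(nrow(members)), members$id)
  for (s in seq_len(ncol(sr))) {
    cand <- which(carrier[, s])
    if (length(cand) == 0L) next
    best <- cand[order(-sr[cand, s], -boost[cand, s], members$id[cand])][1L]
    wins[best] <- wins[best] + 1L
  }
  support <- rowSums(carrier)
  ord <- order(-wins, -support, members$id)
  members$id[ord[1L]]
}

#' Integrate multi-caller SV call sets into a final ensemble call set
#'
#' Runs the full integration pipeline: cross-caller single-linkage
#' clustering under the concordance rules, per-SV-class boost-model
#' training on trio-derived truth labels, FDR-driven threshold selection,
#' retention filtering of caller-specific loci, and final record
#' selection. Unscored SV classes (mCNV, CPX, CTX) pass through flagged
#' \code{Manual_LQ}.
#'
#' @param callsets named list of \code{\link{sv_callset}} objects.
#' @param ped a \code{\link{pedigree}}.
#' @param support_flags per-record orthogonal support table (see
#'   \code{\link{label_training_truth}}); NULL disables training and
#'   applies the default threshold to a pre-scored call set.
#' @param threshold boost threshold; NULL selects it from validation
#'   labels at \code{target_fdr} (or falls back to 0.448).
#' @param target_fdr target FDR for threshold selection.
#' @param conf_level confidence level of the conservative FDR bound used
#'   during threshold selection (default 0.95; the pipeline's validation
#'   sets are large, so guarding against sampling noise is cheap).
#' @param method boost scorer backend (\code{"xgboost"} or
#'   \code{"logistic"}).
#' @param ins_preferred_caller caller whose records win shared INS loci.
#' @param seed random seed (training and train/validation split).
#' @return list: \code{callset} (final integrated \code{sv_callset} with
#'   SOURCES/BOOST/STRATUM annotations), \code{loci}, \code{records}
#'   (per-record provenance with locus, stratum, scores, retained flag),
#'   \code{threshold}, \code{models}.
#' @export
integrate_sv_callsets <- function(callsets, ped, support_flags = NULL,
                                  threshold = NULL, target_fdr = 0.05,
                                  conf_level = 0.95, method = "xgboost",
                                  ins_preferred_caller = NULL, seed = 1L) {
  cl <- cluster_across_callsets(callsets)
  cs <- cl$combined
  rec <- cs$records
  n <- nrow(rec)
  scoreable <- rec$svtype %in% c("DEL", "DUP", "INS", "INV")
  feats <- build_sv_features(cs, ped)
  feats$row <- match(feats$id, rec$id)

  ## score matrix: per record x sample boost score (carriers only)
  score_mat <- matrix(NA_real_, n, ncol(cs$h1),
                      dimnames = list(rec$id, colnames(cs$h1)))
  models <- list()
  if (!is.null(support_flags)) {
    labels <- label_training_truth(cl, ped, support_flags)
    set.seed(seed)
    loci_ids <- unique(rec$locus)
    train_loci <- sample(loci_ids, ceiling(length(loci_ids) / 2))
    in_train <- rec$locus %in% train_loci
    feats$label <- labels[feats$row]
    feats$train <- in_train[feats$row]
    for (tp in intersect(c("DEL", "DUP", "INS", "INV"), unique(rec$svtype))) {
      tr_rows <- feats$train & !is.na(feats$label) & rec$svtype[feats$row] == tp
      rows_tp <- which(rec$svtype[feats$row] == tp)
      if (sum(tr_rows) >= 20L && length(unique(feats$label[tr_rows])) == 2L) {
        mod <- train_boost_model(feats[tr_rows, ], feats$label[tr_rows],
                                 method = method, seed = seed)
      } else {
        pool <- feats$train & !is.na(feats$label) &
                rec$svtype[feats$row] %in% c("DEL", "DUP", "INS", "INV")
        mod <- train_boost_model(feats[pool, ], feats$label[pool],
                                 method = method, seed = seed)
      }
      models[[tp]] <- mod
      sc <- predict(mod, feats[rows_tp, ])
      score_mat[cbind(feats$row[rows_tp],
                      match(feats$sample[rows_tp], colnames(score_mat)))] <- sc
    }
    if (is.null(threshold)) {
      # call-level selection: one score per validation record (mean over
      # carriers), so common true SVs do not dilute the estimated FDR
      rec_score <- rowMeans(score_mat, na.rm = TRUE)
      val <- !in_train & !is.na(labels) & scoreable & !is.nan(rec_score)
      threshold <- select_threshold(rec_score[val], labels[val], target_fdr,
                                    conf_level = conf_level)
    }
  } else if (is.null(threshold)) {
    threshold <- select_threshold(numeric(0), NULL)
  }

  carrier <- (cs$h1 + cs$h2) > 0L
  pass_mat <- score_mat > threshold
  rec$mean_boost <- rowMeans(score_mat, na.rm = TRUE)
  rec$stratum <- cl$loci$stratum[match(rec$locus, cl$loci$locus)]

  ## locus retention
  loci <- cl$loci
  loci$retained <- TRUE
  loci$manual_review <- loci$svtype %in% c("mCNV", "CPX", "CTX")
  for (i in which(loci$stratum != "shared" & !loci$manual_review)) {
    ii <- which(rec$locus == loci$locus[i])
    pass <- as.vector(pass_mat[ii, , drop = FALSE][carrier[ii, , drop = FALSE]])
    loci$retained[i] <- suppressWarnings(retention_rule(pass[!is.na(pass)]))
  }

  ## final record per retained locus
  final_ids <- character(0)
  for (i in which(loci$retained)) {
    ii <- which(rec$locus == loci$locus[i])
    b <- score_mat[ii, , drop = FALSE]; b[is.na(b)] <- 0
    sr_m <- if (!is.null(cs$evidence)) cs$evidence$sr[ii, , drop = FALSE]
            else matrix(0L, length(ii), ncol(carrier))
    rownames(sr_m) <- rownames(b) <- rec$id[ii]
    final_ids <- c(final_ids, select_final_record(
      rec[ii, , drop = FALSE], sr_m, b, carrier[ii, , drop = FALSE],
      ins_preferred_caller = ins_preferred_caller))
  }
  fi <- match(final_ids, rec$id)
  out_rec <- rec[fi, , drop = FALSE]
  out_rec$SOURCES <- loci$callers[match(out_rec$locus, loci$locus)]
  out_rec$BOOST <- out_rec$mean_boost
  out_rec$STRATUM <- out_rec$stratum
  out_rec$filter <- ifelse(out_rec$svtype %in% c("mCNV", "CPX", "CTX"),
                           "Manual_LQ", "PASS")
  ord <- order(out_rec$chrom, out_rec$start, out_rec$end, out_rec$id)
  out_rec <- out_rec[ord, , drop = FALSE]
  oi <- match(out_rec$id, rec$id)
  final <- sv_callset(out_rec, cs$h1[oi, , drop = FALSE], cs$h2[oi, , drop = FALSE],
                      evidence = if (!is.null(cs$evidence))
                        lapply(cs$evidence, function(mm) mm[oi, , drop = FALSE]),
                      phased = FALSE)
  rec$retained <- loci$retained[match(rec$locus, loci$locus)]
  rec$final <- rec$id %in% out_rec$id
  list(callset = final, loci = loci, records = rec,
       threshold = threshold, models = models, score_matrix = score_mat)
}
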