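# Pedigree and VCF input/output. VCF positions are 1-based on disk and
# converted to the package's 0-based half-open convention at this
# boundary.

#' Build a pedigree from a sample table
#'
#' Roles are derived, not read: a sample is a \code{child} iff both its
#' parents are present in the cohort; a \code{parent} iff it is a listed
#' parent of a present child and not itself a child; otherwise
#' \code{unrelated}. Children with exactly one present parent keep the
#' \code{unrelated} role (they do not form a trio) but are flagged
#' \code{duo}. Parent ids referenced but absent from the table are
#' recorded as external.
#'
#' @param df data.frame with columns \code{id}, \code{father},
#'   \code{mother} (\code{NA} or \code{"0"} for none), \code{sex}
#'   (\code{"male"}/\code{"female"} or 1/2), and optionally \code{pop}
#'   and \code{superpop}.
#' @return object of class \code{pedigree}: the annotated sample table
#'   plus a \code{trios} data.frame (child, father, mother).
#' @export
pedigree <- function(df) {
  stopifnot(all(c("id", "father", "mother", "sex") %in% names(df)))
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) stop("duplicate sample id in pedigree: ",
                                 df$id[duplicated(df$id)][1L])
  none <- function(x) is.na(x) | x == "0" | x == ""
  df$father <- ifelse(none(as.character(df$father)), NA_character_, as.character(df$father))
  df$mother <- ifelse(none(as.character(df$mother)), NA_character_, as.character(df$mother))
  if (is.numeric(df$sex)) df$sex <- c("male", "female")[df$sex]
  if (is.null(df$pop)) df$pop <- NA_character_
  if (is.null(df$superpop)) df$superpop <- NA_character_

  present <- function(x) !is.na(x) & x %in% df$id
  has_f <- present(df$father)
  has_m <- present(df$mother)
  is_child <- has_f & has_m
  is_parent <- df$id %in% c(df$father[is_child], df$mother[is_child]) & !is_child
  df$role <- ifelse(is_child, "child", ifelse(is_parent, "parent", "unrelated"))
  df$duo <- xor(has_f, has_m)

  # no sample may be its own ancestor
  parent_of <- rbind(
    data.frame(from = df$id[has_f], to = df$father[has_f], stringsAsFactors = FALSE),
    data.frame(from = df$id[has_m], to = df$mother[has_m], stringsAsFactors = FALSE))
  for (s in df$id) {
    seen <- character(); frontier <- parent_of$to[parent_of$from == s]
    while (length(frontier)) {
      if (s %in% frontier) stop("pedigree cycle: sample ", s, " is its own ancestor")
      seen <- union(seen, frontier)
      frontier <- setdiff(parent_of$to[parent_of$from %in% frontier], seen)
    }
  }

  trios <- data.frame(child = df$id[is_child],
                      father = df$father[is_child],
                      mother = df$mother[is_child],
                      stringsAsFactors = FALSE)
  structure(list(samples = df, trios = trios), class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat("pedigree:", nrow(x$samples), "samples,", nrow(x$trios), "trios,",
      sum(x$samples$duo), "duo children\n")
  invisible(x)
}

#' Read a PED pedigree file
#'
#' Expects the 6 standard whitespace-delimited columns (family, id,
#' father, mother, sex, phenotype) with optional 7th/8th columns carrying
#' population and super-population codes.
#'
#' @param path PED file path.
#' @return a \code{\link{pedigree}}.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("PED file not found: ", path)
  x <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(x) < 6L) stop("PED file must have at least 6 columns")
  df <- data.frame(id = x[[2]], father = x[[3]], mother = x[[4]],
                   sex = c("male", "female")[as.integer(x[[5]])],
                   stringsAsFactors = FALSE)
  if (ncol(x) >= 7L) df$pop <- x[[7]]
  if (ncol(x) >= 8L) df$superpop <- x[[8]]
  pedigree(df)
}

#' Write a pedigree as a PED file
#'
#' @param ped a \code{\link{pedigree}}.
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  s <- ped$samples
  out <- data.frame(fid = s$id, id = s$id,
                    father = ifelse(is.na(s$father), "0", s$father),
                    mother = ifelse(is.na(s$mother), "0", s$mother),
                    sex = match(s$sex, c("male", "female")),
                    pheno = 0L,
                    pop = ifelse(is.na(s$pop), ".", s$pop),
                    superpop = ifelse(is.na(s$superpop), ".", s$superpop))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

# ---------------------------------------------------------------------------
# VCF writing. Minimal VCF 4.2 with the INFO/FORMAT keys the pipeline uses.

vcf_header <- function(chroms, samples, info_lines, format_lines) {
  c("##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(chroms), ">"),
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##FILTER=<ID=FAIL,Description=\"Failed site filters\">",
    "##FILTER=<ID=Manual_LQ,Description=\"Unscored SV class flagged for manual review\">",
    info_lines, format_lines,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

fmt_num <- function(x) ifelse(is.na(x), ".", sprintf("%.6g", x))

#' Write a small-variant panel as VCF
#'
#' @param panel list with \code{sites} (chrom, start, ref, alt, filter)
#'   and allele matrices \code{h1}, \code{h2}; genotypes are written
#'   phased when \code{panel$phased} is TRUE.
#' @param path output path (plain text).
#' @export
write_small_vcf <- function(panel, path) {
  s <- panel$sites
  stats <- site_allele_stats(panel$h1, panel$h2)
  info <- paste0("AC=", stats$AC, ";AN=", stats$AN, ";AF=", fmt_num(stats$AF))
  gt <- gt_compose(panel$h1, panel$h2, phased = isTRUE(panel$phased))
  hdr <- vcf_header(s$chrom, colnames(panel$h1),
    c("##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alternate allele count\">",
      "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele number\">",
      "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternate allele frequency\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  id <- if (!is.null(s$id)) s$id else "."
  body <- paste(s$chrom, s$start + 1L, id, s$ref, s$alt, ".",
                ifelse(is.na(s$filter), ".", s$filter), info, "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
}

#' Read a small-variant VCF into a panel
#'
#' Parsing is delegated to \pkg{vcfR}; coordinates are converted to the
#' package's 0-based convention.
#'
#' @param path VCF path (.vcf or .vcf.gz).
#' @return panel list (sites, h1, h2, phased) as used across the package.
#' @export
read_small_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dec <- gt_decompose(gt_raw)
  sites <- data.frame(chrom = fix$CHROM, start = as.integer(fix$POS) - 1L,
                      ref = fix$REF, alt = fix$ALT,
                      filter = fix$FILTER, stringsAsFactors = FALSE)
  if (!is.null(fix$ID) && any(fix$ID != ".")) sites$id <- fix$ID
  info <- vcf_info_fields(fix$INFO, c("AC", "AN", "AF"))
  sites$AC <- as.integer(info$AC)
  sites$AN <- as.integer(info$AN)
  sites$AF <- as.numeric(info$AF)
  list(sites = sites, h1 = dec$h1, h2 = dec$h2,
       phased = all(dec$phased[!is.na(dec$h1)] | is.na(dec$h2[!is.na(dec$h1)])))
}

vcf_info_fields <- function(info, keys) {
  out <- lapply(keys, function(k) {
    m <- regmatches(info, regexpr(paste0("(^|;)", k, "=[^;]*"), info))
    v <- rep(NA_character_, length(info))
    hit <- grepl(paste0("(^|;)", k, "="), info)
    v[hit] <- sub(paste0("^;?", k, "="), "", m)
    v
  })
  names(out) <- keys
  out
}

#' Write an SV call set as VCF
#'
#' SV records use symbolic ALT alleles with SVTYPE/SVLEN/END INFO keys
#' and per-sample evidence in FORMAT (DP local depth ratio, FD 1-kb flank
#' depth, PE discordant pair count, SR split-read count). Optional INFO
#' annotations SOURCES, BOOST and STRATUM carry integration provenance.
#'
#' @param callset an \code{sv_callset} (see \code{\link{sv_callset}}).
#' @param path output path.
#' @export
write_sv_vcf <- function(callset, path) {
  s <- callset$records
  stats <- site_allele_stats(callset$h1, callset$h2)
  info <- paste0("SVTYPE=", s$svtype, ";SVLEN=", s$svlen, ";END=", s$end,
                 ";AC=", stats$AC, ";AN=", stats$AN)
  for (k in c("SOURCES", "BOOST", "STRATUM")) {
    if (!is.null(s[[k]])) {
      val <- if (is.numeric(s[[k]])) fmt_num(s[[k]]) else s[[k]]
      keep <- !is.na(s[[k]])
      info[keep] <- paste0(info[keep], ";", k, "=", val[keep])
    }
  }
  gt <- gt_compose(callset$h1, callset$h2, phased = isTRUE(callset$phased))
  fmt <- paste(gt,
               fmt_num(callset$evidence$depth),
               fmt_num(callset$evidence$flank_depth),
               callset$evidence$pe, callset$evidence$sr, sep = ":")
  fmt <- matrix(fmt, nrow(gt), ncol(gt))
  hdr <- vcf_header(s$chrom, colnames(callset$h1),
    c("##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
      "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
      "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position (1-based inclusive)\">",
      "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alternate allele count\">",
      "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele number\">",
      "##INFO=<ID=SOURCES,Number=.,Type=String,Description=\"Contributing call sets\">",
      "##INFO=<ID=BOOST,Number=1,Type=Float,Description=\"Mean boost score over carriers\">",
      "##INFO=<ID=STRATUM,Number=1,Type=String,Description=\"Cross-caller membership stratum\">"),
    c("##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=DP,Number=1,Type=Float,Description=\"Local depth ratio\">",
      "##FORMAT=<ID=FD,Number=1,Type=Float,Description=\"Flank depth (1 kb)\">",
      "##FORMAT=<ID=PE,Number=1,Type=Integer,Description=\"Pair-end count within 150 bp\">",
      "##FORMAT=<ID=SR,Number=1,Type=Integer,Description=\"Split-read count within 100 bp\">"))
  filt <- if (!is.null(s$filter)) ifelse(is.na(s$filter), ".", s$filter) else "."
  body <- paste(s$chrom, s$start + 1L, s$id, "N", paste0("<", s$svtype, ">"),
                ".", filt, info, "GT:DP:FD:PE:SR",
                apply(fmt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
}

#' Read an SV VCF into an sv_callset
#'
#' @param path VCF path.
#' @return an \code{\link{sv_callset}}.
#' @export
read_sv_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info <- vcf_info_fields(fix$INFO, c("SVTYPE", "SVLEN", "END", "SOURCES", "BOOST", "STRATUM"))
  dec <- gt_decompose(vcfR::extract.gt(v, element = "GT"))
  num_mat <- function(el) {
    m <- vcfR::extract.gt(v, element = el)
    matrix(suppressWarnings(as.numeric(m)), nrow(m), ncol(m), dimnames = dimnames(m))
  }
  rec <- data.frame(id = fix$ID, chrom = fix$CHROM,
                    start = as.integer(fix$POS) - 1L,
                    end = as.integer(info$END),
                    svtype = info$SVTYPE,
                    svlen = as.integer(info$SVLEN),
                    stringsAsFactors = FALSE)
  if (!is.null(fix$FILTER)) rec$filter <- fix$FILTER
  if (any(!is.na(info$SOURCES))) rec$SOURCES <- info$SOURCES
  if (any(!is.na(info$BOOST))) rec$BOOST <- as.numeric(info$BOOST)
  if (any(!is.na(info$STRATUM))) rec$STRATUM <- info$STRATUM
  sv_callset(rec, h1 = dec$h1, h2 = dec$h2,
             evidence = list(depth = num_mat("DP"), flank_depth = num_mat("FD"),
                             pe = num_mat("PE"), sr = num_mat("SR")),
             phased = all(dec$phased[!is.na(dec$h1) & !is.na(dec$h2)]))
}

# ---------------------------------------------------------------------------
# Multiallelic splitting and allele left-normalisation.

# trim shared suffix then shared prefix of a ref/alt pair, shifting the
# 0-based start right on prefix trims; pure allele trimming, no reference
# context is consulted.
normalize_allele_pair <- function(ref, alt, start) {
  r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
    r <- r[-1L]; a <- a[-1L]; start <- start + 1L
  }
  list(ref = paste(r, collapse = ""), alt = paste(a, collapse = ""), start = start)
}

#' Split multiallelic VCF rows into biallelic records
#'
#' Each alternate allele becomes its own record with genotypes recoded
#' against the retained allele (other alternate alleles count as
#' reference). INDEL alleles are left-normalised by shared-base trimming.
#' Instead of mutating coordinates of same-start records, a reversible
#' key map links every output record to its source row and allele index.
#'
#' @param sites data.frame with chrom, start (0-based), ref, alt
#'   (comma-separated alternates), filter.
#' @param h1,h2 integer allele matrices with indices into the site's
#'   allele list (0 = ref).
#' @return list: \code{sites} (biallelic, with \code{src_row} and
#'   \code{alt_index} key columns), \code{h1}, \code{h2}, \code{key_map}.
#' @export
split_multiallelics <- function(sites, h1, h2) {
  if (any(grepl("<", sites$alt, fixed = TRUE)))
    stop("symbolic alleles found in small-variant stream; route SV records through read_sv_vcf/sv_callset")
  alts <- strsplit(sites$alt, ",", fixed = TRUE)
  n_out <- lengths(alts)
  src <- rep(seq_len(nrow(sites)), n_out)
  k <- unlist(lapply(n_out, seq_len))
  out_sites <- data.frame(chrom = sites$chrom[src], start = sites$start[src],
                          ref = sites$ref[src], alt = unlist(alts),
                          filter = sites$filter[src],
                          src_row = src, alt_index = k, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out_sites))) {
    nz <- normalize_allele_pair(out_sites$ref[i], out_sites$alt[i], out_sites$start[i])
    out_sites$ref[i] <- nz$ref; out_sites$alt[i] <- nz$alt; out_sites$start[i] <- nz$start
  }
  recode <- function(h) {
    m <- h[src, , drop = FALSE]
    out <- (m == k) * 1L  # retained allele -> 1, ref and other alts -> 0
    out[is.na(m)] <- NA_integer_
    out
  }
  key_map <- data.frame(record = seq_len(nrow(out_sites)), src_row = src,
                        alt_index = k,
                        src_start = sites$start[src],
                        norm_start = out_sites$start,
                        shift = out_sites$start - sites$start[src])
  list(sites = out_sites, h1 = recode(h1), h2 = recode(h2), key_map = key_map)
}
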