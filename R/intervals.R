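# Genomic intervals: 0-based half-open [start, end) throughout the
# package. VCF positions are converted at the I/O boundary; BED files are
# consumed natively. Insertion points are zero-length intervals
# (end == start).

#' Construct a genomic-interval table
#'
#' @param chrom character chromosome names.
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions; \code{end == start} encodes
#'   an insertion point, otherwise \code{end > start} is required.
#' @return data.frame with columns chrom/start/end.
#' @export
genomic_intervals <- function(chrom, start, end) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(start))
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (any(end < start)) stop("interval end must be >= start")
  data.frame(chrom = as.character(chrom), start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

# internal: convert 0-based half-open intervals to GRanges (1-based closed);
# zero-length intervals become width-1 anchors at the insertion point so
# overlap queries still see them.
as_gr <- function(x, min_width1 = TRUE) {
  end1 <- x$end
  if (is.null(end1))  # site tables without an explicit end: point records
    end1 <- x$start + if (!is.null(x$ref)) nchar(x$ref) else 1L
  if (min_width1) end1 <- pmax(end1, x$start + 1L)
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(start = x$start + 1L, end = end1))
}

#' Read a BED3 file into a 0-based interval table
#'
#' @param path BED file path (tab- or space-delimited, no header).
#' @return interval data.frame as from \code{\link{genomic_intervals}}.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  x <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  genomic_intervals(x[[1]], x[[2]], x[[3]])
}

#' Write a 0-based interval table as BED3
#'
#' @param x interval data.frame.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  utils::write.table(x[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Build an easy/difficult/high-confidence region stratification
#'
#' Easy and difficult intervals must be disjoint; together they declare
#' the reference space over which \code{\link{classify_region}} is total.
#'
#' @param easy,difficult,high_confidence interval data.frames
#'   (\code{high_confidence} may be NULL).
#' @return object of class \code{region_stratification}.
#' @export
region_stratification <- function(easy, difficult, high_confidence = NULL) {
  ge <- as_gr(easy, min_width1 = FALSE)
  gd <- as_gr(difficult, min_width1 = FALSE)
  if (length(GenomicRanges::intersect(ge, gd)) > 0)
    stop("easy and difficult intervals overlap; stratification must be disjoint")
  structure(list(easy = easy, difficult = difficult,
                 high_confidence = high_confidence,
                 gr_easy = ge, gr_difficult = gd),
            class = "region_stratification")
}

#' Classify variants as easy or difficult
#'
#' An SNV is classified by its single base. Any length-bearing variant
#' that overlaps at least one difficult base -- including variants
#' spanning an easy/difficult border -- is classified difficult. Variants
#' not fully covered by the declared easy+difficult space are an error.
#'
#' @param variants interval data.frame (0-based half-open).
#' @param strat a \code{\link{region_stratification}}.
#' @return character vector, "easy" or "difficult", one per variant.
#' @export
classify_region <- function(variants, strat) {
  stopifnot(inherits(strat, "region_stratification"))
  gv <- as_gr(variants)
  cov_d <- interval_coverage(gv, strat$gr_difficult)
  cov_e <- interval_coverage(gv, strat$gr_easy)
  w <- GenomicRanges::width(gv)
  out <- rep(NA_character_, length(gv))
  out[cov_d > 0L] <- "difficult"
  out[cov_d == 0L & cov_e == w] <- "easy"
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop("variant on chromosome ", variants$chrom[bad],
         " at [", variants$start[bad], ",", variants$end[bad],
         ") lies outside the declared easy/difficult reference space")
  }
  out
}

# total bp of each query interval covered by the subject set
interval_coverage <- function(gq, gs) {
  # seqlevel-mismatch warnings are expected when a query chromosome is
  # absent from the declared space; the caller reports the real error
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gq, gs))
  if (length(hits) == 0L) return(integer(length(gq)))
  q <- gq[S4Vectors::queryHits(hits)]
  s <- gs[S4Vectors::subjectHits(hits)]
  ov <- pmin(GenomicRanges::end(q), GenomicRanges::end(s)) -
        pmax(GenomicRanges::start(q), GenomicRanges::start(s)) + 1L
  as.integer(tapply(ov, factor(S4Vectors::queryHits(hits), levels = seq_along(gq)),
                    sum, default = 0L))
}

#' Reciprocal overlap of interval pairs
#'
#' The reciprocal overlap of two intervals is the overlap length divided
#' by the length of each interval; the value returned is the minimum of
#' the two fractions (bedtools \code{-r} semantics), so a cutoff applies
#' to both members symmetrically.
#'
#' @param start_a,end_a,start_b,end_b 0-based half-open coordinates
#'   (vectorised).
#' @return numeric vector in [0, 1]; 0 for non-overlapping pairs, NA when
#'   either interval has zero length.
#' @export
reciprocal_overlap <- function(start_a, end_a, start_b, end_b) {
  len_a <- end_a - start_a
  len_b <- end_b - start_b
  ov <- pmax(0L, pmin(end_a, end_b) - pmax(start_a, start_b))
  out <- pmin(ov / len_a, ov / len_b)
  out[len_a == 0L | len_b == 0L] <- NA_real_
  out
}

#' Default GRCh38 pseudoautosomal regions of chromosome X
#'
#' PAR1 and PAR2 on chrX in 0-based half-open coordinates. Overridable
#' wherever PAR intervals are accepted.
#'
#' @return interval data.frame with two rows.
#' @export
par_regions_grch38 <- function() {
  genomic_intervals(chrom = c("chrX", "chrX"),
                    start = c(10000L, 155701382L),
                    end = c(2781479L, 156030895L))
}
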