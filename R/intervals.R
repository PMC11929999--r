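# Interval algebra shared by all pipeline stages. Coordinates are 1-based
# fully closed throughout (VCF/GFF native); BED conversion happens only at
# the io boundary. Intervals travel as data frames with columns
# chrom/start/end; IRanges does the heavy lifting underneath.

.check_intervals <- function(x, what = "intervals") {
  req <- c("chrom", "start", "end")
  if (!is.data.frame(x) || !all(req %in% names(x))) {
    stop(what, " must be a data frame with columns chrom, start, end")
  }
  if (nrow(x) && any(x$end < x$start)) {
    stop(what, ": end < start at row(s) ",
         paste(utils::head(which(x$end < x$start), 5), collapse = ", "))
  }
  invisible(x)
}

.as_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end))
}

.from_granges <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Interval length in base pairs (1-based closed convention)
#' @param x Interval data frame with columns `chrom`, `start`, `end`.
#' @return Numeric vector of lengths `end - start + 1`.
#' @export
interval_width <- function(x) {
  .check_intervals(x)
  x$end - x$start + 1
}

#' Reciprocal overlap of interval pairs
#'
#' Overlap length divided by the length of the larger interval. This equals
#' the usual "both intervals covered to at least f by their intersection"
#' criterion: `reciprocal_overlap(a, b) >= f` iff both directional overlap
#' fractions are `>= f`. Pairs on different chromosomes score 0; identical
#' intervals score 1.
#'
#' @param a,b Interval data frames of equal row count (compared row-wise).
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' a <- data.frame(chrom = "1", start = 100, end = 199)
#' b <- data.frame(chrom = "1", start = 150, end = 249)
#' reciprocal_overlap(a, b)  # 0.5
#' @export
reciprocal_overlap <- function(a, b) {
  .check_intervals(a, "a"); .check_intervals(b, "b")
  if (nrow(a) != nrow(b)) stop("reciprocal_overlap: a and b must have equal rows")
  ov <- pmin(a$end, b$end) - pmax(a$start, b$start) + 1
  ov <- pmax(ov, 0)
  ov[as.character(a$chrom) != as.character(b$chrom)] <- 0
  ov / pmax(interval_width(a), interval_width(b))
}

#' Cluster intervals by chained reciprocal overlap
#'
#' Single-linkage clustering: two intervals land in one cluster iff they are
#' connected by a chain of pairwise reciprocal overlaps at or above
#' `threshold` (transitive closure). The result is order-independent; cluster
#' ids are assigned by genomic position of each cluster's span, and the span
#' is `[min start, max end]` over the members.
#'
#' @param x Interval data frame; extra columns are preserved.
#' @param threshold Reciprocal-overlap threshold in `(0, 1]`.
#' @return `x` with an integer `cluster` column; attribute `spans` holds one
#'   row per cluster (`cluster`, `chrom`, `start`, `end`, `n`).
#' @export
cluster_reciprocal <- function(x, threshold = 0.5) {
  .check_intervals(x)
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  n <- nrow(x)
  if (n == 0) {
    out <- x; out$cluster <- integer(0)
    attr(out, "spans") <- data.frame(cluster = integer(0), chrom = character(0),
                                     start = numeric(0), end = numeric(0),
                                     n = integer(0))
    return(out)
  }
  gr <- .as_granges(x)
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  keep <- qi < si
  qi <- qi[keep]; si <- si[keep]
  if (length(qi)) {
    ro <- reciprocal_overlap(x[qi, , drop = FALSE], x[si, , drop = FALSE])
    pass <- ro >= threshold
    qi <- qi[pass]; si <- si[pass]
  }
  comp <- .union_find(n, qi, si)
  # stable ids: order clusters by (chrom, min start, max end) of their span
  span_start <- tapply(x$start, comp, min)
  span_end <- tapply(x$end, comp, max)
  span_chrom <- tapply(as.character(x$chrom), comp, `[`, 1)
  ord <- order(span_chrom, span_start, span_end)
  relab <- integer(length(ord)); relab[ord] <- seq_along(ord)
  ids <- relab[match(comp, as.integer(names(span_start)))]
  out <- x
  out$cluster <- ids
  spans <- data.frame(cluster = relab, chrom = as.character(span_chrom),
                      start = as.numeric(span_start), end = as.numeric(span_end),
                      n = as.integer(table(comp)), stringsAsFactors = FALSE)
  spans <- spans[order(spans$cluster), , drop = FALSE]
  rownames(spans) <- NULL
  attr(out, "spans") <- spans
  out
}

# weighted union-find over n items with edge lists (ai, bi)
.union_find <- function(n, ai, bi) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(ai)) {
    ra <- find(ai[k]); rb <- find(bi[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  vapply(seq_len(n), find, integer(1))
}

#' Merge intervals sharing at least one base
#'
#' Intervals overlapping by >= 1 bp collapse into one; bookended intervals
#' (`end + 1 == start` of the next) stay separate because they share no base.
#'
#' @param x Interval data frame.
#' @return Data frame of disjoint merged intervals, sorted by position.
#' @export
merge_adjacent <- function(x) {
  .check_intervals(x)
  if (nrow(x) == 0) return(x[, c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(.as_granges(x), min.gapwidth = 0L)
  .from_granges(GenomicRanges::sort(gr))
}

#' Subtract one interval set from another
#'
#' Returns the bases of `a` not covered by `b`, as maximal intervals.
#'
#' @param a,b Interval data frames.
#' @return Data frame of intervals.
#' @export
subtract_intervals <- function(a, b) {
  .check_intervals(a, "a"); .check_intervals(b, "b")
  if (nrow(a) == 0) return(a[, c("chrom", "start", "end")])
  if (nrow(b) == 0) return(merge_adjacent(a))
  gr <- GenomicRanges::setdiff(.as_granges(a), .as_granges(b),
                               ignore.strand = TRUE)
  .from_granges(GenomicRanges::sort(gr))
}

#' Per-base support profile of a region
#'
#' Piecewise-constant count of calls covering each base of `region`, the
#' quantity driving call-density trimming of combined regions.
#'
#' @param region Single-row interval data frame.
#' @param calls Interval data frame; every call must overlap the region.
#' @return Data frame with columns `start`, `end`, `support` partitioning the
#'   region; segment boundaries fall exactly at call starts/ends.
#' @export
support_profile <- function(region, calls) {
  .check_intervals(region, "region"); .check_intervals(calls, "calls")
  if (nrow(region) != 1) stop("support_profile: region must be a single interval")
  if (nrow(calls) == 0) {
    stop("support_profile: a combined region always has >= 1 contributing call")
  }
  same <- as.character(calls$chrom) == as.character(region$chrom)
  ov <- pmin(calls$end, region$end) - pmax(calls$start, region$start) + 1
  if (any(!same | ov <= 0)) {
    stop("support_profile: call(s) not overlapping region: row(s) ",
         paste(utils::head(which(!same | ov <= 0), 5), collapse = ", "))
  }
  cs <- pmax(calls$start, region$start) - region$start + 1  # 1-based offsets
  ce <- pmin(calls$end, region$end) - region$start + 1
  cov <- IRanges::coverage(IRanges::IRanges(cs, ce),
                           width = region$end - region$start + 1)
  seg_end <- cumsum(S4Vectors::runLength(cov))
  seg_start <- seg_end - S4Vectors::runLength(cov) + 1
  data.frame(start = region$start + seg_start - 1,
             end = region$start + seg_end - 1,
             support = S4Vectors::runValue(cov))
}
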