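#' Coordinate conventions
#'
#' All interval tables in methdyn are BED-style: 0-based, half-open
#' `[start, end)`. Cytosine positions are 1-based (the Bismark dialect).
#' A 1-based position `p` lies inside `[start, end)` iff
#' `start < p <= end`. These two helpers are the only place the
#' conversion happens.
#'
#' @param pos integer vector of 1-based positions.
#' @return `pos_to_interval()` returns a two-column tibble of the 0-based
#'   half-open single-base interval; `pos_in_interval()` a logical vector.
#' @name coords
NULL

#' @rdname coords
#' @export
pos_to_interval <- function(pos) {
  tibble(start = as.integer(pos) - 1L, end = as.integer(pos))
}

#' @rdname coords
#' @param start,end interval bounds, 0-based half-open.
#' @export
pos_in_interval <- function(pos, start, end) {
  start < pos & pos <= end
}

# GRanges for a site table (chrom, pos; 1-based single-base ranges)
sites_granges <- function(sites) {
  GenomicRanges::GRanges(
    sites$chrom,
    IRanges::IRanges(start = sites$pos, width = 1L)
  )
}

# GRanges for an interval table (chrom, start, end; BED half-open)
intervals_granges <- function(intervals) {
  GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(start = intervals$start + 1L, end = pmax(intervals$end, intervals$start + 1L)),
    strand = if ("strand" %in% names(intervals)) {
      ifelse(intervals$strand %in% c("+", "-"), intervals$strand, "*")
    } else "*"
  )
}

#' Which sites fall inside a set of intervals?
#'
#' @param sites tibble with `chrom` and 1-based `pos` columns.
#' @param intervals tibble with `chrom`, `start`, `end` (0-based half-open).
#' @return logical vector along the rows of `sites`.
#' @export
sites_in_intervals <- function(sites, intervals) {
  if (nrow(intervals) == 0L || nrow(sites) == 0L) {
    return(rep(FALSE, nrow(sites)))
  }
  suppressWarnings(IRanges::overlapsAny(
    sites_granges(sites), intervals_granges(intervals), ignore.strand = TRUE
  ))
}

# all (site, interval) index pairs with the site inside the interval
site_interval_pairs <- function(sites, intervals) {
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    sites_granges(sites), intervals_granges(intervals), ignore.strand = TRUE
  ))
  tibble(
    site = S4Vectors_from(hits, "query"),
    interval = S4Vectors_from(hits, "subject")
  )
}

S4Vectors_from <- function(hits, which) {
  if (which == "query") as.integer(S4Vectors::queryHits(hits)) else as.integer(S4Vectors::subjectHits(hits))
}

# logical: intervals in `x` overlapping >= 1 interval in `y`
intervals_overlap_any <- function(x, y) {
  if (nrow(x) == 0L) return(logical(0))
  if (nrow(y) == 0L) return(rep(FALSE, nrow(x)))
  suppressWarnings(IRanges::overlapsAny(
    intervals_granges(x), intervals_granges(y), ignore.strand = TRUE
  ))
}
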