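#' Interval sets
#'
#' Genomic intervals are represented throughout the package as plain data
#' frames with columns `chrom` (character), `start`, `end` (0-based,
#' half-open, BED convention) and optionally `label`. An *interval set* is
#' such a data frame after normalization: sorted by (chrom, start) with
#' overlapping or bookended intervals merged per chromosome.
#'
#' All set algebra is delegated to \pkg{IRanges}/\pkg{GenomicRanges};
#' conversion shifts BED starts by +1 into the 1-based closed convention
#' those packages use.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer-like vectors, 0-based half-open.
#' @param label optional character labels (free text).
#' @return A data frame of class `interval_set` semantics (plain data frame).
#' @export
intervals <- function(chrom = character(), start = integer(), end = integer(),
                      label = NA_character_) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   label = rep_len(as.character(label), length(chrom)),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    if (any(df$start < 0)) stop("interval start must be >= 0")
    if (any(df$end <= df$start)) stop("interval end must be > start (0-based half-open)")
  }
  df
}

empty_intervals <- function() intervals()

#' @keywords internal
as_granges0 <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(start = iv$start + 1, end = iv$end))
}

#' @keywords internal
granges_to_intervals <- function(gr) {
  if (length(gr) == 0) return(empty_intervals())
  intervals(as.character(GenomicRanges::seqnames(gr)),
            GenomicRanges::start(gr) - 1,
            GenomicRanges::end(gr))
}

#' Merge intervals within a gap
#'
#' Normalizes a set of raw intervals: sorts, and merges any two intervals on
#' the same chromosome separated by at most `gap` base pairs. `gap = 0`
#' merges only overlapping or bookended intervals. Intervals on different
#' chromosomes never merge.
#'
#' @param raw data frame with `chrom`, `start`, `end` (0-based half-open).
#' @param gap non-negative integer; maximum separation (bp) merged across.
#' @return Normalized interval data frame (labels are dropped on merge).
#' @export
merge_intervals <- function(raw, gap = 0) {
  if (length(gap) != 1 || is.na(gap) || gap < 0) stop("gap must be a single non-negative integer")
  if (is.null(raw) || nrow(raw) == 0) return(empty_intervals())
  gr <- as_granges0(intervals(raw$chrom, raw$start, raw$end))
  granges_to_intervals(GenomicRanges::reduce(gr, min.gapwidth = gap + 1))
}

#' Total base pairs covered by an interval set
#' @param iv interval data frame.
#' @export
covered_bp <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(0)
  sum(GenomicRanges::width(GenomicRanges::reduce(as_granges0(iv))))
}

# put both range sets on the union of their seqlevels so set operations
# across disjoint chromosome sets stay silent
align_granges <- function(a, b) {
  ga <- GenomicRanges::reduce(as_granges0(a))
  gb <- GenomicRanges::reduce(as_granges0(b))
  lv <- union(GenomicRanges::seqnames(GenomicRanges::seqinfo(ga)),
              GenomicRanges::seqnames(GenomicRanges::seqinfo(gb)))
  GenomeInfoDb::seqlevels(ga) <- lv
  GenomeInfoDb::seqlevels(gb) <- lv
  list(a = ga, b = gb)
}

#' Overlap between two interval sets in base pairs
#'
#' Symmetric; half-open adjacency ([0,100) vs [100,200)) does not count.
#'
#' @param a,b interval data frames.
#' @return Total overlapping base pairs (numeric scalar).
#' @export
intersect_bp <- function(a, b) {
  g <- align_granges(a, b)
  sum(GenomicRanges::width(GenomicRanges::intersect(g$a, g$b, ignore.strand = TRUE)))
}

#' Intersection of two interval sets
#' @param a,b interval data frames.
#' @return Normalized interval data frame of the overlap.
#' @export
intersect_intervals <- function(a, b) {
  g <- align_granges(a, b)
  granges_to_intervals(GenomicRanges::intersect(g$a, g$b, ignore.strand = TRUE))
}

#' Subtract one interval set from another
#' @param a,b interval data frames; returns a \\ b.
#' @export
setdiff_intervals <- function(a, b) {
  g <- align_granges(a, b)
  granges_to_intervals(GenomicRanges::setdiff(g$a, g$b, ignore.strand = TRUE))
}

#' Which positions fall inside an interval set
#'
#' @param chrom,pos vectors of chromosome and 1-based position (VCF
#'   convention); a position `p` is inside a BED interval `[s, e)` iff
#'   `s < p <= e` in 1-based terms, i.e. `p - 1` in `[s, e)`.
#' @param iv interval data frame.
#' @return logical vector.
#' @export
positions_in_intervals <- function(chrom, pos, iv) {
  if (is.null(iv) || nrow(iv) == 0) return(rep(FALSE, length(pos)))
  gr_pos <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos, width = 1))
  IRanges::overlapsAny(gr_pos, as_granges0(iv))
}

#' Write an interval set as BED
#' @param iv interval data frame.
#' @param path output path.
#' @export
write_bed <- function(iv, path) {
  df <- iv[, intersect(c("chrom", "start", "end", "label"), names(iv)), drop = FALSE]
  utils::write.table(format(df, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file as an interval set
#' @param path BED path (first 3-4 columns used).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  intervals(df[[1]], df[[2]], df[[3]],
            label = if (ncol(df) >= 4) df[[4]] else NA_character_)
}
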