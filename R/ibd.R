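#' IBD scan parameters
#'
#' Identity-by-descent segments between two inbred lines appear as long
#' stretches of near-perfect identity of their homozygous genotypes. The
#' scan tiles each chromosome with fixed windows, computes pairwise
#' identity per window over sites where both lines are non-missing
#' homozygotes (sites inside either line's het blocks are excluded as
#' uninformative), chains passing windows allowing short gaps, clips
#' against an exclusion mask (e.g. pericentromeric low-recombination
#' regions, supplied by the user), and drops short segments.
#'
#' @param window_bp window size (default 100 kb).
#' @param min_identity minimum per-window identity (default 0.995).
#' @param min_sites_per_window windows with fewer comparable sites are
#'   "undefined" and act as chainable gaps (default 20).
#' @param min_segment_bp minimum reported segment span (default 1 Mb).
#' @param merge_gap_windows maximum number of consecutive non-passing
#'   windows bridged inside a segment (default 1).
#' @param exclusion_mask interval set removed from segments before the
#'   length filter.
#' @export
ibd_params <- function(window_bp = 1e5, min_identity = 0.995,
                       min_sites_per_window = 20, min_segment_bp = 1e6,
                       merge_gap_windows = 1, exclusion_mask = empty_intervals()) {
  if (!(min_identity > 0 && min_identity <= 1)) stop("min_identity must be in (0, 1]")
  list(window_bp = window_bp, min_identity = min_identity,
       min_sites_per_window = min_sites_per_window,
       min_segment_bp = min_segment_bp, merge_gap_windows = merge_gap_windows,
       exclusion_mask = exclusion_mask)
}

#' Pairwise identity of two lines in a window
#'
#' @param table genotype_table.
#' @param line_a,line_b line ids.
#' @param window one-row interval data frame (0-based half-open).
#' @param min_sites minimum comparable sites; below it identity is `NA`.
#' @param exclude optional interval set of excluded sites (e.g. het blocks).
#' @return list `identity` (fraction or `NA`), `n` (compared sites).
#' @export
pairwise_identity <- function(table, line_a, line_b, window, min_sites = 20,
                              exclude = NULL) {
  ja <- match(line_a, table$lines); jb <- match(line_b, table$lines)
  if (is.na(ja) || is.na(jb)) stop("unknown line id")
  s <- table$sites
  sel <- s$chrom == window$chrom & (s$pos - 1) >= window$start & (s$pos - 1) < window$end
  if (!is.null(exclude) && nrow(exclude))
    sel <- sel & !positions_in_intervals(s$chrom, s$pos, exclude)
  ga <- table$gt[sel, ja]; gb <- table$gt[sel, jb]
  comp <- !is.na(ga) & !is.na(gb) & ga != 1L & gb != 1L
  n <- sum(comp)
  list(identity = if (n < min_sites) NA_real_ else mean(ga[comp] == gb[comp]), n = n)
}

#' Scan for IBD segments within populations
#'
#' @param table genotype_table (filtered).
#' @param meta [line_meta()]; only within-population pairs are scanned and
#'   lines flagged `excluded_from_popgen` are skipped.
#' @param params [ibd_params()].
#' @param blocks optional per-line het-block sets excluded from identity
#'   computation.
#' @param chrom_lengths named vector; defaults to the last site position
#'   per chromosome.
#' @return data frame: `line_a`, `line_b` (lexicographic), `chrom`,
#'   `start`, `end` (0-based half-open).
#' @export
call_ibd <- function(table, meta, params = ibd_params(), blocks = NULL,
                     chrom_lengths = NULL) {
  meta <- meta[!meta$excluded_from_popgen & meta$line_id %in% table$lines, ]
  s <- table$sites
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(s$pos, s$chrom, max)
  out <- list()
  for (pop in unique(meta$population)) {
    ids <- sort(meta$line_id[meta$population == pop])
    if (length(ids) < 2) next
    pairs <- utils::combn(ids, 2)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      ja <- match(a, table$lines); jb <- match(b, table$lines)
      excl <- rbind(blocks[[a]] %||% empty_intervals(),
                    blocks[[b]] %||% empty_intervals())
      usable <- !is.na(table$gt[, ja]) & !is.na(table$gt[, jb]) &
        table$gt[, ja] != 1L & table$gt[, jb] != 1L
      if (!is.null(excl) && nrow(excl))
        usable <- usable & !positions_in_intervals(s$chrom, s$pos, excl)
      for (ch in names(chrom_lengths)) {
        len <- chrom_lengths[[ch]]
        starts <- seq(0, max(0, len - 1), by = params$window_bp)
        sel <- which(usable & s$chrom == ch)
        if (length(sel) == 0) next
        w <- findInterval(s$pos[sel] - 1, starts)
        match_v <- table$gt[sel, ja] == table$gt[sel, jb]
        n_w <- tabulate(w, nbins = length(starts))
        k_w <- tabulate(w[match_v], nbins = length(starts))
        pass <- n_w >= params$min_sites_per_window &
          (k_w / pmax(n_w, 1)) >= params$min_identity
        segs <- chain_windows(pass, params$merge_gap_windows)
        for (r in seq_len(nrow(segs))) {
          iv <- intervals(ch, starts[segs$from[r]],
                          min(len, starts[segs$to[r]] + params$window_bp))
          iv <- setdiff_intervals(iv, params$exclusion_mask)
          if (nrow(iv)) {
            iv <- iv[iv$end - iv$start >= params$min_segment_bp, , drop = FALSE]
            if (nrow(iv))
              out[[length(out) + 1]] <- data.frame(
                line_a = a, line_b = b, chrom = iv$chrom,
                start = iv$start, end = iv$end, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(line_a = character(), line_b = character(),
                      chrom = character(), start = numeric(), end = numeric()))
  do.call(rbind, out)
}

# runs of TRUE allowing internal gaps of at most `gap` FALSE windows
chain_windows <- function(pass, gap) {
  idx <- which(pass)
  if (length(idx) == 0) return(data.frame(from = integer(), to = integer()))
  brk <- c(TRUE, diff(idx) > gap + 1)
  grp <- cumsum(brk)
  data.frame(from = tapply(idx, grp, min), to = tapply(idx, grp, max))
}

#' Write IBD segments as BED-like TSV
#' @param segs data frame from [call_ibd()].
#' @param path output path.
#' @export
write_ibd <- function(segs, path) {
  utils::write.table(segs[, c("chrom", "start", "end", "line_a", "line_b")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
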