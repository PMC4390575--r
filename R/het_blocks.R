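#' Het-block segmentation parameters
#'
#' Residual-heterozygosity blocks are contiguous genomic regions of one
#' inbred line with an excess of heterozygous SNP calls. Segmentation is a
#' two-state maximum-score dynamic program over the ordered SNP calls of a
#' chromosome: state "inbred" emits het calls with probability
#' `p_het_inbred`, state "block" with `p_het_block`; each state switch pays
#' `switch_cost` (natural-log units). Called blocks are merged within
#' `merge_gap_bp` and must satisfy `min_block_bp` and `min_het_sites`.
#'
#' Defaults are tuned so that simulated blocks spanning hundreds of kb to
#' tens of Mb at in-block het rates of 0.2 and above are recovered at
#' base-pair precision/recall above 0.95.
#'
#' @param p_het_block emission probability of a het call inside a block.
#' @param p_het_inbred emission probability outside.
#' @param switch_cost per-switch penalty on the log scale.
#' @param min_block_bp minimum reported block span (bp).
#' @param min_het_sites minimum het calls supporting a block.
#' @param merge_gap_bp blocks closer than this are merged before filtering.
#' @export
het_block_params <- function(p_het_block = 0.25, p_het_inbred = 0.005,
                             switch_cost = 12, min_block_bp = 1e5,
                             min_het_sites = 20, merge_gap_bp = 2e5) {
  if (!(0 < p_het_inbred && p_het_inbred < p_het_block && p_het_block < 1))
    stop("need 0 < p_het_inbred < p_het_block < 1")
  if (min_block_bp <= 0) stop("min_block_bp must be > 0")
  if (switch_cost < 0) stop("switch_cost must be >= 0")
  list(p_het_block = p_het_block, p_het_inbred = p_het_inbred,
       switch_cost = switch_cost, min_block_bp = min_block_bp,
       min_het_sites = min_het_sites, merge_gap_bp = merge_gap_bp)
}

# Viterbi over two states; obs is logical (het yes/no). Returns logical
# vector, TRUE where the best path is in the block state.
viterbi_two_state <- function(obs, p_block, p_inbred, switch_cost) {
  n <- length(obs)
  e_in <- ifelse(obs, log(p_inbred), log1p(-p_inbred))
  e_bl <- ifelse(obs, log(p_block), log1p(-p_block))
  # scores and backpointers; start in either state at no cost
  s_in <- e_in[1]; s_bl <- e_bl[1]
  bp_in <- matrix(FALSE, n, 2)  # col1: came-from-block for inbred state
  for (i in seq_len(n)[-1]) {
    stay_in <- s_in; jump_in <- s_bl - switch_cost
    stay_bl <- s_bl; jump_bl <- s_in - switch_cost
    from_bl_in <- jump_in > stay_in
    from_in_bl <- jump_bl > stay_bl
    new_in <- e_in[i] + if (from_bl_in) jump_in else stay_in
    new_bl <- e_bl[i] + if (from_in_bl) jump_bl else stay_bl
    bp_in[i, 1] <- from_bl_in
    bp_in[i, 2] <- from_in_bl
    s_in <- new_in; s_bl <- new_bl
  }
  state_block <- logical(n)
  cur_block <- s_bl > s_in
  state_block[n] <- cur_block
  for (i in rev(seq_len(n)[-1])) {
    switched <- if (cur_block) bp_in[i, 2] else bp_in[i, 1]
    if (switched) cur_block <- !cur_block
    state_block[i - 1] <- cur_block
  }
  state_block
}

# path score under the segmentation model (used by tests' exhaustive oracle)
segmentation_path_score <- function(obs, state_block, p_block, p_inbred, switch_cost) {
  e <- ifelse(state_block,
              ifelse(obs, log(p_block), log1p(-p_block)),
              ifelse(obs, log(p_inbred), log1p(-p_inbred)))
  sum(e) - switch_cost * sum(diff(state_block) != 0)
}

#' Call het blocks for one line
#'
#' Runs the two-state segmentation on the line's non-missing SNP calls per
#' chromosome (indels are excluded), snaps each block to its outermost het
#' sites, widens by half the chromosome's median inter-SNP spacing on each
#' side, merges within `merge_gap_bp`, and drops blocks below `min_block_bp`
#' or `min_het_sites`. Chromosomes with fewer than two usable calls yield
#' no blocks.
#'
#' @param table genotype_table (pre-filter: blocks must be known before the
#'   het-outside-blocks filter runs).
#' @param line_id line to segment.
#' @param params [het_block_params()].
#' @return Interval data frame (0-based half-open) of the line's blocks.
#' @export
call_het_blocks <- function(table, line_id, params = het_block_params()) {
  j <- match(line_id, table$lines)
  if (is.na(j)) stop("unknown line: ", line_id)
  snp <- table$sites$vtype == "snp"
  out <- empty_intervals()
  for (ch in unique(table$sites$chrom)) {
    idx <- which(snp & table$sites$chrom == ch & !is.na(table$gt[, j]))
    if (length(idx) < 2) next
    pos <- table$sites$pos[idx]
    obs <- table$gt[idx, j] == 1L
    st <- viterbi_two_state(obs, params$p_het_block, params$p_het_inbred,
                            params$switch_cost)
    if (!any(st)) next
    pad <- stats::median(diff(pos)) / 2
    runs <- rle(st)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (r in which(runs$values)) {
      het_in_run <- which(obs[starts[r]:ends[r]]) + starts[r] - 1
      if (length(het_in_run) == 0) next
      lo <- pos[min(het_in_run)]; hi <- pos[max(het_in_run)]
      out <- rbind(out, intervals(ch, max(0, lo - 1 - pad), hi + pad))
    }
  }
  if (nrow(out) == 0) return(out)
  out <- merge_intervals(out, gap = params$merge_gap_bp)
  # filter: span and supporting het sites
  keep <- logical(nrow(out))
  het_sites <- table$sites[snp & !is.na(table$gt[, j]) & table$gt[, j] == 1L,
                           c("chrom", "pos")]
  for (i in seq_len(nrow(out))) {
    span <- out$end[i] - out$start[i]
    n_het <- sum(het_sites$chrom == out$chrom[i] &
                   het_sites$pos - 1 >= out$start[i] &
                   het_sites$pos - 1 < out$end[i])
    keep[i] <- span >= params$min_block_bp && n_het >= params$min_het_sites
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call het blocks for every line
#' @param table genotype_table.
#' @param params [het_block_params()].
#' @return Named list of interval data frames, one per line.
#' @export
call_het_blocks_all <- function(table, params = het_block_params()) {
  stats::setNames(lapply(table$lines, function(l)
    call_het_blocks(table, l, params)), table$lines)
}

#' Summarize het blocks across lines
#'
#' @param blocks_by_line named list of per-line interval sets.
#' @param table optional genotype_table to tabulate per-line per-chromosome
#'   het/hom call counts.
#' @param large_cut_bp size cut for the "large block" fraction (default
#'   2 Mb).
#' @return list: `per_line` (line, n_blocks, total_bp), `mean_blocks_per_line`,
#'   `mean_block_bp`, `frac_large`, `n_blocks`, and (if `table` given)
#'   `call_counts` per line x chromosome.
#' @export
summarize_blocks <- function(blocks_by_line, table = NULL, large_cut_bp = 2e6) {
  sizes <- unlist(lapply(blocks_by_line, function(b)
    if (nrow(b)) b$end - b$start else numeric(0)))
  per_line <- data.frame(
    line_id = names(blocks_by_line),
    n_blocks = vapply(blocks_by_line, nrow, integer(1)),
    total_bp = vapply(blocks_by_line, covered_bp, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- list(per_line = per_line,
              n_blocks = length(sizes),
              mean_blocks_per_line = if (nrow(per_line)) mean(per_line$n_blocks) else 0,
              mean_block_bp = if (length(sizes)) mean(sizes) else 0,
              frac_large = if (length(sizes)) mean(sizes > large_cut_bp) else 0)
  if (!is.null(table)) {
    cc <- expand.grid(line_id = table$lines, chrom = unique(table$sites$chrom),
                      stringsAsFactors = FALSE)
    cc$n_het <- mapply(function(l, ch) {
      j <- match(l, table$lines)
      sum(table$sites$chrom == ch & !is.na(table$gt[, j]) & table$gt[, j] == 1L)
    }, cc$line_id, cc$chrom)
    cc$n_hom_alt <- mapply(function(l, ch) {
      j <- match(l, table$lines)
      sum(table$sites$chrom == ch & !is.na(table$gt[, j]) & table$gt[, j] == 2L)
    }, cc$line_id, cc$chrom)
    out$call_counts <- cc
  }
  out
}

#' Base-pair precision/recall of called blocks against truth
#' @param called,truth interval data frames.
#' @return named numeric `c(precision, recall)`; both 1 when both sets are
#'   empty, 0/1 conventions when only one is.
#' @export
block_recovery <- function(called, truth) {
  cb <- covered_bp(called); tb <- covered_bp(truth)
  ov <- intersect_bp(called, truth)
  c(precision = if (cb == 0) as.numeric(tb == 0) else ov / cb,
    recall = if (tb == 0) as.numeric(cb == 0) else ov / tb)
}
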