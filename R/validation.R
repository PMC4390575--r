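#' Read-count-ratio genotype caller
#'
#' Calls genotypes from deep-coverage allele counts: a site needs strictly
#' more than `min_depth` reads to be callable; an allele is "supported"
#' when its read fraction strictly exceeds `min_fraction`. Both alleles
#' supported gives a het call, only the alternate a hom-alt, only the
#' reference a hom-ref. Both thresholds are strict inequalities.
#'
#' @param ref_reads,alt_reads non-negative integer vectors.
#' @param min_depth depth must exceed this (default 100, exclusive).
#' @param min_fraction support fraction must exceed this (default 0.10,
#'   exclusive).
#' @return character vector in `{"hom_ref","het","hom_alt","no_call"}`.
#' @export
read_ratio_call <- function(ref_reads, alt_reads, min_depth = 100,
                            min_fraction = 0.10) {
  if (any(ref_reads < 0) || any(alt_reads < 0)) stop("read counts must be >= 0")
  depth <- ref_reads + alt_reads
  out <- rep("no_call", length(depth))
  ok <- depth > min_depth
  ref_sup <- ok & (ref_reads / depth) > min_fraction
  alt_sup <- ok & (alt_reads / depth) > min_fraction
  out[ref_sup & alt_sup] <- "het"
  out[ref_sup & !alt_sup] <- "hom_ref"
  out[!ref_sup & alt_sup] <- "hom_alt"
  out
}

#' Call a whole read-count set
#' @param counts list with matrices `ref` and `alt` (sites x lines), as
#'   from [simulate_read_counts()].
#' @inheritParams read_ratio_call
#' @return character matrix of calls.
#' @export
read_ratio_call_matrix <- function(counts, min_depth = 100, min_fraction = 0.10) {
  out <- matrix(read_ratio_call(as.vector(counts$ref), as.vector(counts$alt),
                                min_depth, min_fraction),
                nrow(counts$ref), dimnames = dimnames(counts$ref))
  out
}

#' Concordance between pipeline and deep-coverage calls
#'
#' Cross-tabulates pipeline genotype calls against the read-ratio caller's
#' calls, stratified by genotype class, het-block context, GQ bin and
#' recalibration flag. Only cells where the deep caller returns a call are
#' "comparable"; the validation rate per stratum is agreeing / comparable.
#'
#' @param table genotype_table (pipeline calls).
#' @param deep_calls character matrix from [read_ratio_call_matrix()] on
#'   the same site/line grid.
#' @param blocks optional per-line het-block interval sets for the
#'   in/out-of-block stratum.
#' @param gq_breaks breakpoints for GQ bins (default `c(0, 30, 60, 99)`,
#'   right-closed).
#' @return data frame: stratum columns, `comparable`, `agree`, `rate`.
#' @export
concordance <- function(table, deep_calls, blocks = NULL,
                        gq_breaks = c(0, 30, 60, 99)) {
  if (!all(dim(deep_calls) == dim(table$gt)))
    stop("deep_calls must match the genotype table's dimensions")
  pip <- matrix(gt_class(as.vector(table$gt)), nrow(table$gt))
  comparable <- !is.na(pip) & deep_calls != "no_call"
  if (!any(comparable)) stop("no comparable calls between the two call sets")
  in_block <- matrix(FALSE, nrow(table$gt), ncol(table$gt))
  if (!is.null(blocks)) {
    for (j in seq_along(table$lines)) {
      b <- blocks[[table$lines[j]]]
      if (!is.null(b) && nrow(b))
        in_block[, j] <- positions_in_intervals(table$sites$chrom, table$sites$pos, b)
    }
  }
  gq_bin <- matrix(cut(as.vector(table$gq), breaks = unique(c(-1, gq_breaks)),
                       include.lowest = FALSE), nrow(table$gq))
  idx <- which(comparable)
  df <- data.frame(
    gt = pip[idx],
    in_block = in_block[idx],
    gq_bin = as.character(gq_bin[idx]),
    recal_flag = table$sites$recal_flag[(idx - 1) %% nrow(pip) + 1],
    agree = pip[idx] == deep_calls[idx],
    stringsAsFactors = FALSE)
  agg <- stats::aggregate(agree ~ gt + in_block + gq_bin + recal_flag, df,
                          function(a) c(n = length(a), k = sum(a)))
  out <- data.frame(agg[c("gt", "in_block", "gq_bin", "recal_flag")],
                    comparable = agg$agree[, "n"], agree = agg$agree[, "k"])
  out$rate <- out$agree / out$comparable
  out
}

#' Overall validation rate by genotype class
#' @inheritParams concordance
#' @return data frame: `gt`, `comparable`, `agree`, `rate`.
#' @export
validation_by_class <- function(table, deep_calls) {
  pip <- matrix(gt_class(as.vector(table$gt)), nrow(table$gt))
  comparable <- !is.na(pip) & deep_calls != "no_call"
  idx <- which(comparable)
  df <- data.frame(gt = pip[idx], agree = pip[idx] == deep_calls[idx])
  agg <- stats::aggregate(agree ~ gt, df, function(a) c(n = length(a), k = sum(a)))
  out <- data.frame(gt = agg$gt, comparable = agg$agree[, "n"],
                    agree = agg$agree[, "k"])
  out$rate <- out$agree / out$comparable
  out
}
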