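#' Inversion definitions
#'
#' @param name inversion names.
#' @param chrom chromosome per inversion.
#' @param bp1_start,bp1_end first breakpoint interval (0-based half-open).
#' @param bp2_start,bp2_end optional second breakpoint interval (`NA` for
#'   single-breakpoint definitions).
#' @return data frame of inversion definitions.
#' @export
inversion_defs <- function(name, chrom, bp1_start, bp1_end,
                           bp2_start = NA, bp2_end = NA) {
  data.frame(name = name, chrom = chrom,
             bp1_start = bp1_start, bp1_end = bp1_end,
             bp2_start = bp2_start, bp2_end = bp2_end,
             stringsAsFactors = FALSE)
}

#' Genotype an inversion from breakpoint-read evidence
#'
#' A line's inversion genotype follows from which read classes are present:
#' reads supporting the inversion breakpoint, and reads bridging the
#' reference (non-inverted) sequence. Each class counts as present when it
#' has at least `min_support` reads. Both present: heterozygous; inversion
#' only: homozygous; reference only: absent; neither: unresolved.
#'
#' @param inv_reads,ref_bridge_reads non-negative integer vectors.
#' @param min_support reads needed to call a class present (default 2).
#' @return character vector in `{"absent","het","hom","unresolved"}`.
#' @export
genotype_inversion <- function(inv_reads, ref_bridge_reads, min_support = 2) {
  if (any(inv_reads < 0) || any(ref_bridge_reads < 0)) stop("read counts must be >= 0")
  inv_p <- inv_reads >= min_support
  ref_p <- ref_bridge_reads >= min_support
  out <- rep("unresolved", length(inv_p))
  out[inv_p & ref_p] <- "het"
  out[inv_p & !ref_p] <- "hom"
  out[!inv_p & ref_p] <- "absent"
  out
}

#' Genotype all lines from an evidence table
#' @param evidence data frame `line_id`, `inversion`, `inv_reads`,
#'   `ref_bridge_reads` (as from [simulate_inversion_evidence()]).
#' @inheritParams genotype_inversion
#' @return the evidence data frame with a `genotype` column appended.
#' @export
genotype_inversions_all <- function(evidence, min_support = 2) {
  evidence$genotype <- genotype_inversion(evidence$inv_reads,
                                          evidence$ref_bridge_reads, min_support)
  evidence
}

inv_breakpoint_intervals <- function(def_row) {
  iv <- intervals(def_row$chrom, def_row$bp1_start, def_row$bp1_end)
  if (!is.na(def_row$bp2_start))
    iv <- rbind(iv, intervals(def_row$chrom, def_row$bp2_start, def_row$bp2_end))
  iv
}

inv_span <- function(def_row) {
  iv <- inv_breakpoint_intervals(def_row)
  intervals(def_row$chrom, min(iv$start), max(iv$end))
}

#' Associate inversion genotypes with het blocks
#'
#' A heterozygous inversion call is "in block" when any of its breakpoint
#' intervals overlaps a het block of that line. Per-population explanatory
#' power is the fraction of large het blocks (span > `large_block_bp`)
#' overlapped by the breakpoint span (first to last breakpoint) of at least
#' one heterozygous inversion of the same line.
#'
#' @param calls genotyped evidence (from [genotype_inversions_all()]).
#' @param defs [inversion_defs()] data frame.
#' @param blocks named per-line het-block interval sets (required for every
#'   called line).
#' @param meta [line_meta()] (for the per-population summary).
#' @param large_block_bp large-block cut (default 2 Mb).
#' @return list: `per_inversion` (hom/het counts and in-block counts),
#'   `per_call` (each call with `in_block`), `explained` (per population:
#'   large blocks, explained, fraction).
#' @export
associate <- function(calls, defs, blocks, meta, large_block_bp = 2e6) {
  unknown <- setdiff(calls$inversion, defs$name)
  if (length(unknown)) stop("calls reference unknown inversion(s): ",
                            paste(unknown, collapse = ", "))
  calls$in_block <- FALSE
  for (i in seq_len(nrow(calls))) {
    if (!(calls$genotype[i] %in% c("het", "hom"))) next
    d <- defs[defs$name == calls$inversion[i], ]
    b <- blocks[[calls$line_id[i]]]
    if (is.null(b)) stop("no het blocks available for line ", calls$line_id[i])
    calls$in_block[i] <- intersect_bp(inv_breakpoint_intervals(d), b) > 0
  }
  per_inv <- do.call(rbind, lapply(unique(calls$inversion), function(nm) {
    cc <- calls[calls$inversion == nm, ]
    data.frame(inversion = nm,
               n_hom = sum(cc$genotype == "hom"),
               hom_in_block = sum(cc$genotype == "hom" & cc$in_block),
               n_het = sum(cc$genotype == "het"),
               het_in_block = sum(cc$genotype == "het" & cc$in_block),
               stringsAsFactors = FALSE)
  }))
  # explanatory power per population over large blocks
  expl <- do.call(rbind, lapply(unique(meta$population), function(pop) {
    ids <- meta$line_id[meta$population == pop]
    n_large <- 0L; n_expl <- 0L
    for (l in intersect(ids, names(blocks))) {
      b <- blocks[[l]]
      if (is.null(b) || nrow(b) == 0) next
      big <- b[b$end - b$start > large_block_bp, , drop = FALSE]
      if (nrow(big) == 0) next
      het_invs <- calls$inversion[calls$line_id == l & calls$genotype == "het"]
      spans <- if (length(het_invs)) do.call(rbind, lapply(het_invs, function(nm)
        inv_span(defs[defs$name == nm, ]))) else empty_intervals()
      for (r in seq_len(nrow(big))) {
        n_large <- n_large + 1L
        if (nrow(spans) && intersect_bp(big[r, , drop = FALSE], spans) > 0)
          n_expl <- n_expl + 1L
      }
    }
    data.frame(population = pop, large_blocks = n_large, explained = n_expl,
               fraction = if (n_large) n_expl / n_large else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(per_inversion = per_inv, per_call = calls, explained = expl)
}
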