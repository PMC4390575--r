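#' Genotype filter policy
#'
#' Class-wise genotype filtering: each rule matches a combination of
#' variant type, genotype class, het-block context and recalibration flag,
#' and gives the minimum GQ a matching call needs to be kept (`Inf` masks
#' the class unconditionally, `0` always keeps it). The first matching rule
#' wins; the rule set must be total over all call classes, which is checked
#' at construction.
#'
#' The default policy encodes: heterozygous calls outside het blocks are
#' masked for both SNPs and indels regardless of quality; SNP hets inside
#' blocks need GQ >= 60; SNP homozygotes need GQ >= 30 on unflagged sites
#' and GQ >= 60 on recalibration-flagged sites; indel homozygotes need
#' GQ >= 60; indel hets are retained only inside blocks at exactly GQ 99
#' (the sole het-indel class whose validation clears the indel bar).
#'
#' @param snp_rules,indel_rules data frames with columns `gt` (`"het"`,
#'   `"hom"` = both homozygote classes, `"hom_ref"`, `"hom_alt"`),
#'   `in_block` (`"in"`, `"out"`, `"any"`), `recal` (`"flagged"`,
#'   `"unflagged"`, `"any"`), `min_gq`.
#' @param indel_proximity_nt inclusive distance (nt) for SNP-near-indel
#'   masking.
#' @param drop_het_outside_blocks_snp,drop_het_outside_blocks_indel
#'   convenience switches prepending the unconditional het-outside-block
#'   mask rule.
#' @return list of class `filter_policy`.
#' @export
filter_policy <- function(snp_rules = NULL, indel_rules = NULL,
                          indel_proximity_nt = 5,
                          drop_het_outside_blocks_snp = TRUE,
                          drop_het_outside_blocks_indel = TRUE) {
  if (indel_proximity_nt < 0) stop("indel_proximity_nt must be >= 0")
  rule <- function(gt, in_block, recal, min_gq)
    data.frame(gt = gt, in_block = in_block, recal = recal, min_gq = min_gq,
               stringsAsFactors = FALSE)
  if (is.null(snp_rules)) {
    snp_rules <- rbind(
      rule("het", "in", "any", 60),
      rule("hom", "any", "flagged", 60),
      rule("hom", "any", "unflagged", 30))
  }
  if (is.null(indel_rules)) {
    indel_rules <- rbind(
      rule("het", "in", "any", 99),
      rule("hom", "any", "any", 60))
  }
  if (drop_het_outside_blocks_snp)
    snp_rules <- rbind(rule("het", "out", "any", Inf), snp_rules)
  if (drop_het_outside_blocks_indel)
    indel_rules <- rbind(rule("het", "out", "any", Inf), indel_rules)
  pol <- list(snp_rules = snp_rules, indel_rules = indel_rules,
              indel_proximity_nt = indel_proximity_nt)
  class(pol) <- "filter_policy"
  check_policy_total(pol)
  pol
}

rule_matches <- function(rules, gt_cls, in_block, flagged) {
  gt_ok <- rules$gt == gt_cls |
    (rules$gt == "hom" & gt_cls %in% c("hom_ref", "hom_alt"))
  blk_ok <- rules$in_block == "any" | rules$in_block == ifelse(in_block, "in", "out")
  rc_ok <- rules$recal == "any" | rules$recal == ifelse(flagged, "flagged", "unflagged")
  which(gt_ok & blk_ok & rc_ok)
}

check_policy_total <- function(pol) {
  for (vt in c("snp", "indel")) {
    rules <- if (vt == "snp") pol$snp_rules else pol$indel_rules
    for (g in c("hom_ref", "het", "hom_alt"))
      for (b in c(TRUE, FALSE))
        for (f in c(TRUE, FALSE))
          if (length(rule_matches(rules, g, b, f)) == 0)
            stop(sprintf("filter policy not total: no %s rule for gt=%s in_block=%s flagged=%s",
                         vt, g, b, f))
  }
  invisible(pol)
}

#' Apply class-wise genotype filters
#'
#' Masks (sets to missing) every call whose first matching rule it fails.
#' Sites left with no non-missing non-reference call are flagged
#' `invariant_after_filter` in the returned table's sites (records are
#' retained). Idempotent: a second application changes nothing.
#'
#' @param table genotype_table (with blocks computed on it pre-filter).
#' @param blocks named per-line list of het-block interval sets.
#' @param policy [filter_policy()].
#' @return list: `table` (filtered), `report` (masked counts by reason,
#'   variant-site counts before/after, both with invariant records counted
#'   and dropped).
#' @export
apply_filters <- function(table, blocks, policy = filter_policy()) {
  gt <- table$gt; gq <- table$gq
  s <- table$sites
  reason <- matrix(NA_character_, nrow(gt), ncol(gt))
  for (j in seq_along(table$lines)) {
    b <- blocks[[table$lines[j]]] %||% empty_intervals()
    in_block <- positions_in_intervals(s$chrom, s$pos, b)
    for (vt in c("snp", "indel")) {
      rules <- if (vt == "snp") policy$snp_rules else policy$indel_rules
      vsel <- s$vtype == vt
      for (g in c("hom_ref", "het", "hom_alt")) {
        for (blk in c(TRUE, FALSE)) {
          for (fl in c(TRUE, FALSE)) {
            sel <- vsel & !is.na(gt[, j]) & gt_class(gt[, j]) == g &
              in_block == blk & s$recal_flag == fl
            if (!any(sel)) next
            ri <- rule_matches(rules, g, blk, fl)[1]
            fail <- sel & gq[, j] < rules$min_gq[ri]
            fail[is.na(fail)] <- FALSE
            if (any(fail)) {
              reason[fail, j] <- sprintf("%s_rule_%d", vt, ri)
              gt[fail, j] <- NA_integer_
              gq[fail, j] <- NA_integer_
            }
          }
        }
      }
    }
  }
  out <- table
  out$gt <- gt; out$gq <- gq
  variant_before <- sum(rowSums(table$gt != 0, na.rm = TRUE) > 0)
  nonvar <- rowSums(gt != 0, na.rm = TRUE) == 0
  out$sites$invariant_after_filter <- nonvar
  report <- list(
    masked_by_reason = table(reason[!is.na(reason)]),
    n_masked = sum(!is.na(reason)),
    variant_sites_before = variant_before,
    variant_sites_after = sum(!nonvar),
    sites_total = nrow(s))
  list(table = out, report = report)
}

#' Mask SNP genotypes near indel calls in the same line
#'
#' A SNP genotype in line L is masked iff L carries a non-missing,
#' non-hom-ref indel call on the same chromosome whose POS distance to the
#' SNP POS is at most `distance_nt` (inclusive; the indel's anchor
#' coordinate is used). Masking is per line, not per site.
#'
#' @param table genotype_table containing SNP and indel records.
#' @param distance_nt inclusive distance in nt (default 5).
#' @return list: `table`, `n_masked`.
#' @export
mask_snps_near_indels <- function(table, distance_nt = 5) {
  gt <- table$gt; gq <- table$gq
  s <- table$sites
  snp_i <- which(s$vtype == "snp")
  n_masked <- 0L
  for (j in seq_along(table$lines)) {
    ind_i <- which(s$vtype == "indel" & !is.na(gt[, j]) & gt[, j] != 0L)
    if (length(ind_i) == 0) next
    for (ch in unique(s$chrom[ind_i])) {
      ip <- sort(s$pos[ind_i[s$chrom[ind_i] == ch]])
      sp_idx <- snp_i[s$chrom[snp_i] == ch]
      if (length(sp_idx) == 0) next
      sp <- s$pos[sp_idx]
      # nearest indel distance via findInterval on sorted indel positions
      k <- findInterval(sp, ip)
      d_lo <- ifelse(k >= 1, sp - ip[pmax(k, 1)], Inf)
      d_hi <- ifelse(k < length(ip), ip[pmin(k + 1, length(ip))] - sp, Inf)
      hit <- pmin(d_lo, d_hi) <= distance_nt & !is.na(gt[sp_idx, j])
      if (any(hit)) {
        n_masked <- n_masked + sum(hit)
        gt[sp_idx[hit], j] <- NA_integer_
        gq[sp_idx[hit], j] <- NA_integer_
      }
    }
  }
  out <- table; out$gt <- gt; out$gq <- gq
  list(table = out, n_masked = n_masked)
}

#' Apply callability and IBD region masks
#'
#' The callability mask (uncallable regions) drops sites for all lines
#' (records are removed). Each IBD segment must carry a label of the form
#' `"lineA|lineB"`; within the segment the calls of one line of the pair
#' (by default the lexicographically second) are masked, so the pair
#' contributes a single representative to population statistics.
#'
#' @param table genotype_table.
#' @param masks named list of interval sets: `uncallable` (optional),
#'   `ibd` (optional, labels `"lineA|lineB"`).
#' @param ibd_drop which line of each IBD pair to mask: `"second"` or
#'   `"first"` in lexicographic order.
#' @return filtered genotype_table.
#' @export
apply_region_masks <- function(table, masks = list(), ibd_drop = c("second", "first")) {
  ibd_drop <- match.arg(ibd_drop)
  out <- table
  if (!is.null(masks$uncallable) && nrow(masks$uncallable) > 0) {
    drop <- positions_in_intervals(out$sites$chrom, out$sites$pos, masks$uncallable)
    out <- subset_table(out, !drop)
  }
  ibd <- masks$ibd
  if (!is.null(ibd) && nrow(ibd) > 0) {
    if (any(is.na(ibd$label)) || any(!grepl("|", ibd$label, fixed = TRUE)))
      stop("IBD mask intervals must be labelled 'lineA|lineB'")
    for (i in seq_len(nrow(ibd))) {
      pair <- sort(strsplit(ibd$label[i], "|", fixed = TRUE)[[1]])
      victim <- if (ibd_drop == "second") pair[2] else pair[1]
      j <- match(victim, out$lines)
      if (is.na(j)) next
      sel <- positions_in_intervals(out$sites$chrom, out$sites$pos, ibd[i, , drop = FALSE])
      out$gt[sel, j] <- NA_integer_
      out$gq[sel, j] <- NA_integer_
    }
  }
  out
}

#' Full filter composition
#'
#' Fixed order: class-wise GQ/flag/context rules, then SNP-near-indel
#' masking, then region masks (callability, IBD).
#'
#' @inheritParams apply_filters
#' @param masks see [apply_region_masks()].
#' @return list: `table`, `report` (class-rule report plus
#'   `n_masked_near_indel`).
#' @export
filter_genotypes <- function(table, blocks, policy = filter_policy(),
                             masks = list()) {
  f1 <- apply_filters(table, blocks, policy)
  f2 <- mask_snps_near_indels(f1$table, policy$indel_proximity_nt)
  tab <- apply_region_masks(f2$table, masks)
  rep <- f1$report
  rep$n_masked_near_indel <- f2$n_masked
  list(table = tab, report = rep)
}
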