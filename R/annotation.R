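#' Classify variant sites against a simplified gene model
#'
#' Assigns each SNP a functional category from a simplified annotation:
#' coding positions are classified by codon degeneracy (a site where all
#' four nucleotides encode the same amino acid is `fourfold`; an
#' amino-acid-changing alternate allele is `nonsynonymous`; other coding
#' changes are `synonymous_non4fold`), introns of at most
#' `small_intron_max` bp contribute `small_intron` sites in their interior
#' (an `splice_buffer` bp buffer at each edge is excluded), `UTR` features
#' map through, and everything else is `intergenic`. The "neutral" site
#' class used by downstream statistics is `fourfold` plus `small_intron`.
#'
#' @param sites site data frame (`chrom`, `pos` 1-based, `ref`, `alt`,
#'   `vtype`); only SNPs are classified, indels get `other`.
#' @param gene_model data frame with columns `transcript`, `chrom`,
#'   `feature` (`"CDS"`, `"intron"`, `"UTR"`), `start`, `end` (1-based,
#'   inclusive), `strand` (`"+"`/`"-"`). CDS intervals of a transcript are
#'   concatenated in genomic order (reverse order on `-`); a transcript
#'   whose CDS length is not a multiple of 3 is skipped with a warning.
#' @param ref_seq named list/vector of chromosome sequences (character),
#'   1-based indexing; required to derive codons for CDS classification.
#' @param small_intron_max small-intron size cut in bp (default 65).
#' @param splice_buffer interior buffer at each splice edge (default 8).
#' @return data frame: `category`, `impact`, `neutral` per site.
#' @export
classify_sites <- function(sites, gene_model, ref_seq,
                           small_intron_max = 65, splice_buffer = 8) {
  n <- nrow(sites)
  category <- rep("intergenic", n)
  stop_gain <- rep(FALSE, n)
  category[sites$vtype != "snp"] <- "other"

  # UTR and small-intron features
  utr <- gene_model[gene_model$feature == "UTR", , drop = FALSE]
  for (i in seq_len(nrow(utr)))
    category[sites$vtype == "snp" & sites$chrom == utr$chrom[i] &
               sites$pos >= utr$start[i] & sites$pos <= utr$end[i]] <- "UTR"
  intr <- gene_model[gene_model$feature == "intron", , drop = FALSE]
  for (i in seq_len(nrow(intr))) {
    len <- intr$end[i] - intr$start[i] + 1
    if (len > small_intron_max) next
    lo <- intr$start[i] + splice_buffer; hi <- intr$end[i] - splice_buffer
    if (lo > hi) next
    category[sites$vtype == "snp" & sites$chrom == intr$chrom[i] &
               sites$pos >= lo & sites$pos <= hi] <- "small_intron"
  }

  # CDS: build per-position codon context
  code <- Biostrings::GENETIC_CODE
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cds <- gene_model[gene_model$feature == "CDS", , drop = FALSE]
  for (tr in unique(cds$transcript)) {
    tc <- cds[cds$transcript == tr, , drop = FALSE]
    strand <- tc$strand[1]
    tc <- tc[order(tc$start, decreasing = (strand == "-")), , drop = FALSE]
    gpos <- unlist(lapply(seq_len(nrow(tc)), function(i) {
      p <- tc$start[i]:tc$end[i]
      if (strand == "-") rev(p) else p
    }))
    if (length(gpos) %% 3 != 0) {
      warning("transcript ", tr, " CDS length not divisible by 3; skipped")
      next
    }
    chrom <- tc$chrom[1]
    seq_ch <- ref_seq[[chrom]]
    base_at <- function(p) toupper(substr(seq_ch, p, p))
    hit <- which(sites$vtype == "snp" & sites$chrom == chrom &
                   sites$pos %in% gpos)
    for (si in hit) {
      ci <- match(sites$pos[si], gpos)                 # coding coordinate
      codon_idx <- (ci - 1) %/% 3
      offs <- (ci - 1) %% 3 + 1                        # position in codon
      cpos <- gpos[codon_idx * 3 + 1:3]
      codon <- vapply(cpos, base_at, character(1))
      if (strand == "-") codon <- comp[codon]
      ref_nt <- base_at(sites$pos[si]); alt_nt <- toupper(sites$alt[si])
      if (strand == "-") { ref_nt <- comp[[ref_nt]]; alt_nt <- comp[[alt_nt]] }
      codon[offs] <- ref_nt                            # ensure ref codon
      aa_ref <- code[[paste(codon, collapse = "")]]
      alts <- setdiff(c("A", "C", "G", "T"), codon[offs])
      aa_all <- vapply(alts, function(a) {
        cd <- codon; cd[offs] <- a; code[[paste(cd, collapse = "")]]
      }, character(1))
      cd_alt <- codon; cd_alt[offs] <- alt_nt
      aa_alt <- code[[paste(cd_alt, collapse = "")]]
      category[si] <- if (aa_alt != aa_ref) "nonsynonymous"
        else if (all(aa_all == aa_ref)) "fourfold"
        else "synonymous_non4fold"
      if (aa_alt == "*" && aa_ref != "*") stop_gain[si] <- TRUE
    }
  }
  impact <- rep("modifier", n)
  impact[category == "nonsynonymous"] <- "moderate"
  impact[category %in% c("synonymous_non4fold", "fourfold")] <- "low"
  impact[stop_gain] <- "high"
  data.frame(category = category, impact = impact,
             neutral = category %in% c("fourfold", "small_intron"),
             stringsAsFactors = FALSE)
}

#' Polarize segregating alleles against outgroups
#'
#' Weighted-vote ancestral inference: the posterior for allele *a* is the
#' summed weight of outgroups carrying *a*, normalized over outgroups
#' carrying either segregating allele; outgroups carrying a third allele
#' are uninformative. A site is polarized when the winning allele is one of
#' the two segregating alleles and its posterior reaches `threshold`
#' (default 0.70). With no informative outgroup the site is unpolarized and
#' the posterior undefined.
#'
#' @param ref,alt character vectors of the segregating alleles.
#' @param outgroups character matrix (sites x outgroups) of outgroup
#'   alleles (`NA` for missing).
#' @param weights per-outgroup weights (default equal).
#' @param threshold posterior needed to polarize (default 0.70).
#' @return data frame: `ancestral` (allele or `NA`), `derived`, `posterior`,
#'   `polarized`.
#' @export
polarize <- function(ref, alt, outgroups, weights = NULL, threshold = 0.70) {
  outgroups <- as.matrix(outgroups)
  if (ncol(outgroups) < 1) stop("at least one outgroup required")
  if (is.null(weights)) weights <- rep(1, ncol(outgroups))
  n <- length(ref)
  w_ref <- w_alt <- numeric(n)
  for (k in seq_len(ncol(outgroups))) {
    w_ref <- w_ref + weights[k] * (!is.na(outgroups[, k]) & outgroups[, k] == ref)
    w_alt <- w_alt + weights[k] * (!is.na(outgroups[, k]) & outgroups[, k] == alt)
  }
  tot <- w_ref + w_alt
  post <- ifelse(tot > 0, pmax(w_ref, w_alt) / tot, NA_real_)
  anc <- ifelse(tot == 0, NA_character_, ifelse(w_ref >= w_alt, ref, alt))
  polarized <- !is.na(post) & post >= threshold
  anc[!polarized] <- NA_character_
  data.frame(ancestral = anc,
             derived = ifelse(polarized, ifelse(anc == ref, alt, ref), NA_character_),
             posterior = post, polarized = polarized, stringsAsFactors = FALSE)
}
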