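#' Genotype tables
#'
#' The pipeline's central container: a sites-by-lines matrix of genotype
#' calls with per-call genotype qualities. Genotypes are stored as an
#' integer matrix with codes 0 = homozygous reference, 1 = heterozygous,
#' 2 = homozygous alternate, `NA` = missing; `gq` is an integer matrix of
#' per-genotype quality scores (0-99, `NA` where the call is missing).
#'
#' Sites carry VCF-convention 1-based positions, a variant type
#' (`"snp"`/`"indel"`) and `recal_flag`, a logical site-level flag set when
#' variant-quality recalibration flagged the site.
#'
#' @param sites data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `vtype`, `recal_flag`.
#' @param lines character vector of line identifiers.
#' @param gt integer matrix `nrow(sites)` x `length(lines)`.
#' @param gq integer matrix of the same shape.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(sites, lines, gt, gq) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref", "alt", "vtype", "recal_flag")
  missing_cols <- setdiff(req, names(sites))
  if (length(missing_cols)) stop("sites lacks columns: ", paste(missing_cols, collapse = ", "))
  gt <- as.matrix(gt); gq <- as.matrix(gq)
  storage.mode(gt) <- "integer"; storage.mode(gq) <- "integer"
  if (!all(dim(gt) == c(nrow(sites), length(lines))) || !all(dim(gq) == dim(gt)))
    stop("gt/gq dimensions must be sites x lines")
  colnames(gt) <- colnames(gq) <- lines
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]; rownames(sites) <- NULL
  gt <- gt[ord, , drop = FALSE]; gq <- gq[ord, , drop = FALSE]
  obj <- structure(list(sites = sites, lines = lines, gt = gt, gq = gq),
                   class = "genotype_table")
  validate_genotype_table(obj)
  obj
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d sites (%d snp, %d indel) x %d lines\n",
              nrow(x$sites), sum(x$sites$vtype == "snp"),
              sum(x$sites$vtype == "indel"), length(x$lines)))
  invisible(x)
}

#' Validate a genotype table's invariants
#' @param x genotype_table.
#' @return `x`, invisibly; stops on violation.
#' @export
validate_genotype_table <- function(x) {
  s <- x$sites
  if (any(s$pos < 1)) stop("positions must be >= 1 (VCF convention)")
  if (any(s$ref == s$alt)) stop("ref and alt alleles must differ")
  snp <- s$vtype == "snp"
  if (any(nchar(s$ref[snp]) != 1 | nchar(s$alt[snp]) != 1))
    stop("SNP records must have single-nucleotide alleles")
  if (is.unsorted(order(s$chrom, s$pos))) stop("sites must be sorted by (chrom, pos)")
  key <- paste(s$chrom, s$pos, s$ref, s$alt)
  if (anyDuplicated(key)) stop("duplicate (chrom, pos, ref, alt) records")
  bad <- !is.na(x$gt) & !(x$gt %in% 0:2)
  if (any(bad)) stop("genotype codes must be 0/1/2/NA")
  if (any(!is.na(x$gt) & is.na(x$gq))) stop("gq must be defined for non-missing calls")
  invisible(x)
}

GT_LEVELS <- c("hom_ref", "het", "hom_alt")

#' Map integer genotype codes to class names
#' @param code integer vector (0/1/2/NA).
#' @return character vector (`"hom_ref"`, `"het"`, `"hom_alt"`, `NA`).
#' @export
gt_class <- function(code) {
  out <- rep(NA_character_, length(code))
  ok <- !is.na(code)
  out[ok] <- GT_LEVELS[code[ok] + 1L]
  out
}

#' Line metadata
#'
#' One row per line: identifier, population label, and a flag excluding the
#' line from population-genetic statistics (e.g. lines with suspect
#' provenance, which stay in the panel but not in the popgen sample).
#'
#' @param line_id character vector.
#' @param population character vector of population labels.
#' @param excluded_from_popgen logical vector (default all `FALSE`).
#' @export
line_meta <- function(line_id, population, excluded_from_popgen = FALSE) {
  data.frame(line_id = as.character(line_id),
             population = as.character(population),
             excluded_from_popgen = rep_len(excluded_from_popgen, length(line_id)),
             stringsAsFactors = FALSE)
}

#' Read line metadata from TSV (line_id<TAB>population[<TAB>excluded])
#' @param path TSV path, with header.
#' @export
read_line_meta <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  line_meta(df$line_id, df$population,
            if ("excluded_from_popgen" %in% names(df)) df$excluded_from_popgen else FALSE)
}

#' Write line metadata as TSV
#' @param meta line_meta data frame.
#' @param path output path.
#' @export
write_line_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

GT_STRING_MAP <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
                   "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)

#' Load a VCF into a genotype table
#'
#' Reads a VCF 4.x file (via \pkg{vcfR}), keeping biallelic SNP and indel
#' records; multiallelic records are split into one biallelic record per
#' alternate allele (genotypes involving other alternates become missing and
#' the split origin is flagged in `sites$multiallelic_split`). The site
#' `recal_flag` is set when the FILTER column contains `recal_filter_tag`.
#'
#' @param path VCF path (plain text or bgzip).
#' @param gq_field FORMAT key holding the genotype quality (default `"GQ"`).
#' @param recal_filter_tag FILTER tag marking recalibration-flagged sites.
#' @param missing_gq how to treat calls lacking GQ: `"missing"` masks the
#'   call; `"zero"` keeps it at GQ 0.
#' @return A [genotype_table()].
#' @export
vcf_to_table <- function(path, gq_field = "GQ", recal_filter_tag = "RECAL_FLAG",
                         missing_gq = c("missing", "zero")) {
  missing_gq <- match.arg(missing_gq)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no records: ", path)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  gq_raw <- suppressWarnings(vcfR::extract.gt(v, element = gq_field, as.numeric = TRUE))
  if (is.null(gq_raw)) gq_raw <- matrix(NA_real_, nrow(gt_raw), ncol(gt_raw))
  lines <- colnames(gt_raw)

  out_sites <- list(); out_gt <- list(); out_gq <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    multi <- length(alts) > 1
    for (ai in seq_along(alts)) {
      alt <- alts[ai]
      ref <- fix$REF[i]
      gt_codes <- rep(NA_integer_, length(lines))
      raw <- gt_raw[i, ]
      raw <- gsub("|", "/", raw, fixed = TRUE)
      if (multi) {
        # relabel this alternate as 1, other alternates as missing
        parts <- strsplit(raw, "/", fixed = TRUE)
        gt_codes <- vapply(parts, function(p) {
          if (length(p) != 2 || any(p == ".")) return(NA_integer_)
          p <- suppressWarnings(as.integer(p))
          if (any(is.na(p))) return(NA_integer_)
          if (any(!(p %in% c(0L, ai)))) return(NA_integer_)
          sum(p == ai)
        }, integer(1))
      } else {
        norm <- sub("\\|", "/", raw)
        gt_codes <- unname(GT_STRING_MAP[norm])
        gt_codes[is.na(norm) | norm %in% c("./.", ".")] <- NA_integer_
        if (any(!is.na(norm) & !(norm %in% c(names(GT_STRING_MAP), "./.", ".")) & is.na(gt_codes)))
          stop("unparseable genotype in record ", fix$CHROM[i], ":", fix$POS[i])
      }
      gq_codes <- as.integer(round(gq_raw[i, ]))
      if (missing_gq == "missing") {
        gt_codes[!is.na(gt_codes) & is.na(gq_codes)] <- NA_integer_
      } else {
        gq_codes[!is.na(gt_codes) & is.na(gq_codes)] <- 0L
      }
      gq_codes[is.na(gt_codes)] <- NA_integer_
      out_sites[[length(out_sites) + 1]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.numeric(fix$POS[i]), ref = ref, alt = alt,
        vtype = if (nchar(ref) == 1 && nchar(alt) == 1) "snp" else "indel",
        recal_flag = grepl(recal_filter_tag, fix$FILTER[i] %||% "", fixed = TRUE),
        multiallelic_split = multi, stringsAsFactors = FALSE)
      out_gt[[length(out_gt) + 1]] <- gt_codes
      out_gq[[length(out_gq) + 1]] <- gq_codes
    }
  }
  sites <- do.call(rbind, out_sites)
  genotype_table(sites, lines, do.call(rbind, out_gt), do.call(rbind, out_gq))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Write a genotype table as VCF 4.2
#'
#' Masked/missing genotypes are written as `./.`; flagged sites carry the
#' recalibration tag in FILTER, all others `PASS`. Round-tripping through
#' [vcf_to_table()] recovers the table on all loaded fields.
#'
#' @param x genotype_table.
#' @param path output path (plain text).
#' @param recal_filter_tag FILTER tag for `recal_flag` sites.
#' @export
table_to_vcf <- function(x, path, recal_filter_tag = "RECAL_FLAG") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=inbredvar",
               sprintf("##FILTER=<ID=%s,Description=\"Flagged by variant quality recalibration\">",
                       recal_filter_tag),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                       "FORMAT", x$lines), collapse = "\t")), con)
  gt_str <- matrix("./.", nrow(x$gt), ncol(x$gt))
  gt_str[!is.na(x$gt) & x$gt == 0L] <- "0/0"
  gt_str[!is.na(x$gt) & x$gt == 1L] <- "0/1"
  gt_str[!is.na(x$gt) & x$gt == 2L] <- "1/1"
  cell <- matrix(paste0(gt_str, ":", ifelse(is.na(x$gq), ".", x$gq)),
                 nrow(x$gt), ncol(x$gt))
  cell[gt_str == "./."] <- "./.:."
  body <- paste(x$sites$chrom, format(x$sites$pos, scientific = FALSE, trim = TRUE),
                ".", x$sites$ref, x$sites$alt, ".",
                ifelse(x$sites$recal_flag, recal_filter_tag, "PASS"), ".",
                "GT:GQ", apply(cell, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Subset a genotype table by site index and/or lines
#' @param x genotype_table.
#' @param sites_idx logical or integer index over sites (default all).
#' @param lines character vector of line ids (default all).
#' @export
subset_table <- function(x, sites_idx = NULL, lines = NULL) {
  if (is.null(sites_idx)) sites_idx <- seq_len(nrow(x$sites))
  if (is.null(lines)) lines <- x$lines
  li <- match(lines, x$lines)
  if (anyNA(li)) stop("unknown line id(s): ", paste(lines[is.na(li)], collapse = ", "))
  sites <- x$sites[sites_idx, , drop = FALSE]; rownames(sites) <- NULL
  genotype_table(sites, lines,
                 x$gt[sites_idx, li, drop = FALSE],
                 x$gq[sites_idx, li, drop = FALSE])
}
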