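#' Run the full cohort analysis on a simulated panel
#'
#' Orchestrates the stages in pipeline order on a synthetic cohort:
#' simulate, segment het blocks, apply genotype filters (class rules,
#' SNP-near-indel masking, region masks), validate against simulated deep
#' read counts, scan IBD, genotype inversions and quantify their het-block
#' association, polarize against simulated outgroups, and compute the
#' population-genetic summaries. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @param het_params [het_block_params()].
#' @param policy [filter_policy()].
#' @param ibd_par [ibd_params()].
#' @param masks optional region masks (see [apply_region_masks()]).
#' @param outdir optional directory; when given, stage outputs are written
#'   (VCF, per-line BED, TSVs) and a manifest with checksums returned.
#' @return list with every stage's result: `sim`, `blocks`, `block_summary`,
#'   `filtered`, `filter_report`, `deep_calls`, `validation`, `ibd`,
#'   `inversions`, `polar`, `alleles`, `windows`, `fst`, `sfs`, and (when
#'   `outdir` is set) `manifest`.
#' @export
run_cohort_analysis <- function(config = sim_config(),
                                het_params = het_block_params(),
                                policy = filter_policy(),
                                ibd_par = ibd_params(),
                                masks = list(),
                                outdir = NULL) {
  sim <- simulate_cohort(config)
  blocks <- call_het_blocks_all(sim$table, het_params)
  block_summary <- summarize_blocks(blocks)

  filt <- filter_genotypes(sim$table, blocks, policy, masks)

  counts <- simulate_read_counts(sim$table, sim$truth, config$depth_mean,
                                 config$read_error, seed = config$seed + 1)
  deep <- read_ratio_call_matrix(counts)
  validation <- validation_by_class(sim$table, deep)

  ibd <- call_ibd(filt$table, sim$meta, ibd_par, blocks = blocks,
                  chrom_lengths = config$chrom_lengths)

  inv <- NULL
  if (length(config$planted_inversions)) {
    ev <- simulate_inversion_evidence(sim$truth, seed = config$seed + 2)
    calls <- genotype_inversions_all(ev)
    defs <- do.call(rbind, lapply(config$planted_inversions, function(v)
      inversion_defs(v$name, v$chrom, v$start, min(v$start + 1e3, v$end),
                     max(v$start, v$end - 1e3), v$end)))
    inv <- associate(calls, defs, blocks, sim$meta)
  }

  og <- simulate_outgroups(sim$truth, config$outgroup_divergence,
                           seed = config$seed + 3)
  polar <- polarize(filt$table$sites$ref, filt$table$sites$alt, og,
                    weights = config$outgroup_weights)

  alleles <- haploidize(filt$table)
  keep <- !sim$meta$excluded_from_popgen
  windows <- do.call(rbind, lapply(sim$meta$population[keep] |> unique(), function(p) {
    cols <- sim$meta$line_id[keep & sim$meta$population == p]
    w <- window_stats(alleles[, cols, drop = FALSE], filt$table$sites,
                      config$chrom_lengths,
                      outgroup_consensus = polar$ancestral)
    w$population <- p
    w
  }))
  fst <- hudson_fst(alleles, sim$meta)
  sfs <- build_sfs(alleles, filt$table$sites, polar, sim$meta)

  res <- list(sim = sim, blocks = blocks, block_summary = block_summary,
              filtered = filt$table, filter_report = filt$report,
              deep_calls = deep, validation = validation, ibd = ibd,
              inversions = inv, polar = polar, alleles = alleles,
              windows = windows, fst = fst, sfs = sfs)
  if (!is.null(outdir)) res$manifest <- write_run_outputs(res, outdir)
  res
}

write_run_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- function(f) file.path(outdir, f)
  table_to_vcf(res$filtered, p("filtered.vcf")); paths <- c(paths, p("filtered.vcf"))
  write_line_meta(res$sim$meta, p("line_meta.tsv")); paths <- c(paths, p("line_meta.tsv"))
  for (l in names(res$blocks)) {
    f <- p(sprintf("hetblocks_%s.bed", l))
    if (nrow(res$blocks[[l]])) { write_bed(res$blocks[[l]], f); paths <- c(paths, f) }
  }
  utils::write.table(res$windows, p("window_stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$sfs, p("sfs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(res$fst), p("fst.tsv"), sep = "\t", quote = FALSE)
  write_ibd(res$ibd, p("ibd.tsv"))
  paths <- c(paths, p("window_stats.tsv"), p("sfs.tsv"), p("fst.tsv"), p("ibd.tsv"))
  if (!is.null(res$inversions)) {
    utils::write.table(res$inversions$per_inversion, p("inversion_assoc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p("inversion_assoc.tsv"))
  }
  data.frame(path = paths,
             md5 = vapply(paths, function(f) unname(tools::md5sum(f)), character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
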