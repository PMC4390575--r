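#!/usr/bin/env Rscript
# Stage 1: generate the synthetic cohort and write its on-disk artifacts
# (VCF, line metadata, ground-truth BEDs). Everything downstream consumes
# these via the package API; the files document what a real run would read.

source("analysis/00_config.R")

sim <- demo_cohort()
cat(sprintf("cohort: %d sites x %d lines across %d chromosomes\n",
            nrow(sim$table$sites), length(sim$table$lines),
            length(unique(sim$table$sites$chrom))))
cat(sprintf("  SNPs %d, indels %d; flagged sites %.1f%%\n",
            sum(sim$table$sites$vtype == "snp"),
            sum(sim$table$sites$vtype == "indel"),
            100 * mean(sim$table$sites$recal_flag)))

dir.create(res_path("cohort"), showWarnings = FALSE)
table_to_vcf(sim$table, res_path("cohort", "cohort.vcf"))
write_line_meta(sim$meta, res_path("cohort", "line_meta.tsv"))
for (l in names(sim$truth$planted_blocks)) {
  b <- sim$truth$planted_blocks[[l]]
  if (nrow(b)) write_bed(b, res_path("cohort", sprintf("truth_blocks_%s.bed", l)))
}
write.table(sim$truth$inversion_genotypes,
            res_path("cohort", "truth_inversions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

n_carriers <- sum(vapply(sim$truth$planted_blocks, nrow, integer(1)) > 0)
cat(sprintf("  %d of %d lines carry planted het blocks (het inversions)\n",
            n_carriers, length(sim$table$lines)))
cat("wrote", res_path("cohort"), "\n")
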