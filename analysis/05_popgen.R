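#!/usr/bin/env Rscript
# Stage 5: population-genetic summaries on the filtered, haploidized,
# polarized calls — windowed diversity, Hudson's F_ST, the unfolded SFS,
# LD decay and private high-frequency derived alleles.

source("analysis/00_config.R")

sim <- demo_cohort()
blocks <- call_het_blocks_all(sim$table)
filt <- filter_genotypes(sim$table, blocks, filter_policy())
cfg <- demo_config()

og <- simulate_outgroups(sim$truth, cfg$outgroup_divergence, seed = cfg$seed + 3)
polar <- polarize(filt$table$sites$ref, filt$table$sites$alt, og,
                  weights = cfg$outgroup_weights)
cat(sprintf("polarization: %.1f%% of sites polarized at the 0.70 rule\n",
            100 * mean(polar$polarized)))

alleles <- haploidize(filt$table)
keep <- !sim$meta$excluded_from_popgen

win_all <- do.call(rbind, lapply(unique(sim$meta$population[keep]), function(p) {
  ids <- sim$meta$line_id[keep & sim$meta$population == p]
  w <- window_stats(alleles[, ids, drop = FALSE], filt$table$sites,
                    cfg$chrom_lengths, outgroup_consensus = polar$ancestral)
  w$population <- p
  w
}))
med_pi <- tapply(win_all$pi, win_all$population, stats::median, na.rm = TRUE)
cat("median per-window pi by population:\n")
print(round(med_pi, 5))

fst <- hudson_fst(alleles, sim$meta)
auto <- filt$table$sites$chrom != "X"
fst_auto <- hudson_fst(alleles, sim$meta, site_sel = auto)
fst_x <- hudson_fst(alleles, sim$meta, site_sel = !auto)
cat("genome-wide Hudson F_ST:\n")
print(round(fst, 3))

sfs <- build_sfs(alleles, filt$table$sites, polar, sim$meta)
priv <- private_high_freq(alleles, filt$table$sites, polar, sim$meta)
cat(sprintf("private high-frequency derived alleles (>=20%%): %d sites\n",
            nrow(priv)))
print(table(priv$population))
ld <- ld_decay(alleles, filt$table$sites, max_dist = 1000, seed = cfg$seed)
tests <- diversity_tests(win_all)
cat(sprintf("pi ANOVA across populations: F = %.1f\n",
            tests$anova[[1]][["F value"]][1]))

dir.create(res_path("popgen"), showWarnings = FALSE)
write.table(win_all, res_path("popgen", "window_stats.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(as.data.frame(fst), res_path("popgen", "fst_genomewide.tsv"),
            sep = "\t", quote = FALSE)
write.table(as.data.frame(fst_auto), res_path("popgen", "fst_autosome.tsv"),
            sep = "\t", quote = FALSE)
write.table(as.data.frame(fst_x), res_path("popgen", "fst_x.tsv"),
            sep = "\t", quote = FALSE)
write.table(sfs, res_path("popgen", "sfs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(priv, res_path("popgen", "private_alleles.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ld, res_path("popgen", "ld_decay.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", res_path("popgen"), "\n")
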