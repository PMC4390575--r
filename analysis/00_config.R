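# Shared settings for the analysis scripts: one deterministic demo cohort
# with the panel's structure at desk scale — five populations, inbred
# lines, two planted inversions driving het blocks, one line excluded
# from population genetics for suspect provenance.

library(inbredvar)

RESULTS_DIR <- "results/analysis"
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

demo_config <- function(seed = 2024) {
  sim_config(
    seed = seed,
    populations = data.frame(label = c("B", "I", "N", "T", "Z"),
                             n_lines = c(4, 4, 4, 4, 6),
                             F = c(0.10, 0.10, 0.10, 0.10, 0.05)),
    chrom_lengths = c(`2L` = 1.5e6, `2R` = 1.5e6, X = 1e6, `4` = 1e5),
    planted_inversions = list(
      list(name = "In(2L)d", chrom = "2L", start = 3e5, end = 1.2e6,
           het_freq = c(B = 0.3, I = 0.2, N = 0.2, T = 0.3, Z = 0.5),
           hom_freq = 0.1),
      list(name = "In(2R)d", chrom = "2R", start = 4e5, end = 1.0e6,
           het_freq = c(B = 0.2, I = 0.2, N = 0.1, T = 0.2, Z = 0.4),
           hom_freq = 0.05)))
}

demo_inversion_defs <- function() {
  inversion_defs(c("In(2L)d", "In(2R)d"), c("2L", "2R"),
                 bp1_start = c(3e5, 4e5), bp1_end = c(3.01e5, 4.01e5),
                 bp2_start = c(1.19e6, 0.99e6), bp2_end = c(1.2e6, 1.0e6))
}

# the cohort every script operates on; the last Z line plays the role of a
# suspect-provenance line kept in the panel but excluded from popgen
demo_cohort <- function(seed = 2024) {
  sim <- simulate_cohort(demo_config(seed))
  sim$meta$excluded_from_popgen[nrow(sim$meta)] <- TRUE
  sim
}

res_path <- function(...) file.path(RESULTS_DIR, ...)
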