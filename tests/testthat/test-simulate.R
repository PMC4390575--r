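small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed,
             populations = data.frame(label = c("A", "B"), n_lines = c(10, 10),
                                      F = c(0, 0)),
             chrom_lengths = c(c1 = 1e6),
             missing_rate = 0, error_het_rate = 0, het_rate_outside = 0,
             indel_fraction = 0, ...)
}

test_that("simulation is bit-identical under the same seed", {
  s1 <- simulate_cohort(small_cfg(seed = 11))
  s2 <- simulate_cohort(small_cfg(seed = 11))
  expect_identical(s1$table$gt, s2$table$gt)
  expect_identical(s1$table$gq, s2$table$gq)
  expect_identical(s1$truth$pop_freq, s2$truth$pop_freq)
  s3 <- simulate_cohort(small_cfg(seed = 12))
  expect_false(identical(s1$table$gt, s3$table$gt))
})

test_that("F = 0 populations show no differentiation beyond sampling noise", {
  sim <- simulate_cohort(small_cfg(seed = 3))
  al <- haploidize(sim$table)
  f <- hudson_fst(al, sim$meta)["A", "B"]
  expect_lt(abs(f), 0.02)
})

test_that("planted blocks exist exactly for het inversion carriers", {
  cfg <- sim_config(seed = 5,
                    populations = data.frame(label = "P", n_lines = 8, F = 0.05),
                    chrom_lengths = c(c1 = 1e6),
                    planted_inversions = list(list(name = "inv1", chrom = "c1",
                                                   start = 2e5, end = 8e5,
                                                   het_freq = 0.5, hom_freq = 0.1)))
  sim <- simulate_cohort(cfg)
  ig <- sim$truth$inversion_genotypes
  het_lines <- ig$line_id[ig$genotype == "het"]
  has_block <- vapply(sim$truth$planted_blocks, nrow, integer(1)) > 0
  expect_setequal(names(has_block)[has_block], het_lines)
})

test_that("realized population frequencies track truth frequencies", {
  # correlation is capped by binomial sampling noise sqrt(var(p) /
  # (var(p) + E[p(1-p)]/n)); under the 1/p frequency density that cap is
  # ~0.97 at n = 20 and clears 0.99 only near n = 100
  run_cor <- function(n_lines, seed) {
    cfg <- sim_config(seed = seed,
                      populations = data.frame(label = "P", n_lines = n_lines,
                                               F = 0.05),
                      chrom_lengths = c(c1 = 1e6), missing_rate = 0,
                      error_het_rate = 0, het_rate_outside = 0,
                      indel_fraction = 0)
    sim <- simulate_cohort(cfg)
    stats::cor(rowMeans(haploidize(sim$table), na.rm = TRUE),
               sim$truth$pop_freq[, "P"])
  }
  expect_gt(run_cor(20, seed = 9), 0.95)
  expect_gt(run_cor(100, seed = 10), 0.99)
})

test_that("het rate outside blocks matches its generative rate", {
  cfg <- sim_config(seed = 21,
                    populations = data.frame(label = "P", n_lines = 10, F = 0),
                    chrom_lengths = c(c1 = 2e6), missing_rate = 0,
                    het_rate_outside = 0.004, error_het_rate = 0.006,
                    indel_fraction = 0)
  sim <- simulate_cohort(cfg)
  p <- 0.004 + 0.006
  n <- length(sim$table$gt)
  obs <- mean(sim$table$gt == 1L)
  expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("read counts reflect the true genotype", {
  cfg <- small_cfg(seed = 2, het_rate_in_block = 0.5)
  cfg$het_rate_outside <- 0.02          # ensure some true hets exist
  sim <- simulate_cohort(cfg)
  rc <- simulate_read_counts(sim$table, sim$truth, depth_mean = 50,
                             read_error = 0, seed = 4)
  expect_true(all(rc$alt[sim$truth$true_gt == 0L] == 0))
  expect_true(all(rc$ref[sim$truth$true_gt == 2L] == 0))
  # het alt fraction concentrates on 1/2 at high depth
  rc2 <- simulate_read_counts(sim$table, sim$truth, depth_mean = 1e5,
                              read_error = 0, seed = 4)
  hets <- which(sim$truth$true_gt == 1L)[1:5]
  if (length(hets)) {
    frac <- rc2$alt[hets] / (rc2$alt[hets] + rc2$ref[hets])
    expect_true(all(abs(frac - 0.5) < 0.01))
  }
  rc3 <- simulate_read_counts(sim$table, sim$truth, depth_mean = 50,
                              read_error = 0, seed = 4)
  expect_identical(rc$alt, rc3$alt)
})

test_that("inversion evidence separates the three carrier states", {
  cfg <- sim_config(seed = 5,
                    populations = data.frame(label = "P", n_lines = 20, F = 0.05),
                    chrom_lengths = c(c1 = 2e5), snp_density = 1 / 1000,
                    planted_inversions = list(list(name = "inv1", chrom = "c1",
                                                   start = 1e4, end = 19e4,
                                                   het_freq = 0.4, hom_freq = 0.2)))
  sim <- simulate_cohort(cfg)
  ev <- simulate_inversion_evidence(sim$truth, mean_support = 30, seed = 6)
  g <- sim$truth$inversion_genotypes$genotype
  expect_true(all(ev$inv_reads[g == "absent"] == 0))
  expect_true(all(ev$ref_bridge_reads[g == "hom"] == 0))
  expect_true(all(ev$inv_reads[g == "het"] > 0 | ev$ref_bridge_reads[g == "het"] > 0))
  ev2 <- simulate_inversion_evidence(sim$truth, mean_support = 30, seed = 6)
  expect_identical(ev, ev2)
})

test_that("outgroup divergence behaves at its extremes and in between", {
  sim <- simulate_cohort(small_cfg(seed = 8))
  anc <- sim$truth$ancestral
  og0 <- simulate_outgroups(sim$truth, c(o = 0), seed = 1)
  expect_true(all(og0[, 1] == anc))
  og1 <- simulate_outgroups(sim$truth, c(o = 1), seed = 1)
  expect_true(all(og1[, 1] != anc))
  og <- simulate_outgroups(sim$truth, c(o = 0.05), seed = 1)
  expect_lt(abs(mean(og[, 1] != anc) - 0.05), 0.01)
})
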