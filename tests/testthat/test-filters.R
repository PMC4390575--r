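# The shared filter_fixture() (helper-fixtures.R) plants rule violations:
# in-block het below GQ 60, het outside any block, hom on a flagged site
# below GQ 60, plus SNPs at distances 1/5/6 of a same-line indel.

test_that("class rules mask exactly the planted violations", {
  fx <- filter_fixture()
  res <- apply_filters(fx$table, fx$blocks)
  expect_equal(res$report$n_masked, 3)
  key <- paste(res$table$sites$pos, sep = "_")
  gt_of <- function(pos, line) unname(res$table$gt[match(pos, res$table$sites$pos),
                                                   match(line, res$table$lines)])
  expect_equal(gt_of(1000, "L01"), 1L)              # in-block het, GQ 80 kept
  expect_true(is.na(gt_of(1500, "L01")))            # in-block het, GQ 40 masked
  expect_true(is.na(gt_of(6000, "L01")))            # het outside block masked
  expect_true(is.na(gt_of(2000, "L02")))            # flagged hom GQ 45 masked
  expect_equal(gt_of(2500, "L02"), 2L)              # unflagged hom GQ 45 kept
  expect_equal(gt_of(3000, "L01"), 0L)
})

test_that("filtering is idempotent and reports variant-site attrition", {
  fx <- filter_fixture()
  r1 <- apply_filters(fx$table, fx$blocks)
  r2 <- apply_filters(r1$table, fx$blocks)
  expect_identical(r1$table$gt, r2$table$gt)
  expect_equal(r2$report$n_masked, 0)
  expect_lte(r1$report$variant_sites_after, r1$report$variant_sites_before)
  # a site whose only non-ref call was masked is flagged invariant, not dropped
  expect_equal(nrow(r1$table$sites), nrow(fx$table$sites))
  inv <- r1$table$sites$invariant_after_filter
  expect_true(inv[r1$table$sites$pos == 6000])
})

test_that("SNPs near a same-line indel are masked at the inclusive boundary", {
  fx <- filter_fixture()
  res <- mask_snps_near_indels(fx$table, distance_nt = 5)
  gt_of <- function(pos, line) unname(res$table$gt[match(pos, res$table$sites$pos),
                                                   match(line, res$table$lines)])
  # indel at 9001 carried by L01 only
  expect_true(is.na(gt_of(8996, "L01")))   # distance 5 -> masked
  expect_true(is.na(gt_of(9000, "L01")))   # distance 1 -> masked
  expect_equal(gt_of(8996, "L02"), 0L)     # other line unaffected
  expect_equal(gt_of(9000, "L02"), 0L)
  expect_equal(gt_of(9007, "L01"), 0L)     # distance 6 -> kept
  expect_equal(gt_of(8000, "L01"), 0L)     # far away -> kept
})

test_that("indel proximity distances 4, 5, 6 split at the inclusive 5 nt rule", {
  s <- rbind(make_sites("2L", c(996, 1000, 1005, 1006, 1007)),
             make_sites("2L", 1001, ref = "AT", alt = "A", vtype = "indel"))
  gt <- matrix(0L, 6, 1); gq <- matrix(99L, 6, 1)
  gt[6, 1] <- 2L                                     # the indel call
  tab <- genotype_table(s, "L01", gt, gq)
  res <- mask_snps_near_indels(tab, distance_nt = 5)
  gt_of <- function(pos) unname(res$table$gt[match(pos, res$table$sites$pos), 1])
  expect_true(is.na(gt_of(996)))    # distance 5 -> masked
  expect_true(is.na(gt_of(1000)))   # distance 1 -> masked
  expect_true(is.na(gt_of(1005)))   # distance 4 -> masked
  expect_true(is.na(gt_of(1006)))   # distance 5 -> masked
  expect_equal(gt_of(1007), 0L)     # distance 6 -> kept
})

test_that("region masks drop uncallable sites and one line of each IBD pair", {
  s <- make_sites("2L", c(1000, 500000, 900000))
  gt <- matrix(c(0L, 2L, 0L, 2L, 0L, 2L), 3)
  tab <- genotype_table(s, c("lineA", "lineB"), gt, matrix(99L, 3, 2))
  out <- apply_region_masks(tab, list(uncallable = intervals("2L", 0, 2000)))
  expect_equal(nrow(out$sites), 2)
  ibd <- intervals("2L", 0, 1e6, label = "lineA|lineB")
  out2 <- apply_region_masks(tab, list(ibd = ibd))
  expect_true(all(is.na(out2$gt[, "lineB"])))
  expect_true(all(!is.na(out2$gt[, "lineA"])))
  out3 <- apply_region_masks(tab, list())
  expect_identical(out3$gt, tab$gt)
  bad <- intervals("2L", 0, 1e6)
  expect_error(apply_region_masks(tab, list(ibd = bad)), "lineA\\|lineB")
})

test_that("an incomplete rule set is rejected at construction", {
  rules <- data.frame(gt = "het", in_block = "in", recal = "any", min_gq = 60)
  expect_error(filter_policy(snp_rules = rules,
                             drop_het_outside_blocks_snp = FALSE),
               "not total")
})

test_that("post-filter het calls outside blocks are zero on simulated errors", {
  cfg <- sim_config(seed = 13,
                    populations = data.frame(label = "P", n_lines = 8, F = 0.05),
                    chrom_lengths = c(c1 = 5e5), missing_rate = 0,
                    het_rate_outside = 0, error_het_rate = 0.01,
                    indel_fraction = 0)
  sim <- simulate_cohort(cfg)
  blocks <- call_het_blocks_all(sim$table)
  res <- apply_filters(sim$table, blocks)
  out_block_het <- 0
  for (j in seq_along(res$table$lines)) {
    b <- blocks[[res$table$lines[j]]]
    inb <- positions_in_intervals(res$table$sites$chrom, res$table$sites$pos, b)
    out_block_het <- out_block_het +
      sum(!inb & !is.na(res$table$gt[, j]) & res$table$gt[, j] == 1L)
  }
  expect_equal(out_block_het, 0)
})
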