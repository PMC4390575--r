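# Fixtures shared by the unit and acceptance suites.

# 10 variant sites x 2 lines with planted rule violations (plus one indel
# record used by the proximity rule). L01 carries a het block over
# [0, 5000) on 2L. Expected class-rule maskings (hand oracle):
#   pos 1500 L01: in-block het, GQ 40  < 60      -> masked
#   pos 6000 L01: het outside any block          -> masked
#   pos 2000 L02: hom on flagged site, GQ 45 < 60-> masked
# and proximity maskings for the SNPs at distances <= 5 of the L01 indel
# at pos 9001 (8996 and 9000; 9007 at distance 6 is kept).
filter_fixture <- function() {
  s <- rbind(
    make_sites("2L", c(1000, 1500, 6000, 2000, 2500, 3000),
               recal_flag = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)),
    make_sites("2L", c(8000, 8996, 9000, 9007)),
    make_sites("2L", 9001, ref = "AT", alt = "A", vtype = "indel"))
  gt <- matrix(0L, 11, 2)
  gq <- matrix(99L, 11, 2)
  set_call <- function(gt, gq, pos_i, line, g, q) {
    gt[pos_i, line] <- g; gq[pos_i, line] <- q; list(gt = gt, gq = gq)
  }
  x <- set_call(gt, gq, 1, 1, 1L, 80L)
  x <- set_call(x$gt, x$gq, 2, 1, 1L, 40L)
  x <- set_call(x$gt, x$gq, 3, 1, 1L, 99L)
  x <- set_call(x$gt, x$gq, 4, 2, 2L, 45L)
  x <- set_call(x$gt, x$gq, 5, 2, 2L, 45L)
  x <- set_call(x$gt, x$gq, 11, 1, 2L, 99L)       # L01 indel at pos 9001
  tab <- genotype_table(s, c("L01", "L02"), x$gt, x$gq)
  blocks <- list(L01 = intervals("2L", 0, 5000), L02 = empty_intervals())
  list(table = tab, blocks = blocks)
}

# copy line A's calls into line B over [start, end) to plant an IBD segment
plant_ibd <- function(sim, line_a, line_b, chrom, start, end) {
  sel <- sim$table$sites$chrom == chrom &
    (sim$table$sites$pos - 1) >= start & (sim$table$sites$pos - 1) < end
  ja <- match(line_a, sim$table$lines); jb <- match(line_b, sim$table$lines)
  sim$table$gt[sel, jb] <- sim$table$gt[sel, ja]
  sim
}

# clean unstructured single-population cohort for calibration checks
neutral_cfg <- function(seed, n_lines = 20, len = 2e6, density = 1 / 200) {
  sim_config(seed = seed,
             populations = data.frame(label = "P", n_lines = n_lines, F = 0),
             chrom_lengths = c(c1 = len), snp_density = density,
             missing_rate = 0, het_rate_outside = 0, error_het_rate = 0,
             indel_fraction = 0)
}
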