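# Reference sequence containing all 64 codons as one CDS (192 nt), framed
# by intergenic flanks. Degeneracy oracle uses seqinr's translation,
# independent of the Biostrings code path inside classify_sites().
all_codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                c("A", "C", "G", "T")), 1, paste, collapse = "")

test_that("codon degeneracy matches an independent all-codon enumeration", {
  cds_seq <- paste(all_codons, collapse = "")
  ref_seq <- list(chr1 = paste0("AAAA", cds_seq, "TTTT"))
  gm <- data.frame(transcript = "t1", chrom = "chr1", feature = "CDS",
                   start = 5, end = 4 + nchar(cds_seq), strand = "+",
                   stringsAsFactors = FALSE)
  oracle_aa <- function(codon) seqinr::translate(strsplit(codon, "")[[1]])
  # one site per codon position, alt = next nucleotide cyclically
  nxt <- c(A = "C", C = "G", G = "T", T = "A")
  pos <- 5:(4 + nchar(cds_seq))
  ref_nt <- strsplit(cds_seq, "")[[1]]
  sites <- make_sites("chr1", pos, ref = ref_nt, alt = unname(nxt[ref_nt]))
  cl <- classify_sites(sites, gm, ref_seq)
  for (i in seq_along(pos)) {
    codon_idx <- (i - 1) %/% 3
    offs <- (i - 1) %% 3 + 1
    codon <- strsplit(all_codons[codon_idx + 1], "")[[1]]
    aa_ref <- oracle_aa(paste(codon, collapse = ""))
    variants <- vapply(c("A", "C", "G", "T"), function(n) {
      cd <- codon; cd[offs] <- n; oracle_aa(paste(cd, collapse = ""))
    }, character(1))
    cd_alt <- codon; cd_alt[offs] <- nxt[[ref_nt[i]]]
    aa_alt <- oracle_aa(paste(cd_alt, collapse = ""))
    want <- if (aa_alt != aa_ref) "nonsynonymous"
      else if (all(variants == aa_ref)) "fourfold"
      else "synonymous_non4fold"
    expect_equal(cl$category[i], want,
                 label = sprintf("codon %s offset %d", all_codons[codon_idx + 1], offs))
  }
})

test_that("canonical codon examples classify as expected", {
  ref_seq <- list(chr1 = "AAAAGGATTTT")       # CDS GGA at 5..7 (Gly)
  gm <- data.frame(transcript = "t1", chrom = "chr1", feature = "CDS",
                   start = 5, end = 7, strand = "+", stringsAsFactors = FALSE)
  s <- make_sites("chr1", 7, ref = "A", alt = "C")   # GGA -> GGC, Gly -> Gly
  expect_equal(classify_sites(s, gm, ref_seq)$category, "fourfold")
  ref_seq2 <- list(chr1 = "AAAAAAATTTT")      # CDS AAA at 5..7 (Lys)
  s2 <- make_sites("chr1", 5, ref = "A", alt = "G")  # AAA -> GAA, Lys -> Glu
  expect_equal(classify_sites(s2, gm, ref_seq2)$category, "nonsynonymous")
  expect_equal(classify_sites(s2, gm, ref_seq2)$impact, "moderate")
})

test_that("reverse-strand CDS positions map through the complement", {
  # genomic TCC at 5..7 on '-' is codon GGA read 3'->5'; third codon
  # position is genomic position 5
  ref_seq <- list(chr1 = "AAAATCCTTTT")
  gm <- data.frame(transcript = "t1", chrom = "chr1", feature = "CDS",
                   start = 5, end = 7, strand = "-", stringsAsFactors = FALSE)
  s <- make_sites("chr1", 5, ref = "T", alt = "G")   # GGA -> GGC on the mRNA
  expect_equal(classify_sites(s, gm, ref_seq)$category, "fourfold")
})

test_that("small introns, UTRs and intergenic sites classify by position", {
  gm <- rbind(
    data.frame(transcript = "t1", chrom = "chr1", feature = "intron",
               start = 100, end = 159, strand = "+"),   # 60 bp: small
    data.frame(transcript = "t1", chrom = "chr1", feature = "intron",
               start = 300, end = 399, strand = "+"),   # 100 bp: not small
    data.frame(transcript = "t1", chrom = "chr1", feature = "UTR",
               start = 500, end = 520, strand = "+"))
  s <- make_sites("chr1", c(130, 103, 350, 510, 900))
  cl <- classify_sites(s, gm, list(chr1 = strrep("A", 1000)))
  expect_equal(cl$category,
               c("small_intron", "intergenic",  # 103 is inside the splice buffer
                 "intergenic", "UTR", "intergenic"))
  expect_equal(cl$neutral, c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("a CDS with length not divisible by 3 is skipped with a warning", {
  gm <- data.frame(transcript = "t1", chrom = "chr1", feature = "CDS",
                   start = 5, end = 8, strand = "+", stringsAsFactors = FALSE)
  s <- make_sites("chr1", 5)
  expect_warning(cl <- classify_sites(s, gm, list(chr1 = strrep("A", 20))),
                 "not divisible by 3")
  expect_equal(cl$category, "intergenic")
})

test_that("polarization follows the weighted vote and the 0.70 rule", {
  og <- matrix(c("A", "A", "A"), 1)
  p <- polarize("A", "G", og)
  expect_equal(p$ancestral, "A")
  expect_equal(p$posterior, 1)
  expect_true(p$polarized)
  expect_equal(p$derived, "G")

  og2 <- matrix(c("A", "A", "G"), 1)
  p2 <- polarize("A", "G", og2)
  expect_equal(p2$posterior, 2 / 3, tolerance = 1e-12)
  expect_false(p2$polarized)
  expect_true(is.na(p2$ancestral))

  og3 <- matrix(c("C", "C", "C"), 1)   # third allele only: uninformative
  p3 <- polarize("A", "G", og3)
  expect_false(p3$polarized)
  expect_true(is.na(p3$posterior))

  # weights can tip the vote past the threshold
  p4 <- polarize("A", "G", og2, weights = c(3, 3, 1))
  expect_true(p4$polarized)
  expect_equal(p4$ancestral, "A")
  expect_equal(p4$posterior, 6 / 7, tolerance = 1e-12)
})

test_that("polarization is accurate against diverged simulated outgroups", {
  cfg <- sim_config(seed = 41,
                    populations = data.frame(label = "P", n_lines = 6, F = 0),
                    chrom_lengths = c(c1 = 1e6), missing_rate = 0,
                    indel_fraction = 0)
  sim <- simulate_cohort(cfg)
  og <- simulate_outgroups(sim$truth, c(a = 0.02, b = 0.02, c = 0.02), seed = 42)
  p <- polarize(sim$table$sites$ref, sim$table$sites$alt, og)
  acc <- mean(p$ancestral[p$polarized] == sim$truth$ancestral[p$polarized])
  expect_gte(acc, 0.99)
})
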