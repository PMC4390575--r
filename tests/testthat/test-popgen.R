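test_that("haploidize maps homozygotes, drops hets, and seeds random policy", {
  tab <- make_table(c(100, 200, 300), matrix(c(0L, 1L, 2L), 3, 1))
  a <- haploidize(tab)
  expect_equal(unname(a[, 1]), c(0L, NA, 1L))
  r1 <- haploidize(tab, policy = "random", seed = 5)
  r2 <- haploidize(tab, policy = "random", seed = 5)
  expect_identical(r1, r2)
  expect_false(is.na(r1[2, 1]))
})

test_that("pi and theta closed forms hold for two haplotypes", {
  # n = 2 copies, one differing site, L = 10
  al <- matrix(c(0L, 1L), 1, 2)
  w <- single_window(al, pos = 5, L = 10)
  expect_equal(w$pi, 0.1)
  expect_equal(w$theta_w, 0.1)            # a_2 = 1
  expect_true(is.na(w$tajima_d) || is.finite(w$tajima_d))
})

test_that("window statistics match the brute-force pairwise oracle", {
  set.seed(91)
  for (rep in 1:30) {
    n <- sample(2:6, 1)
    S <- sample(1:50, 1)
    L <- 1000
    al <- matrix(0L, S, n)
    for (s in seq_len(S)) {
      k <- sample(seq_len(n - 1), 1)
      al[s, sample(n, k)] <- 1L
    }
    pos <- sort(sample(L, S))
    w <- single_window(al, pos, L)
    o <- oracle_diversity(al, L)
    expect_equal(w$pi, o$pi, tolerance = 1e-12)
    expect_equal(w$theta_w, o$theta_w, tolerance = 1e-12)
    expect_equal(w$tajima_d, o$tajima_d, tolerance = 1e-12)
    expect_equal(w$n_segregating, o$S)
  }
})

test_that("the published worked example for Tajima's D reproduces", {
  # n = 6 copies, derived counts {1, 1, 3}, L = 100
  al <- rbind(c(1L, 0L, 0L, 0L, 0L, 0L),
              c(0L, 1L, 0L, 0L, 0L, 0L),
              c(1L, 1L, 1L, 0L, 0L, 0L))
  w <- single_window(al, pos = c(10, 20, 30), L = 100)
  o <- oracle_diversity(al, 100)
  expect_equal(w$tajima_d, o$tajima_d, tolerance = 1e-12)
  expect_equal(w$pi, o$pi, tolerance = 1e-12)
})

test_that("window tiling keeps a flagged terminal partial window", {
  ws <- inbredvar:::window_starts(25000, 10000, 5000)
  expect_equal(ws$starts, c(0, 5000, 10000, 15000))
  expect_false(any(ws$partial))
  ws2 <- inbredvar:::window_starts(23000, 10000, 5000)
  expect_equal(ws2$starts, c(0, 5000, 10000, 15000))
  expect_true(ws2$partial[4])
  expect_false(any(ws2$partial[1:3]))
})

test_that("missing data lowers the per-site sample size in pi", {
  al <- matrix(c(1L, 0L, 0L, NA), 1, 4)      # k=1 of n=3 observed
  w <- single_window(al, pos = 5, L = 10)
  expect_equal(w$pi, (2 * 1 * 2 / (3 * 2)) / 10)
})

test_that("Hudson F_ST hits its fixed points and label symmetry", {
  # identical sample frequencies in both populations: the unbiased
  # estimator is 0 up to the O(1/n) finite-sample correction (mirrored
  # samples are not independent draws from a common population)
  set.seed(7)
  n <- 50
  meta_big <- line_meta(sprintf("l%03d", 1:(2 * n)), rep(c("A", "B"), each = n))
  k <- pmin(pmax(rbinom(200, n, 0.3), 1), n - 1)
  one_pop <- t(vapply(k, function(kk) c(rep(1L, kk), rep(0L, n - kk)),
                      integer(n)))
  al <- cbind(one_pop, one_pop)
  colnames(al) <- meta_big$line_id
  expect_lte(abs(hudson_fst(al, meta_big)["A", "B"]), 1 / (n - 1) + 1e-12)
  # fixed difference -> 1
  meta <- line_meta(sprintf("l%02d", 1:10), rep(c("A", "B"), each = 5))
  al2 <- cbind(matrix(1L, 50, 5), matrix(0L, 50, 5))
  colnames(al2) <- meta$line_id
  expect_equal(hudson_fst(al2, meta)["A", "B"], 1)
  # allele-label swap leaves F_ST unchanged
  set.seed(8)
  al3 <- matrix(rbinom(500, 1, 0.4), 100, 10,
                dimnames = list(NULL, meta$line_id))
  f1 <- hudson_fst(al3, meta)["A", "B"]
  f2 <- hudson_fst(1L - al3, meta)["A", "B"]
  expect_equal(f1, f2, tolerance = 1e-12)
  # symmetric matrix with zero diagonal
  m <- hudson_fst(al3, meta)
  expect_equal(m, t(m))
  expect_equal(diag(m), c(A = 0, B = 0))
})

test_that("SFS counts, totals, and balancing behave", {
  # 5 singleton sites, n = 10 -> spectrum [5, 0, ..., 0]
  al <- matrix(0L, 5, 10)
  for (i in 1:5) al[i, i] <- 1L
  meta <- line_meta(sprintf("l%02d", 1:10), rep("P", 10))
  colnames(al) <- meta$line_id
  sites <- make_sites("2L", seq(100, 500, by = 100))
  polar <- data.frame(ancestral = sites$ref, derived = sites$alt,
                      posterior = 1, polarized = TRUE)
  sfs <- build_sfs(al, sites, polar, meta)
  expect_equal(sfs$count, c(5, rep(0, 8)))
  expect_equal(sum(sfs$count), 5)
  # balancing subsamples each class to the smallest class size
  classes <- c("x", "x", "x", "y", "y")
  sfs_b <- build_sfs(al, sites, polar, meta, classes = classes, balance = TRUE,
                     seed = 3)
  tots <- tapply(sfs_b$count, sfs_b$class, sum)
  expect_equal(as.vector(tots), c(2, 2))
  # balancing never increases any class count
  sfs_u <- build_sfs(al, sites, polar, meta, classes = classes)
  for (cl in c("x", "y"))
    expect_lte(sum(sfs_b$count[sfs_b$class == cl]),
               sum(sfs_u$count[sfs_u$class == cl]))
})

test_that("derived counts fold through ref-ancestral polarity", {
  # alt is ancestral at one site: derived copies = ref copies
  al <- matrix(c(1L, 1L, 1L, 0L), 1, 4)
  meta <- line_meta(sprintf("l%d", 1:4), rep("P", 4))
  colnames(al) <- meta$line_id
  sites <- make_sites("2L", 100)
  polar <- data.frame(ancestral = sites$alt, derived = sites$ref,
                      posterior = 1, polarized = TRUE)
  sfs <- build_sfs(al, sites, polar, meta)
  expect_equal(sfs$count[sfs$k == 1], 1)    # one derived (ref) copy
})

test_that("LD r-squared hits coupling, independence and determinism", {
  # two perfectly coupled sites
  al <- rbind(rep(c(0L, 1L), 10), rep(c(0L, 1L), 10))
  sites <- make_sites("2L", c(100, 200))
  ld <- ld_decay(al, sites, max_dist = 500)
  expect_equal(sum(ld$n_pairs), 1)
  expect_equal(ld$mean_r2[!is.na(ld$mean_r2)], 1)
  # independent sites: mean r2 near 1/n
  set.seed(11)
  n <- 400
  al2 <- matrix(rbinom(2 * n, 1, 0.5), 2, n)
  ld2 <- ld_decay(al2, sites, max_dist = 500)
  expect_lt(abs(ld2$mean_r2[!is.na(ld2$mean_r2)] - 1 / n), 3 * sqrt(2) / n)
  # site order swap and reruns leave binned means unchanged
  ld3 <- ld_decay(al2[2:1, ], make_sites("2L", c(200, 100))[2:1, ],
                  max_dist = 500)
  expect_equal(ld2$mean_r2, ld3$mean_r2)
  expect_identical(ld2, ld_decay(al2, sites, max_dist = 500))
  # excluded chromosome contributes no pairs
  ld4 <- ld_decay(al, make_sites("4", c(100, 200)), max_dist = 500,
                  exclude_chroms = "4")
  expect_equal(sum(ld4$n_pairs), 0)
})

test_that("private high-frequency alleles respect privacy and missingness", {
  meta <- line_meta(sprintf("l%02d", 1:8), rep(c("Z", "B"), each = 4))
  sites <- make_sites("2L", c(100, 200, 300))
  polar <- data.frame(ancestral = sites$ref, derived = sites$alt,
                      posterior = c(1, 1, 1), polarized = TRUE)
  al <- rbind(c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L),   # 50% in Z, 0 in B -> private
              c(1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L),   # segregates in both
              c(1L, 1L, NA, NA, 0L, 0L, 0L, 0L))   # 50% missing in Z
  colnames(al) <- meta$line_id
  priv <- private_high_freq(al, sites, polar, meta)
  expect_equal(nrow(priv), 1)
  expect_equal(priv$population, "Z")
  expect_equal(priv$pos, 100)
  expect_equal(priv$freq, 0.5)
  # below the frequency floor
  al2 <- al; al2[1, 2] <- 0L                        # 25% in Z
  priv2 <- private_high_freq(al2, sites, polar, meta, min_freq = 0.3)
  expect_equal(nrow(priv2), 0)
  # posterior gate
  polar3 <- polar; polar3$posterior <- 0.6; polar3$polarized <- FALSE
  expect_equal(nrow(private_high_freq(al, sites, polar3, meta)), 0)
})

test_that("diversity comparison tests run over window data", {
  set.seed(5)
  win <- data.frame(
    population = rep(c("A", "B"), each = 40),
    chrom = rep(c("2L", "X"), 40),
    pi = c(rnorm(40, 0.005, 0.001), rnorm(40, 0.008, 0.001)))
  res <- diversity_tests(win)
  expect_true(res$anova[[1]][["Pr(>F)"]][1] < 0.01)
  expect_true(all(is.finite(res$wilcoxon_x_vs_auto)))
})
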