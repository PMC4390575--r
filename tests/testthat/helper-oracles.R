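# Shared fixtures and independent brute-force oracles.
# Oracles are deliberately naive (per-bp bitmaps, explicit pairwise sums,
# exhaustive path enumeration) and never call the implementation paths they
# check.

make_sites <- function(chrom, pos, ref = "A", alt = "G", vtype = "snp",
                       recal_flag = FALSE) {
  n <- length(pos)
  data.frame(chrom = rep_len(chrom, n), pos = pos,
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             vtype = rep_len(vtype, n), recal_flag = rep_len(recal_flag, n),
             stringsAsFactors = FALSE)
}

make_table <- function(pos, gt, gq = NULL, chrom = "2L", vtype = "snp",
                       recal_flag = FALSE, ref = "A", alt = "G") {
  gt <- as.matrix(gt)
  if (is.null(gq)) { gq <- gt; gq[] <- 99L; gq[is.na(gt)] <- NA_integer_ }
  lines <- sprintf("L%02d", seq_len(ncol(gt)))
  genotype_table(make_sites(chrom, pos, ref, alt, vtype, recal_flag),
                 lines, gt, as.matrix(gq))
}

# per-bp bitmap interval oracle (chromosome <= 10 kb)
bitmap_covered <- function(iv, len = 1e4) {
  out <- 0
  for (ch in unique(iv$chrom)) {
    bits <- logical(len)
    sel <- iv[iv$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(sel)))
      bits[(sel$start[i] + 1):sel$end[i]] <- TRUE
    out <- out + sum(bits)
  }
  out
}

bitmap_intersect <- function(a, b, len = 1e4) {
  out <- 0
  for (ch in union(unique(a$chrom), unique(b$chrom))) {
    ba <- logical(len); bb <- logical(len)
    sa <- a[a$chrom == ch, , drop = FALSE]
    sb <- b[b$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(sa))) ba[(sa$start[i] + 1):sa$end[i]] <- TRUE
    for (i in seq_len(nrow(sb))) bb[(sb$start[i] + 1):sb$end[i]] <- TRUE
    out <- out + sum(ba & bb)
  }
  out
}

random_intervals <- function(n, len = 1e4, chroms = "c1") {
  s <- sample.int(len - 2, n, replace = TRUE) - 1
  w <- sample.int(500, n, replace = TRUE)
  intervals(sample(chroms, n, replace = TRUE), s, pmin(s + w, len))
}

# textbook diversity oracle on a complete 0/1 haplotype matrix (no missing)
oracle_diversity <- function(alleles, L) {
  n <- ncol(alleles)
  pairs <- utils::combn(n, 2)
  d <- vapply(seq_len(ncol(pairs)), function(k)
    sum(alleles[, pairs[1, k]] != alleles[, pairs[2, k]]), numeric(1))
  pi_sum <- mean(d)
  k <- rowSums(alleles)
  S <- sum(k > 0 & k < n)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  denom <- sqrt(e1 * S + e2 * S * (S - 1))
  D <- if (S == 0 || denom == 0) NA_real_ else (pi_sum - S / a1) / denom
  list(pi = pi_sum / L, theta_w = S / (a1 * L), tajima_d = D, S = S)
}

# exhaustive best segmentation over paths with at most `max_switches`
# state switches (block/inbred), by direct enumeration of switch points
oracle_best_path <- function(obs, p_block, p_inbred, switch_cost,
                             max_switches = 2) {
  n <- length(obs)
  score <- function(st) inbredvar:::segmentation_path_score(obs, st, p_block,
                                                           p_inbred, switch_cost)
  best <- NULL; best_s <- -Inf
  for (start_block in c(FALSE, TRUE)) {
    st0 <- rep(start_block, n)
    cand <- list(st0)
    # one switch
    for (i in 2:n) {
      st <- st0; st[i:n] <- !start_block
      cand[[length(cand) + 1]] <- st
      if (max_switches >= 2 && i < n) {
        for (j in (i + 1):n) {
          st2 <- st; st2[j:n] <- start_block
          cand[[length(cand) + 1]] <- st2
        }
      }
    }
    for (st in cand) {
      s <- score(st)
      if (s > best_s) { best_s <- s; best <- st }
    }
  }
  list(path = best, score = best_s)
}

# window stats for one population on a single chromosome spanning [0, L)
single_window <- function(alleles, pos, L, chrom = "c1", ...) {
  sites <- make_sites(chrom, pos)
  window_stats(alleles, sites, stats::setNames(L, chrom),
               window_bp = L, stride_bp = L, ...)
}
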