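#' Haploidize an inbred-line genotype table
#'
#' Inbred lines contribute one allele copy each to population statistics:
#' homozygous calls map to their allele (0 = reference, 1 = alternate),
#' heterozygous calls become missing under the default policy (or a random
#' allele under `policy = "random"`), and missing calls stay missing.
#'
#' @param table genotype_table (filtered).
#' @param policy `"missing"` (default) or `"random"`.
#' @param seed RNG seed for `policy = "random"`.
#' @return integer matrix sites x lines with values 0/1/NA.
#' @export
haploidize <- function(table, policy = c("missing", "random"), seed = 1) {
  policy <- match.arg(policy)
  gt <- table$gt
  out <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  out[!is.na(gt) & gt == 0L] <- 0L
  out[!is.na(gt) & gt == 2L] <- 1L
  het <- !is.na(gt) & gt == 1L
  if (policy == "random" && any(het)) {
    set.seed(seed)
    out[het] <- sample(0:1, sum(het), replace = TRUE)
  }
  out
}

#' Tajima's D constants for sample size n
#' @param n number of allele copies (>= 2).
#' @return named list `a1, a2, b1, b2, c1, c2, e1, e2`.
#' @export
tajima_constants <- function(n) {
  if (n < 2) stop("n must be >= 2")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D from total pairwise diversity and segregating sites
#' @param pi_sum sum over sites of per-site pairwise diversity (not
#'   per-bp).
#' @param S number of segregating sites.
#' @param n sample size (allele copies).
#' @return Tajima's D, or `NA` when `S = 0`.
#' @export
tajima_d <- function(pi_sum, S, n) {
  if (S == 0 || n < 2) return(NA_real_)
  k <- tajima_constants(n)
  denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  if (denom == 0) return(NA_real_)      # n = 2 has zero variance constants
  (pi_sum - S / k$a1) / denom
}

window_starts <- function(len, window_bp, stride_bp) {
  full <- seq(0, max(0, len - window_bp), by = stride_bp)
  partial <- logical(length(full))
  last_end <- full[length(full)] + window_bp
  if (last_end < len) {
    full <- c(full, full[length(full)] + stride_bp)
    partial <- c(partial, TRUE)
  }
  list(starts = full, partial = partial)
}

#' Sliding-window diversity statistics
#'
#' Tiles each chromosome with sliding windows (default 10 kb / 5 kb
#' stride; a small chromosome named by `small_chrom` uses 500 bp / 250 bp)
#' and computes per window: pi (sum of per-site pairwise diversity
#' `2k(n-k)/(n(n-1))` with per-site sample size, per callable bp),
#' Watterson's theta (`S / (a_n L)` with the window's modal sample size),
#' Tajima's D, and polymorphism/divergence where `outgroup_consensus` is
#' supplied (divergence = fraction of window sites whose outgroup consensus
#' differs from the within-sample major allele, per callable bp). Terminal
#' partial windows are kept and flagged.
#'
#' @param alleles haploidized matrix from [haploidize()] (possibly
#'   column-subset to one population).
#' @param sites site data frame aligned to `alleles` rows.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param callable optional interval set of callable regions; `NULL` treats
#'   whole chromosomes as callable.
#' @param outgroup_consensus optional per-site character vector of the
#'   outgroup/ancestral consensus allele.
#' @param window_bp,stride_bp window size and stride (defaults 10 kb/5 kb).
#' @param small_chrom chromosome name given the small windows (default
#'   `"4"`), with `small_window_bp`/`small_stride_bp` (500/250 bp).
#' @param small_window_bp,small_stride_bp see above.
#' @return data frame of per-window statistics.
#' @export
window_stats <- function(alleles, sites, chrom_lengths, callable = NULL,
                         outgroup_consensus = NULL,
                         window_bp = 1e4, stride_bp = 5e3,
                         small_chrom = "4", small_window_bp = 500,
                         small_stride_bp = 250) {
  out <- list()
  k_alt <- rowSums(alleles == 1L, na.rm = TRUE)
  n_obs <- rowSums(!is.na(alleles))
  major <- ifelse(n_obs == 0, NA_character_,
                  ifelse(k_alt * 2 >= n_obs, sites$alt, sites$ref))
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    wb <- if (ch == small_chrom) small_window_bp else window_bp
    sb <- if (ch == small_chrom) small_stride_bp else stride_bp
    ws <- window_starts(len, wb, sb)
    ch_idx <- which(sites$chrom == ch)
    pos0 <- sites$pos[ch_idx] - 1
    for (wi in seq_along(ws$starts)) {
      w0 <- ws$starts[wi]; w1 <- min(w0 + wb, len)
      L <- if (is.null(callable)) w1 - w0 else
        intersect_bp(intervals(ch, w0, w1), callable)
      if (L == 0) {
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = w0, end = w1, partial = ws$partial[wi],
          n_callable = 0, n_segregating = NA, n_modal = NA,
          pi = NA_real_, theta_w = NA_real_, tajima_d = NA_real_,
          divergence = NA_real_, poly_over_div = NA_real_)
        next
      }
      idx <- ch_idx[pos0 >= w0 & pos0 < w1]
      k <- k_alt[idx]; nn <- n_obs[idx]
      seg <- which(nn >= 2 & k > 0 & k < nn)
      S <- length(seg)
      pi_sum <- if (S) sum(2 * k[seg] * (nn[seg] - k[seg]) /
                             (nn[seg] * (nn[seg] - 1))) else 0
      n_modal <- if (S) as.integer(names(sort(table(nn[seg]), decreasing = TRUE))[1])
        else if (length(idx)) max(nn[idx], 2) else NA_integer_
      theta <- if (!is.na(n_modal) && n_modal >= 2)
        S / (tajima_constants(n_modal)$a1 * L) else NA_real_
      D <- if (S && !is.na(n_modal)) tajima_d(pi_sum, S, n_modal) else NA_real_
      div <- NA_real_; pod <- NA_real_
      if (!is.null(outgroup_consensus) && length(idx)) {
        comp <- idx[!is.na(outgroup_consensus[idx]) & !is.na(major[idx])]
        if (length(comp)) {
          div <- sum(outgroup_consensus[comp] != major[comp]) / L
          pod <- if (div > 0) (pi_sum / L) / div else NA_real_
        }
      }
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = w0, end = w1, partial = ws$partial[wi],
        n_callable = L, n_segregating = S, n_modal = n_modal,
        pi = pi_sum / L, theta_w = theta, tajima_d = D,
        divergence = div, poly_over_div = pod)
    }
  }
  do.call(rbind, out)
}

#' Unfolded site frequency spectrum
#'
#' Counts polarized segregating sites by derived-allele copy number,
#' stratified by population, chromosome partition (X vs autosome) and site
#' class. Uses complete-case sites at the stratum's modal sample size so
#' that counts stay integers and per-stratum totals equal the polarized
#' segregating sites retained. Optional balancing subsamples every class
#' (within population x partition) to the smallest class size without
#' replacement, reproducibly under `seed`.
#'
#' @param alleles haploidized matrix.
#' @param sites site data frame.
#' @param polar data frame from [polarize()] aligned to sites.
#' @param meta [line_meta()] (popgen-excluded lines are dropped).
#' @param classes optional per-site class labels (e.g.
#'   `classify_sites()$category`); `NULL` puts everything in class
#'   `"all"`.
#' @param x_chrom chromosome name treated as the X partition.
#' @param balance subsample classes to the smallest class (default FALSE).
#' @param seed RNG seed for balancing.
#' @return data frame: `population`, `partition`, `class`, `k`, `count`,
#'   plus per-stratum `n` (sample size).
#' @export
build_sfs <- function(alleles, sites, polar, meta, classes = NULL,
                      x_chrom = "X", balance = FALSE, seed = 1) {
  meta <- meta[!meta$excluded_from_popgen, ]
  if (is.null(classes)) classes <- rep("all", nrow(sites))
  partition <- ifelse(sites$chrom == x_chrom, "X", "autosome")
  out <- list()
  for (pop in unique(meta$population)) {
    cols <- match(meta$line_id[meta$population == pop], colnames(alleles))
    cols <- cols[!is.na(cols)]
    if (length(cols) < 2) next
    a <- alleles[, cols, drop = FALSE]
    n_i <- rowSums(!is.na(a))
    k_alt <- rowSums(a == 1L, na.rm = TRUE)
    derived_is_alt <- polar$polarized & !is.na(polar$derived) &
      polar$derived == sites$alt
    derived_is_ref <- polar$polarized & !is.na(polar$derived) &
      polar$derived == sites$ref
    k_der <- ifelse(derived_is_alt, k_alt, ifelse(derived_is_ref, n_i - k_alt, NA))
    for (part in unique(partition)) {
      psel <- partition == part & polar$polarized & !is.na(k_der)
      if (!any(psel)) next
      n_target <- as.integer(names(sort(table(n_i[psel & n_i >= 2]),
                                        decreasing = TRUE))[1])
      if (is.na(n_target) || n_target < 2) next
      use <- which(psel & n_i == n_target & k_der > 0 & k_der < n_target)
      if (balance && length(use)) {
        set.seed(seed)
        sizes <- table(classes[use])
        m <- min(sizes)
        use <- unlist(lapply(names(sizes), function(cl) {
          u <- use[classes[use] == cl]
          if (length(u) > m) sort(sample(u, m)) else u
        }))
      }
      for (cl in unique(classes[use])) {
        u <- use[classes[use] == cl]
        cnt <- tabulate(k_der[u], nbins = n_target - 1)
        out[[length(out) + 1]] <- data.frame(
          population = pop, partition = part, class = cl,
          k = seq_len(n_target - 1), count = cnt, n = n_target,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(data.frame(population = character(), partition = character(),
                                      class = character(), k = integer(),
                                      count = integer(), n = integer()))
  do.call(rbind, out)
}

hudson_fst_pair <- function(alleles, cols1, cols2, site_sel = NULL) {
  a1 <- alleles[, cols1, drop = FALSE]; a2 <- alleles[, cols2, drop = FALSE]
  n1 <- rowSums(!is.na(a1)); n2 <- rowSums(!is.na(a2))
  k1 <- rowSums(a1 == 1L, na.rm = TRUE); k2 <- rowSums(a2 == 1L, na.rm = TRUE)
  ok <- n1 >= 2 & n2 >= 2
  if (!is.null(site_sel)) ok <- ok & site_sel
  if (!any(ok)) return(NA_real_)
  p1 <- k1[ok] / n1[ok]; p2 <- k2[ok] / n2[ok]
  hw <- (2 * p1 * (1 - p1) * n1[ok] / (n1[ok] - 1) +
           2 * p2 * (1 - p2) * n2[ok] / (n2[ok] - 1)) / 2
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  if (sum(hb) == 0) return(NA_real_)
  1 - mean(hw) / mean(hb)
}

#' Hudson's F_ST between all population pairs
#'
#' Ratio-of-averages estimator: `1 - mean(H_within) / mean(H_between)`
#' over sites where both populations have at least two informative lines,
#' with the unbiased within-population heterozygosity
#' `2p(1-p) n/(n-1)` and `H_between = p1(1-p2) + p2(1-p1)`.
#'
#' @param alleles haploidized matrix.
#' @param meta [line_meta()] (popgen-excluded lines dropped).
#' @param site_sel optional logical site subset (e.g. autosomes only).
#' @return symmetric matrix of pairwise F_ST (diagonal 0).
#' @export
hudson_fst <- function(alleles, meta, site_sel = NULL) {
  meta <- meta[!meta$excluded_from_popgen, ]
  pops <- unique(meta$population)
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (j <= i) next
    c1 <- match(meta$line_id[meta$population == pops[i]], colnames(alleles))
    c2 <- match(meta$line_id[meta$population == pops[j]], colnames(alleles))
    f <- hudson_fst_pair(alleles, c1[!is.na(c1)], c2[!is.na(c2)], site_sel)
    m[i, j] <- m[j, i] <- f
  }
  m
}

#' LD decay: mean r-squared by distance bin
#'
#' Computes squared correlation of allele indicators for site pairs within
#' `max_dist`, on lines complete for both sites; pairs monomorphic in the
#' pairwise-complete subset are skipped. Pairs are subsampled to
#' `max_pairs` reproducibly under `seed`.
#'
#' @param alleles haploidized matrix.
#' @param sites site data frame.
#' @param max_dist maximum pair distance in bp (default 1000).
#' @param breaks distance bin breakpoints (default 10 equal bins).
#' @param max_pairs cap on evaluated pairs (default 2e5).
#' @param seed RNG seed for subsampling.
#' @param exclude_chroms chromosomes left out (default `"4"`).
#' @return data frame: `dist_lo`, `dist_hi`, `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(alleles, sites, max_dist = 1000, breaks = NULL,
                     max_pairs = 2e5, seed = 1, exclude_chroms = "4") {
  if (is.null(breaks)) breaks <- seq(0, max_dist, length.out = 11)
  pair_i <- integer(0); pair_j <- integer(0)
  for (ch in setdiff(unique(sites$chrom), exclude_chroms)) {
    idx <- which(sites$chrom == ch)
    pos <- sites$pos[idx]
    hi <- findInterval(pos + max_dist, pos)
    for (a in seq_along(idx)) {
      if (hi[a] > a) {
        b <- (a + 1):hi[a]
        pair_i <- c(pair_i, rep(idx[a], length(b)))
        pair_j <- c(pair_j, idx[b])
      }
    }
  }
  if (length(pair_i) == 0)
    return(data.frame(dist_lo = head(breaks, -1), dist_hi = breaks[-1],
                      mean_r2 = NA_real_, n_pairs = 0L))
  set.seed(seed)
  if (length(pair_i) > max_pairs) {
    keep <- sort(sample.int(length(pair_i), max_pairs))
    pair_i <- pair_i[keep]; pair_j <- pair_j[keep]
  }
  d <- abs(sites$pos[pair_j] - sites$pos[pair_i])
  r2 <- vapply(seq_along(pair_i), function(k) {
    x <- alleles[pair_i[k], ]; y <- alleles[pair_j[k], ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2) return(NA_real_)
    x <- x[ok]; y <- y[ok]
    if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
    stats::cor(x, y)^2
  }, numeric(1))
  bin <- cut(d, breaks, include.lowest = TRUE)
  ok <- !is.na(r2)
  agg_mean <- tapply(r2[ok], bin[ok], mean)
  agg_n <- tapply(r2[ok], bin[ok], length)
  data.frame(dist_lo = head(breaks, -1), dist_hi = breaks[-1],
             mean_r2 = as.numeric(agg_mean[levels(bin)]),
             n_pairs = as.integer(ifelse(is.na(agg_n[levels(bin)]), 0,
                                         agg_n[levels(bin)])))
}

#' Private high-frequency derived alleles
#'
#' Reports, per population, polarized derived alleles whose frequency is at
#' least `min_freq` in that population, exactly zero in every other
#' population (among non-missing calls), with missing fraction below
#' `max_missing` in every population and ancestral posterior at least
#' `min_posterior`.
#'
#' @param alleles haploidized matrix.
#' @param sites site data frame.
#' @param polar data frame from [polarize()].
#' @param meta [line_meta()].
#' @param classes optional per-site class labels.
#' @param min_freq minimum derived frequency in the focal population
#'   (default 0.20, inclusive).
#' @param max_missing maximum per-population missing fraction (default
#'   0.20, exclusive).
#' @param min_posterior ancestral posterior threshold (default 0.70).
#' @return data frame: `site`, `chrom`, `pos`, `population`, `freq`,
#'   `class`.
#' @export
private_high_freq <- function(alleles, sites, polar, meta, classes = NULL,
                              min_freq = 0.20, max_missing = 0.20,
                              min_posterior = 0.70) {
  meta <- meta[!meta$excluded_from_popgen, ]
  if (is.null(classes)) classes <- rep("all", nrow(sites))
  pops <- unique(meta$population)
  cols <- lapply(pops, function(p)
    stats::na.omit(match(meta$line_id[meta$population == p], colnames(alleles))))
  names(cols) <- pops
  n_lines <- vapply(cols, length, integer(1))
  freq <- sapply(pops, function(p) {
    a <- alleles[, cols[[p]], drop = FALSE]
    k <- rowSums(a == 1L, na.rm = TRUE); n <- rowSums(!is.na(a))
    ifelse(n > 0, k / n, NA_real_)
  })
  miss <- sapply(pops, function(p) {
    a <- alleles[, cols[[p]], drop = FALSE]
    rowSums(is.na(a)) / ncol(a)
  })
  derived_is_alt <- polar$polarized & !is.na(polar$derived) &
    polar$derived == sites$alt
  derived_is_ref <- polar$polarized & !is.na(polar$derived) &
    polar$derived == sites$ref
  dfreq <- freq
  dfreq[derived_is_ref, ] <- 1 - freq[derived_is_ref, ]
  dfreq[!(derived_is_alt | derived_is_ref), ] <- NA
  ok_post <- polar$polarized & !is.na(polar$posterior) &
    polar$posterior >= min_posterior
  ok_miss <- rowSums(miss >= max_missing) == 0
  out <- list()
  for (p in pops) {
    others <- setdiff(pops, p)
    sel <- which(ok_post & ok_miss & !is.na(dfreq[, p]) & dfreq[, p] >= min_freq &
                   rowSums(dfreq[, others, drop = FALSE] > 0, na.rm = TRUE) == 0 &
                   rowSums(is.na(dfreq[, others, drop = FALSE])) == 0)
    if (length(sel))
      out[[length(out) + 1]] <- data.frame(
        site = sel, chrom = sites$chrom[sel], pos = sites$pos[sel],
        population = p, freq = dfreq[sel, p], class = classes[sel],
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(site = integer(), chrom = character(), pos = numeric(),
                      population = character(), freq = numeric(),
                      class = character()))
  do.call(rbind, out)
}

#' Summarize private alleles by frequency bin and class
#' @param priv data frame from [private_high_freq()].
#' @param freq_breaks bin breakpoints (default 20% bins from 0.2 to 1).
#' @return list: `counts` (population x bin x class long data frame),
#'   `ratios` (per population nonsynonymous/synonymous and UTR/synonymous
#'   count ratios where those classes exist).
#' @export
private_allele_summary <- function(priv, freq_breaks = seq(0.2, 1, by = 0.2)) {
  if (nrow(priv) == 0) return(list(counts = priv, ratios = NULL))
  priv$freq_bin <- cut(priv$freq, unique(c(freq_breaks, 1.0001)),
                       include.lowest = TRUE, right = FALSE)
  counts <- as.data.frame(table(population = priv$population,
                                freq_bin = priv$freq_bin, class = priv$class))
  syn_classes <- c("synonymous_non4fold", "fourfold")
  ratios <- do.call(rbind, lapply(unique(priv$population), function(p) {
    pp <- priv[priv$population == p, ]
    syn <- sum(pp$class %in% syn_classes)
    data.frame(population = p,
               nonsyn_over_syn = if (syn) sum(pp$class == "nonsynonymous") / syn else NA,
               utr_over_syn = if (syn) sum(pp$class == "UTR") / syn else NA)
  }))
  list(counts = counts, ratios = ratios)
}

#' Compare windowed diversity across populations
#'
#' Thin reporting step over precomputed window statistics: one-way ANOVA
#' with Tukey post-hoc contrasts of pi across populations, and per
#' population a Wilcoxon test of X-chromosome versus autosomal pi.
#'
#' @param win_df long data frame of window stats with columns `population`,
#'   `chrom`, `pi` (and optionally `tajima_d`).
#' @param x_chrom name of the X chromosome.
#' @return list: `anova`, `tukey`, `wilcoxon_x_vs_auto` (per population
#'   p-values).
#' @export
diversity_tests <- function(win_df, x_chrom = "X") {
  win_df <- win_df[!is.na(win_df$pi), ]
  fit <- stats::aov(pi ~ population, data = win_df)
  wil <- vapply(unique(win_df$population), function(p) {
    d <- win_df[win_df$population == p, ]
    x <- d$pi[d$chrom == x_chrom]; a <- d$pi[d$chrom != x_chrom]
    if (length(x) < 2 || length(a) < 2) return(NA_real_)
    stats::wilcox.test(x, a)$p.value
  }, numeric(1))
  list(anova = summary(fit), tukey = stats::TukeyHSD(fit),
       wilcoxon_x_vs_auto = wil)
}
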