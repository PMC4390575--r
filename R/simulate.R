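#' Simulation configuration
#'
#' Bundles every knob of the synthetic-cohort generator. The generator
#' emulates the statistical structure the pipeline assumes: several
#' island-model populations (Balding-Nichols differentiation with a single
#' parameter `F` per population), deeply inbred lines that are homozygous
#' outside planted heterozygous blocks, het blocks caused by heterozygous
#' inversions, quality-stratified genotype errors, deep read counts and
#' diverged outgroup alleles.
#'
#' @param seed integer RNG seed; all generator output is deterministic in it.
#' @param populations data frame with `label`, `n_lines`, `F` (fixation
#'   index in `[0,1)`; 0 means the population frequency equals the ancestral
#'   frequency exactly).
#' @param chrom_lengths named numeric vector, chromosome -> length in bp.
#' @param snp_density expected variant sites per bp.
#' @param indel_fraction fraction of variant sites simulated as indels.
#' @param planted_inversions list of inversions, each a list with `name`,
#'   `chrom`, `start`, `end` (0-based half-open span) and `het_freq` /
#'   `hom_freq` (scalar or named per-population carrier probabilities).
#' @param het_rate_in_block probability a call inside a line's planted het
#'   block is heterozygous.
#' @param het_rate_outside residual true-heterozygosity rate outside blocks.
#' @param error_het_rate rate of spurious heterozygous calls outside blocks.
#' @param gq_beta list of `c(shape1, shape2)` Beta parameters per call class
#'   (`hom`, `het_true`, `het_error`); GQ = round(99 * Beta draw). Error
#'   het calls default to a lower-GQ distribution so quality stratifies
#'   with validation rate.
#' @param flag_rate baseline probability a site carries the recalibration
#'   flag; `flag_error_boost` is added for sites holding at least one error
#'   het call.
#' @param flag_error_boost see `flag_rate`.
#' @param missing_rate per-call missingness probability.
#' @param outgroup_divergence named numeric vector: per-outgroup
#'   substitution probability away from the ancestral allele.
#' @param outgroup_weights weights used by the polarization vote (default
#'   equal).
#' @param depth_mean expected read depth for simulated read counts.
#' @param read_error per-read miscall probability.
#' @param freq_min truncation bound of the neutral-like ancestral frequency
#'   density (proportional to 1/p on `[freq_min, 1 - freq_min]`).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       populations = data.frame(
                         label = c("B", "I", "N", "T", "Z"),
                         n_lines = c(5, 5, 5, 5, 8),
                         F = c(0.10, 0.10, 0.10, 0.10, 0.05)),
                       chrom_lengths = c(`2L` = 2e6, `2R` = 2e6, `3L` = 2e6,
                                         `3R` = 2e6, X = 2e6, `4` = 1e5),
                       snp_density = 1 / 200,
                       indel_fraction = 0.12,
                       planted_inversions = list(),
                       het_rate_in_block = 0.40,
                       het_rate_outside = 0.001,
                       error_het_rate = 0.005,
                       gq_beta = list(hom = c(9, 1), het_true = c(9, 1),
                                      het_error = c(1.5, 3)),
                       flag_rate = 0.05,
                       flag_error_boost = 0.25,
                       missing_rate = 0.02,
                       outgroup_divergence = c(og1 = 0.04, og2 = 0.08, og3 = 0.12),
                       outgroup_weights = NULL,
                       depth_mean = 150,
                       read_error = 0.005,
                       freq_min = 0.001) {
  rates <- c(snp_density = snp_density, indel_fraction = indel_fraction,
             het_rate_in_block = het_rate_in_block,
             het_rate_outside = het_rate_outside,
             error_het_rate = error_het_rate, flag_rate = flag_rate,
             missing_rate = missing_rate, read_error = read_error)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (any(populations$F < 0 | populations$F >= 1)) stop("F must lie in [0, 1)")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (is.null(outgroup_weights))
    outgroup_weights <- stats::setNames(rep(1, length(outgroup_divergence)),
                                        names(outgroup_divergence))
  structure(as.list(environment()), class = "sim_config")
}

NUCS <- c("A", "C", "G", "T")

# draw from density proportional to 1/p on [pmin, 1-pmin] (inverse CDF)
draw_neutral_freq <- function(n, pmin) {
  pmin * ((1 - pmin) / pmin)^stats::runif(n)
}

inv_carrier_prob <- function(freq, pop) {
  if (is.null(names(freq))) rep_len(freq, length(pop)) else {
    out <- unname(freq[pop]); out[is.na(out)] <- 0; out
  }
}

#' Simulate a cohort of inbred lines
#'
#' Per site, an ancestral (= reference) allele frequency is drawn from a
#' neutral-like density proportional to 1/p, and per-population derived
#' frequencies from a Balding-Nichols Beta distribution with parameter `F`.
#' Each line is homozygous outside its planted het blocks except for a
#' small residual-het rate plus a spurious-het error rate; inside blocks
#' (the spans of inversions the line carries heterozygous) calls are
#' heterozygous with probability `het_rate_in_block`. GQ scores are drawn
#' from class-specific distributions, with error hets lower on average.
#'
#' @param config a [sim_config()].
#' @return list with elements `table` ([genotype_table()]), `meta`
#'   ([line_meta()]), and `truth`: a list with `planted_blocks` (per-line
#'   interval sets), `inversion_genotypes` (line x inversion data frame),
#'   `ancestral` (per-site allele), `pop_freq` (sites x populations derived
#'   frequency matrix), `true_gt` (error-free genotype matrix) and
#'   `error_het` (logical matrix marking injected spurious hets).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pops <- config$populations
  lines <- unlist(lapply(seq_len(nrow(pops)), function(i)
    sprintf("%s%02d", pops$label[i], seq_len(pops$n_lines[i]))))
  line_pop <- rep(pops$label, pops$n_lines)
  meta <- line_meta(lines, line_pop)

  # sites per chromosome
  site_list <- lapply(names(config$chrom_lengths), function(ch) {
    len <- config$chrom_lengths[[ch]]
    n <- stats::rpois(1, len * config$snp_density)
    if (n == 0) return(NULL)
    pos <- sort(sample.int(len, min(n, len)))
    is_indel <- stats::runif(length(pos)) < config$indel_fraction
    ref <- sample(NUCS, length(pos), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(NUCS, r), 1), character(1))
    ref[is_indel] <- paste0(ref[is_indel], "A")   # deletion-style records
    data.frame(chrom = ch, pos = pos, ref = ref, alt = alt,
               vtype = ifelse(is_indel, "indel", "snp"),
               recal_flag = FALSE, stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, site_list)
  if (is.null(sites) || nrow(sites) == 0)
    stop("no polymorphic sites sampled; increase snp_density or chromosome lengths")
  ns <- nrow(sites)

  p0 <- draw_neutral_freq(ns, config$freq_min)  # derived (= alt) ancestral frequency
  pop_freq <- sapply(seq_len(nrow(pops)), function(i) {
    F <- pops$F[i]
    if (F == 0) p0 else stats::rbeta(ns, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
  })
  colnames(pop_freq) <- pops$label

  # inversion genotypes and planted blocks
  inv_geno <- NULL
  planted <- stats::setNames(vector("list", length(lines)), lines)
  for (l in lines) planted[[l]] <- empty_intervals()
  if (length(config$planted_inversions)) {
    rows <- list()
    for (inv in config$planted_inversions) {
      p_hom <- inv_carrier_prob(inv$hom_freq %||% 0, line_pop)
      p_het <- inv_carrier_prob(inv$het_freq %||% 0, line_pop)
      u <- stats::runif(length(lines))
      g <- ifelse(u < p_hom, "hom", ifelse(u < p_hom + p_het, "het", "absent"))
      rows[[length(rows) + 1]] <- data.frame(line_id = lines, inversion = inv$name,
                                             genotype = g, stringsAsFactors = FALSE)
      for (li in which(g == "het")) {
        planted[[lines[li]]] <- merge_intervals(rbind(
          planted[[lines[li]]],
          intervals(inv$chrom, inv$start, inv$end, label = inv$name)))
      }
    }
    inv_geno <- do.call(rbind, rows)
  }

  # genotypes: truth first (inbred homozygotes + real hets), then error overlay
  gt <- matrix(NA_integer_, ns, length(lines))
  true_gt <- matrix(NA_integer_, ns, length(lines))
  err <- matrix(FALSE, ns, length(lines))
  for (j in seq_along(lines)) {
    p <- pop_freq[, line_pop[j]]
    g <- ifelse(stats::runif(ns) < p, 2L, 0L)          # inbred homozygote
    in_block <- positions_in_intervals(sites$chrom, sites$pos, planted[[lines[j]]])
    u <- stats::runif(ns)
    g[in_block & u < config$het_rate_in_block] <- 1L
    res_het <- !in_block & u < config$het_rate_outside
    g[res_het] <- 1L
    true_gt[, j] <- g
    u2 <- stats::runif(ns)
    e <- !in_block & !res_het & u2 < config$error_het_rate
    g[e] <- 1L
    err[, j] <- e
    gt[, j] <- g
  }

  # recalibration flag: baseline rate, boosted where error hets landed
  has_err <- rowSums(err) > 0
  sites$recal_flag <- stats::runif(ns) <
    (config$flag_rate + config$flag_error_boost * has_err)

  # GQ by call class
  gq <- matrix(NA_integer_, ns, length(lines))
  draw_gq <- function(n, shp) as.integer(round(99 * stats::rbeta(n, shp[1], shp[2])))
  is_het <- gt == 1L
  hom_idx <- which(!is_het)
  gq[hom_idx] <- draw_gq(length(hom_idx), config$gq_beta$hom)
  het_true_idx <- which(is_het & !err)
  gq[het_true_idx] <- draw_gq(length(het_true_idx), config$gq_beta$het_true)
  het_err_idx <- which(is_het & err)
  gq[het_err_idx] <- draw_gq(length(het_err_idx), config$gq_beta$het_error)

  # missingness
  miss <- matrix(stats::runif(ns * length(lines)) < config$missing_rate, ns)
  gt[miss] <- NA_integer_; gq[miss] <- NA_integer_

  tab <- genotype_table(sites, lines, gt, gq)
  # genotype_table sorts by (chrom, pos); replicate that order on truth matrices
  ord <- order(sites$chrom, sites$pos)
  truth <- list(planted_blocks = planted,
                inversion_genotypes = inv_geno,
                ancestral = sites$ref[ord],
                pop_freq = pop_freq[ord, , drop = FALSE],
                true_gt = true_gt[ord, , drop = FALSE],
                error_het = err[ord, , drop = FALSE])
  colnames(truth$true_gt) <- colnames(truth$error_het) <- lines
  list(table = tab, meta = meta, truth = truth)
}

#' Simulate deep-coverage read counts
#'
#' Given the cohort's true genotypes, draws a Poisson depth per call and
#' binomial alternate-read counts with success probability `read_error`,
#' 0.5, or `1 - read_error` for true hom-ref, het, hom-alt respectively.
#'
#' @param table genotype_table (defines the site/line grid).
#' @param truth truth list from [simulate_cohort()] (uses `true_gt`).
#' @param depth_mean expected depth (> 0).
#' @param read_error per-read miscall probability.
#' @param seed RNG seed.
#' @return list with integer matrices `ref` and `alt` (sites x lines).
#' @export
simulate_read_counts <- function(table, truth, depth_mean = 150,
                                 read_error = 0.005, seed = 1) {
  if (depth_mean <= 0) stop("depth_mean must be > 0")
  set.seed(seed)
  tg <- truth$true_gt
  n <- length(tg)
  depth <- matrix(stats::rpois(n, depth_mean), nrow(tg))
  p_alt <- matrix(read_error, nrow(tg), ncol(tg))
  p_alt[tg == 1L] <- 0.5
  p_alt[tg == 2L] <- 1 - read_error
  alt <- matrix(stats::rbinom(n, as.vector(depth), as.vector(p_alt)), nrow(tg))
  ref <- depth - alt
  dimnames(ref) <- dimnames(alt) <- dimnames(tg)
  list(ref = ref, alt = alt)
}

#' Simulate breakpoint-read evidence for inversions
#'
#' Heterozygous carriers yield reads of both classes (inversion-breakpoint
#' reads and reference-bridging reads); homozygous carriers yield only
#' inversion reads; non-carriers only reference-bridging reads, apart from
#' a Poisson noise rate.
#'
#' @param truth truth list from [simulate_cohort()] (uses
#'   `inversion_genotypes`).
#' @param mean_support expected read count per chromosome copy (> 0).
#' @param seed RNG seed.
#' @param noise_rate Poisson rate of stray reads of the absent class.
#' @return data frame: `line_id`, `inversion`, `inv_reads`,
#'   `ref_bridge_reads`.
#' @export
simulate_inversion_evidence <- function(truth, mean_support = 20, seed = 1,
                                        noise_rate = 0) {
  if (mean_support <= 0) stop("mean_support must be > 0")
  ig <- truth$inversion_genotypes
  if (is.null(ig) || nrow(ig) == 0)
    return(data.frame(line_id = character(), inversion = character(),
                      inv_reads = integer(), ref_bridge_reads = integer()))
  set.seed(seed)
  n <- nrow(ig)
  inv_rate <- ifelse(ig$genotype == "hom", 2 * mean_support,
                     ifelse(ig$genotype == "het", mean_support, noise_rate))
  ref_rate <- ifelse(ig$genotype == "absent", 2 * mean_support,
                     ifelse(ig$genotype == "het", mean_support, noise_rate))
  data.frame(line_id = ig$line_id, inversion = ig$inversion,
             inv_reads = stats::rpois(n, inv_rate),
             ref_bridge_reads = stats::rpois(n, ref_rate),
             stringsAsFactors = FALSE)
}

#' Simulate outgroup alleles
#'
#' Each outgroup carries the ancestral allele except with its configured
#' divergence probability, in which case it carries one of the three other
#' nucleotides uniformly.
#'
#' @param truth truth list from [simulate_cohort()] (uses `ancestral`).
#' @param divergence named numeric vector of per-outgroup divergence
#'   probabilities (>= 1 outgroup).
#' @param seed RNG seed.
#' @return character matrix sites x outgroups.
#' @export
simulate_outgroups <- function(truth, divergence = c(og1 = 0.04, og2 = 0.08, og3 = 0.12),
                               seed = 1) {
  if (length(divergence) < 1) stop("at least one outgroup required")
  set.seed(seed)
  anc <- truth$ancestral
  out <- sapply(seq_along(divergence), function(i) {
    a <- anc
    hit <- stats::runif(length(a)) < divergence[i]
    if (any(hit)) {
      a[hit] <- vapply(a[hit], function(x) sample(setdiff(NUCS, x), 1), character(1))
    }
    a
  })
  colnames(out) <- names(divergence)
  out
}
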