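#' Per-site nucleotide diversity from allele counts
#'
#' Unbiased per-site heterozygosity `2 j (n - j) / (n (n - 1))` where `j`
#' is the alternate-allele count and `n` the number of called alleles.
#' This is the average number of differences over all unordered allele
#' pairs at the site, the site-wise term of theta-pi.
#'
#' @param j alternate allele count(s), `0 <= j <= n`.
#' @param n called allele count(s), `n >= 2`.
#' @return per-site pi, vectorized over `j` and `n`.
#' @export
site_pi <- function(j, n) {
  if (any(n < 2)) stop("site_pi undefined for n < 2 called alleles")
  if (any(j < 0 | j > n)) stop("need 0 <= j <= n")
  2 * j * (n - j) / (n * (n - 1))
}

# guarded vectorized version used internally: NA where n < 2
site_pi_safe <- function(j, n) {
  out <- rep(NA_real_, length(j))
  ok <- !is.na(n) & n >= 2
  out[ok] <- 2 * j[ok] * (n[ok] - j[ok]) / (n[ok] * (n[ok] - 1))
  out
}

#' Weir-Cockerham per-site variance components for two populations
#'
#' Returns the among-population component `a` and the total
#' `a + b + c` of the Weir & Cockerham (1984) moment estimator for two
#' populations, computed from per-population sample sizes (individuals
#' with non-missing calls), alternate allele frequencies and observed
#' heterozygote proportions.  The per-site estimate is `a / (a+b+c)`;
#' windowed values should be computed as the ratio of the summed
#' components ([windowed_fst()]), never as the mean of per-site ratios.
#'
#' @param n_a,n_b individuals with non-missing calls in each population.
#' @param p_a,p_b alternate allele frequency (from non-missing calls).
#' @param h_a,h_b observed heterozygote proportion.
#' @return list with numeric vectors `a` (among-population component)
#'   and `d` (total `a + b + c`); both `NA` where the site is unusable
#'   (a population fully missing, or fewer than 3 calls overall).
#' @export
wc_fst_site <- function(n_a, p_a, h_a, n_b, p_b, h_b) {
  r <- 2
  ok <- !is.na(n_a) & !is.na(n_b) & n_a >= 1 & n_b >= 1 & (n_a + n_b) > 2
  nbar <- (n_a + n_b) / r
  nc <- (n_a + n_b - (n_a^2 + n_b^2) / (n_a + n_b)) / (r - 1)
  pbar <- (n_a * p_a + n_b * p_b) / (n_a + n_b)
  s2 <- (n_a * (p_a - pbar)^2 + n_b * (p_b - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n_a * h_a + n_b * h_b) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  a[!ok] <- NA_real_
  d <- a + b + cc
  d[!ok] <- NA_real_
  list(a = a, d = d)
}

# per-site summaries for one population's dosage submatrix
pop_site_counts <- function(d) {
  called <- colSums(!is.na(d))            # individuals
  list(
    n_ind = called,
    n_alleles = 2 * called,
    j = colSums(d, na.rm = TRUE),         # alt allele count
    het = colSums(d == 1L, na.rm = TRUE))
}

# one pass over all sites: everything the window engine needs
site_stats <- function(gm, pop_a, pop_b) {
  ia <- pop_rows(gm, pop_a)
  ib <- pop_rows(gm, pop_b)
  A <- pop_site_counts(gm$dosage[ia, , drop = FALSE])
  B <- pop_site_counts(gm$dosage[ib, , drop = FALSE])
  p_a <- ifelse(A$n_alleles > 0, A$j / A$n_alleles, NA_real_)
  p_b <- ifelse(B$n_alleles > 0, B$j / B$n_alleles, NA_real_)
  h_a <- ifelse(A$n_ind > 0, A$het / A$n_ind, NA_real_)
  h_b <- ifelse(B$n_ind > 0, B$het / B$n_ind, NA_real_)
  wc <- wc_fst_site(A$n_ind, p_a, h_a, B$n_ind, p_b, h_b)
  list(
    chrom = gm$variants$chrom, pos = gm$variants$pos,
    pi_a = site_pi_safe(A$j, A$n_alleles),
    pi_b = site_pi_safe(B$j, B$n_alleles),
    n_a = A$n_alleles, n_b = B$n_alleles,
    seg_a = A$j > 0 & A$j < A$n_alleles & A$n_alleles >= 2,
    seg_b = B$j > 0 & B$j < B$n_alleles & B$n_alleles >= 2,
    wc_a = wc$a, wc_d = wc$d)
}

# index range [lo, hi] of sorted positions falling in each window
window_site_ranges <- function(pos, starts, ends) {
  lo <- findInterval(starts - 1L, pos) + 1L
  hi <- findInterval(ends, pos)
  list(lo = lo, hi = hi, n = pmax(hi - lo + 1L, 0L))
}

range_sum <- function(v, lo, hi) {
  v[is.na(v)] <- 0
  cs <- c(0, cumsum(v))
  out <- cs[hi + 1L] - cs[lo]
  out[hi < lo] <- 0
  out
}

#' Windowed nucleotide diversity
#'
#' Sums [site_pi()] over the sites of each window (using the chosen
#' population's non-missing allele counts) and divides by the window
#' size in bp, yielding per-bp diversity comparable across windows.
#'
#' @param gm a [genotype_matrix()] with metadata attached.
#' @param population population label.
#' @param windows data.frame of windows (`chrom`, `start`, `end`), e.g.
#'   from [make_windows()].
#' @return `windows` with columns `n_snps` and `pi` added; windows
#'   without usable sites report `pi = 0`.
#' @export
windowed_pi <- function(gm, population, windows) {
  ss <- site_stats_single(gm, population)
  out <- windows
  out$n_snps <- 0L
  out$pi <- 0
  for (chr in unique(windows$chrom)) {
    wi <- which(windows$chrom == chr)
    si <- which(ss$chrom == chr)
    rg <- window_site_ranges(ss$pos[si], windows$start[wi], windows$end[wi])
    out$n_snps[wi] <- rg$n
    out$pi[wi] <- range_sum(ss$pi[si], rg$lo, rg$hi) /
      (windows$end[wi] - windows$start[wi] + 1)
  }
  out
}

site_stats_single <- function(gm, population) {
  ia <- pop_rows(gm, population)
  A <- pop_site_counts(gm$dosage[ia, , drop = FALSE])
  list(chrom = gm$variants$chrom, pos = gm$variants$pos,
       pi = site_pi_safe(A$j, A$n_alleles),
       n = A$n_alleles,
       seg = A$j > 0 & A$j < A$n_alleles & A$n_alleles >= 2)
}

#' Windowed Weir-Cockerham Fst (ratio of sums)
#'
#' The window estimate is `sum(a) / sum(a+b+c)` over usable in-window
#' sites — the "weighted" estimator.  Negative estimates are retained as
#' computed so the genome-wide Z-transform keeps its shape.
#'
#' @inheritParams windowed_pi
#' @param pop_a,pop_b the two population labels.
#' @return `windows` with `n_snps` and `fst` added; `fst` is `NA` where
#'   no site yields a nonzero total component.
#' @export
windowed_fst <- function(gm, pop_a, pop_b, windows) {
  ss <- site_stats(gm, pop_a, pop_b)
  out <- windows
  out$n_snps <- 0L
  out$fst <- NA_real_
  for (chr in unique(windows$chrom)) {
    wi <- which(windows$chrom == chr)
    si <- which(ss$chrom == chr)
    rg <- window_site_ranges(ss$pos[si], windows$start[wi], windows$end[wi])
    out$n_snps[wi] <- rg$n
    num <- range_sum(ss$wc_a[si], rg$lo, rg$hi)
    den <- range_sum(ss$wc_d[si], rg$lo, rg$hi)
    out$fst[wi] <- ifelse(den != 0, num / den, NA_real_)
  }
  out
}

# Tajima's D from S segregating sites, summed pi, and n chromosomes
tajima_d_value <- function(S, pi_hat, n) {
  if (is.na(n) || n < 4 || is.na(S) || S < 1) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Windowed Tajima's D
#'
#' Computes D per window from the segregating-site count S and the
#' summed (absolute, not per-bp) pairwise diversity.  Because the
#' normalizing constants assume a fixed number of sampled chromosomes,
#' the window uses the minimum per-site non-missing allele count among
#' its usable sites — a conservative single-n approximation under
#' missing data.  Windows with `S = 0` or fewer than 4 chromosomes
#' report `NA`.
#'
#' @inheritParams windowed_pi
#' @return `windows` with columns `n_snps`, `S`, `n_chrom` and `tajd`.
#' @export
tajimas_d <- function(gm, population, windows) {
  ss <- site_stats_single(gm, population)
  out <- windows
  out$n_snps <- 0L
  out$S <- 0L
  out$n_chrom <- NA_integer_
  out$tajd <- NA_real_
  for (chr in unique(windows$chrom)) {
    wi <- which(windows$chrom == chr)
    si <- which(ss$chrom == chr)
    pos <- ss$pos[si]
    rg <- window_site_ranges(pos, windows$start[wi], windows$end[wi])
    out$n_snps[wi] <- rg$n
    n_c <- ss$n[si]
    pi_c <- ss$pi[si]
    seg_c <- ss$seg[si]
    for (k in seq_along(wi)) {
      if (rg$n[k] == 0) next
      sel <- rg$lo[k]:rg$hi[k]
      usable <- n_c[sel] >= 2
      if (!any(usable)) next
      n_min <- min(n_c[sel][usable])
      S <- sum(seg_c[sel][usable])
      pi_hat <- sum(pi_c[sel][usable])
      out$S[wi[k]] <- S
      out$n_chrom[wi[k]] <- n_min
      out$tajd[wi[k]] <- tajima_d_value(S, pi_hat, n_min)
    }
  }
  out
}

#' Z-transform a vector of window statistics
#'
#' Standardizes to zero mean and unit sample standard deviation
#' (denominator n - 1) over the non-missing entries; `NA` entries
#' (flagged windows) stay `NA`.
#'
#' @param values numeric vector.
#' @return standardized vector of the same length.
#' @export
zscore <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2)
    stop("zscore needs at least 2 retained values")
  s <- stats::sd(values[ok])
  if (s == 0) stop("zscore undefined: zero spread")
  (values - mean(values[ok])) / s
}

#' log2 diversity ratio between a focal and a reference population
#'
#' `log2(pi_focal / pi_reference)`; strongly negative when the focal
#' population has locally reduced diversity (a focal-population sweep).
#' Undefined (NA) when either diversity is zero — such windows carry the
#' `RATIO_UNDEFINED` flag downstream and are excluded from ranking.
#'
#' @param pi_a focal per-bp diversity (numerator), `>= 0`.
#' @param pi_b reference per-bp diversity (denominator), `>= 0`.
#' @return numeric vector; `NA` where either input is zero.
#' @export
log2_pi_ratio <- function(pi_a, pi_b) {
  if (any(pi_a < 0, na.rm = TRUE) || any(pi_b < 0, na.rm = TRUE))
    stop("diversities must be nonnegative")
  out <- rep(NA_real_, length(pi_a))
  ok <- !is.na(pi_a) & !is.na(pi_b) & pi_a > 0 & pi_b > 0
  out[ok] <- log2(pi_a[ok] / pi_b[ok])
  out
}

#' Squared genotype correlation between two loci
#'
#' The unphased-dosage surrogate for LD r^2: the squared Pearson
#' correlation of dosage vectors over pairwise-complete samples.
#'
#' @param g1,g2 dosage vectors of equal length (NA = missing).
#' @return r^2, or `NA` when fewer than two complete pairs remain or a
#'   locus is monomorphic among them.
#' @export
dosage_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) return(NA_real_)
  x <- g1[ok]; y <- g2[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Linkage-disequilibrium decay table
#'
#' Computes r^2 for all same-contig variant pairs within `max_dist` bp
#' in one population, bins pairs by physical distance and reports the
#' mean r^2 per bin.  Pairs where either locus is monomorphic (or with
#' fewer than two complete genotype pairs) are skipped.
#'
#' @param gm a [genotype_matrix()] with metadata.
#' @param population population label.
#' @param max_dist maximum pair distance in bp.
#' @param bin_width distance bin width in bp.
#' @return data.frame with `bin_mid` (bp), `mean_r2` (`NA` for empty
#'   bins) and `n_pairs`.
#' @export
ld_decay <- function(gm, population, max_dist = 100000, bin_width = 1000) {
  rows <- pop_rows(gm, population)
  n_bins <- ceiling(max_dist / bin_width)
  sums <- numeric(n_bins)
  counts <- integer(n_bins)
  for (chr in unique(gm$variants$chrom)) {
    ci <- which(gm$variants$chrom == chr)
    pos <- gm$variants$pos[ci]
    d <- gm$dosage[rows, ci, drop = FALSE]
    m <- length(ci)
    if (m < 2) next
    for (i in seq_len(m - 1)) {
      jmax <- findInterval(pos[i] + max_dist, pos)
      if (jmax <= i) next
      for (j in (i + 1):jmax) {
        r2 <- dosage_r2(d[, i], d[, j])
        if (is.na(r2)) next
        bin <- max(1L, ceiling((pos[j] - pos[i]) / bin_width))
        sums[bin] <- sums[bin] + r2
        counts[bin] <- counts[bin] + 1L
      }
    }
  }
  data.frame(
    bin_mid = (seq_len(n_bins) - 0.5) * bin_width,
    mean_r2 = ifelse(counts > 0, sums / counts, NA_real_),
    n_pairs = counts)
}
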