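test_that("site_pi matches the pairwise-difference definition", {
  expect_equal(site_pi(1, 2), 1.0)
  expect_equal(site_pi(0, 10), 0.0)
  expect_equal(site_pi(10, 10), 0.0)
  expect_equal(site_pi(2, 4), 2 / 3)
  expect_error(site_pi(0, 1), "n < 2")
  # symmetric in j <-> n - j, maximal at j = n/2
  for (n in c(4, 10, 20)) {
    j <- 0:n
    v <- site_pi(j, n)
    expect_equal(v, rev(v))
    expect_equal(which.max(v) - 1, n / 2)
  }
})

test_that("wc_fst_site reproduces the Weir-Cockerham components", {
  wc <- wc_fst_site(10, 1, 0, 10, 0, 0)
  expect_equal(wc$a / wc$d, 1.0)
  wc <- wc_fst_site(10, 0.5, 0.5, 10, 0.5, 0.5)
  expect_equal(wc$a, -0.0138889, tolerance = 1e-6)
  expect_equal(wc$d, 0.25, tolerance = 1e-12)
  expect_equal(wc$a / wc$d, -0.0555556, tolerance = 1e-6)
  # monomorphic identical site: zero components, site skipped downstream
  wc <- wc_fst_site(10, 0, 0, 10, 0, 0)
  expect_equal(wc$a, 0)
  expect_equal(wc$d, 0)
})

test_that("windowed_pi sums site pi over the window per bp", {
  # sites with per-site pi 1.0 (j=1, n=2) and 0.5 (j=1, n=4)
  d <- cbind(s1 = c(1L, 1L), s2 = c(NA, 0L))
  gm <- gm_from_dosage(t(d), pos = c(1000L, 2000L), contig_len = 10000)
  win <- data.frame(chrom = "chr1", start = 1L, end = 10000L)
  out <- windowed_pi(gm, "popA", win)
  expect_equal(out$pi, 1.5e-4)
  expect_equal(out$n_snps, 2L)
  # empty window reports zero
  win0 <- data.frame(chrom = "chr1", start = 5000L, end = 9000L)
  expect_equal(windowed_pi(gm, "popA", win0)$pi, 0)
})

test_that("windowed pi and Fst match brute-force oracles on random data", {
  set.seed(101)
  for (rep in 1:30) {
    gm <- random_gm(n_per_pop = sample(3:12, 1),
                    n_variants = sample(5:20, 1),
                    missing_rate = runif(1, 0, 0.2))
    win <- data.frame(chrom = "chr1", start = 1L, end = gm$contigs[["chr1"]])
    ia <- which(gm$meta$population == "popA")
    ib <- which(gm$meta$population == "popB")
    expect_equal(windowed_pi(gm, "popA", win)$pi,
                 oracle_window_pi(gm$dosage[ia, , drop = FALSE],
                                  win$end - win$start + 1),
                 tolerance = 1e-12)
    expect_equal(windowed_fst(gm, "popA", "popB", win)$fst,
                 oracle_windowed_fst(gm$dosage[ia, , drop = FALSE],
                                     gm$dosage[ib, , drop = FALSE]),
                 tolerance = 1e-12)
  }
})

test_that("windowed Fst is the ratio of sums, not the mean of site Fst", {
  # one strongly differentiated site + one weakly informative site:
  # the two summaries disagree, and ours equals the ratio of sums
  dA <- cbind(v1 = rep(2L, 8), v2 = c(1L, rep(0L, 7)))
  dB <- cbind(v1 = rep(0L, 8), v2 = c(0L, 1L, rep(0L, 6)))
  gm <- gm_from_dosage(rbind(dA, dB),
                       populations = rep(c("popA", "popB"), each = 8))
  win <- data.frame(chrom = "chr1", start = 1L, end = 100L)
  ours <- windowed_fst(gm, "popA", "popB", win)$fst
  ratio_of_sums <- oracle_windowed_fst(dA, dB)
  site_fsts <- vapply(1:2, function(j) {
    comp <- oracle_wc_components(dA[, j], dB[, j])
    comp["a"] / sum(comp)
  }, numeric(1))
  expect_equal(ours, ratio_of_sums, tolerance = 1e-12)
  expect_gt(abs(ours - mean(site_fsts)), 0.01)
})

test_that("identical populations give non-positive windowed Fst", {
  set.seed(102)
  d <- random_gm(n_per_pop = 10, n_variants = 15, missing_rate = 0)$dosage
  rownames(d) <- NULL
  gm <- gm_from_dosage(rbind(d[1:10, ], d[1:10, ]),
                       populations = rep(c("popA", "popB"), each = 10))
  win <- data.frame(chrom = "chr1", start = 1L, end = 160L)
  fst <- windowed_fst(gm, "popA", "popB", win)$fst
  expect_lte(fst, 1e-12)
  ia <- 1:10
  expect_equal(fst, oracle_windowed_fst(d[ia, ], d[ia, ]), tolerance = 1e-12)
})

test_that("Tajima's D has the expected sign and matches the oracle", {
  # n = 10 chromosomes (5 diploids), S = 5 singletons: pi_hat = 1.0
  # below S/a1 = 1.7674, so D < 0
  d_singletons <- rbind(diag(1L, 5), matrix(0L, 0, 5))
  gm <- gm_from_dosage(d_singletons)
  win <- data.frame(chrom = "chr1", start = 1L, end = 100L)
  D_neg <- tajimas_d(gm, "popA", win)
  expect_lt(D_neg$tajd, 0)
  expect_equal(D_neg$S, 5L)
  expect_equal(D_neg$n_chrom, 10L)
  expect_equal(D_neg$tajd, oracle_tajimas_d(d_singletons), tolerance = 1e-10)
  # S = 5 sites all at frequency 1/2: pi_hat = 5 * 2*5*5/(10*9) = 2.7778,
  # above 1.7674, so D > 0
  d_mid <- matrix(1L, 5, 5)
  gm2 <- gm_from_dosage(d_mid)
  D_pos <- tajimas_d(gm2, "popA", win)
  expect_gt(D_pos$tajd, 0)
  expect_equal(D_pos$tajd, oracle_tajimas_d(d_mid), tolerance = 1e-10)
  # monomorphic window: D undefined
  gm3 <- gm_from_dosage(matrix(0L, 5, 3))
  expect_true(is.na(tajimas_d(gm3, "popA", win)$tajd))
})

test_that("Tajima's D equals the oracle on random fixtures", {
  set.seed(103)
  for (rep in 1:100) {
    gm <- random_gm(n_per_pop = sample(3:10, 1),
                    n_variants = sample(3:15, 1),
                    missing_rate = runif(1, 0, 0.15))
    win <- data.frame(chrom = "chr1", start = 1L,
                      end = gm$contigs[["chr1"]])
    ia <- which(gm$meta$population == "popA")
    ours <- tajimas_d(gm, "popA", win)$tajd
    theirs <- oracle_tajimas_d(gm$dosage[ia, , drop = FALSE])
    if (is.na(theirs)) expect_true(is.na(ours))
    else expect_equal(ours, theirs, tolerance = 1e-10)
  }
})

test_that("zscore standardizes to mean 0, sd 1", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(zscore(c(2, 2, 2)), "zero spread")
  expect_error(zscore(c(1, NA, NA)), "at least 2")
  set.seed(104)
  x <- rnorm(50)
  z <- zscore(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  # NA entries pass through without contributing
  x[c(3, 7)] <- NA
  z <- zscore(x)
  expect_true(all(is.na(z[c(3, 7)])))
  expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 1e-12)
})

test_that("log2_pi_ratio handles zero-diversity windows by flagging", {
  expect_equal(log2_pi_ratio(0.002, 0.002), 0)
  expect_equal(log2_pi_ratio(0.004, 0.001), 2)
  expect_true(is.na(log2_pi_ratio(0.001, 0)))
  expect_true(is.na(log2_pi_ratio(0, 0.001)))
  expect_error(log2_pi_ratio(-1, 1), "nonnegative")
})

test_that("dosage_r2 is the squared Pearson correlation of dosages", {
  g <- c(0L, 1L, 2L, 0L, 1L)
  expect_equal(dosage_r2(g, g), 1)
  expect_equal(dosage_r2(g, 2L - g), 1)
  expect_equal(dosage_r2(c(0, 0, 1, 2), c(0, 1, 1, 2)),
               oracle_r2(c(0, 0, 1, 2), c(0, 1, 1, 2)))
  expect_equal(dosage_r2(c(0, 0, 1, 2), c(0, 1, 1, 2)), 8 / 11)
  expect_true(is.na(dosage_r2(c(1, 1, 1), c(0, 1, 2))))
  expect_true(is.na(dosage_r2(c(0, NA, 1), c(NA, 1, 2))))
  set.seed(105)
  for (rep in 1:50) {
    g1 <- rbinom(20, 2, 0.4); g2 <- rbinom(20, 2, 0.6)
    g1[sample(20, 3)] <- NA
    expect_equal(dosage_r2(g1, g2), oracle_r2(g1, g2), tolerance = 1e-12)
  }
})

test_that("ld_decay bins same-contig pairs by distance", {
  set.seed(106)
  d <- matrix(rbinom(18, 2, 0.5), nrow = 6)
  gm <- gm_from_dosage(d, pos = c(100L, 200L, 10000L),
                       contig_len = 20000)
  out <- ld_decay(gm, "popA", max_dist = 10000, bin_width = 1000)
  expect_equal(nrow(out), 10)
  expect_equal(out$n_pairs[1], 1L)   # the (100, 200) pair
  expect_equal(out$n_pairs[10], 2L)  # (100, 10000) and (200, 10000)
  expect_equal(sum(out$n_pairs), 3L)
  expect_true(all(is.na(out$mean_r2[out$n_pairs == 0])))
  # a single variant yields an empty table
  gm1 <- gm_from_dosage(d[, 1, drop = FALSE], pos = 100L)
  expect_equal(sum(ld_decay(gm1, "popA", 10000, 1000)$n_pairs), 0L)
})

test_that("r2 between independent loci scales as roughly 1/n", {
  set.seed(107)
  mean_r2_at_n <- function(n) {
    d <- matrix(rbinom(n * 60, 2, 0.5), nrow = n)
    gm <- gm_from_dosage(d, pos = seq_len(60) * 100L, contig_len = 10000)
    out <- ld_decay(gm, "popA", max_dist = 10000, bin_width = 10000)
    sum(out$mean_r2 * out$n_pairs, na.rm = TRUE) / sum(out$n_pairs)
  }
  m10 <- mean_r2_at_n(10)
  m40 <- mean_r2_at_n(40)
  expect_lt(abs(m10 - 1 / 10) / (1 / 10), 0.5)
  expect_lt(abs(m40 - 1 / 40) / (1 / 40), 0.5)
  expect_lt(m40, m10)  # sampling noise shrinks with n
})
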