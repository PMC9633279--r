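test_that("balding_nichols_freqs has the Beta mean and variance", {
  expect_error(balding_nichols_freqs(0.5, 0), "strictly")
  expect_error(balding_nichols_freqs(0.5, 1), "strictly")
  expect_error(balding_nichols_freqs(1.2, 0.1), "strictly")
  set.seed(501)
  draws <- balding_nichols_freqs(rep(0.5, 1e5), 0.1, 1)[, 1]
  expect_lt(abs(mean(draws) - 0.5), 0.01)
  expect_lt(abs(var(draws) - 0.5 * 0.5 * 0.1) / (0.5 * 0.5 * 0.1), 0.1)
  # small F concentrates on the ancestral frequency
  tight <- balding_nichols_freqs(rep(0.3, 1e4), 0.001, 1)[, 1]
  expect_lt(sd(tight), 0.02)
  # populations are drawn independently
  two <- balding_nichols_freqs(rep(0.5, 1e4), 0.2, 2)
  expect_lt(abs(cor(two[, 1], two[, 2])), 0.05)
})

test_that("plant_sweep pushes in-region frequencies toward fixation", {
  set.seed(502)
  m <- 500
  pos <- seq_len(m) * 100L
  p_anc <- runif(m, 0.05, 0.95)
  freqs <- balding_nichols_freqs(p_anc, 0.1, 2)
  colnames(freqs) <- c("pop1", "pop2")
  sweep <- list(contig = "chr1", start = 10000, end = 30000,
                F_sweep = 0.6, fixation_push = 1, swept_population = "pop1")
  out <- plant_sweep(freqs, p_anc, rep("chr1", m), pos, sweep)
  inr <- pos >= 10000 & pos <= 30000
  expect_true(all(out[inr, "pop1"] %in% c(0, 1)))
  expect_equal(out[!inr, ], freqs[!inr, ])      # outside untouched
  expect_equal(out[, "pop2"], freqs[, "pop2"])  # other population untouched
  # region without SNPs: warning, no-op
  sweep_empty <- sweep; sweep_empty$start <- 60000; sweep_empty$end <- 61000
  expect_warning(out2 <- plant_sweep(freqs, p_anc, rep("chr1", m), pos,
                                     sweep_empty), "no SNPs")
  expect_equal(out2, freqs)
})

test_that("push = 0 with the background F leaves the distribution alone", {
  set.seed(503)
  m <- 5000
  p_anc <- runif(m, 0.05, 0.95)
  freqs <- balding_nichols_freqs(p_anc, 0.1, 2)
  colnames(freqs) <- c("pop1", "pop2")
  sweep <- list(contig = "chr1", start = 1, end = m * 100,
                F_sweep = 0.1, fixation_push = 0, swept_population = "pop1")
  out <- plant_sweep(freqs, p_anc, rep("chr1", m), seq_len(m) * 100L, sweep)
  # redrawn values, same law: compare distributions, not values
  ks <- suppressWarnings(ks.test(out[, "pop1"], freqs[, "pop1"]))
  expect_gt(ks$p.value, 0.001)
})

test_that("the default sweep collapses expected heterozygosity >= 5-fold", {
  set.seed(504)
  ratios <- numeric(20)
  for (r in 1:20) {
    m <- 500
    p_anc <- runif(m, 0.05, 0.95)
    freqs <- balding_nichols_freqs(p_anc, 0.1, 2)
    colnames(freqs) <- c("pop1", "pop2")
    sweep <- list(contig = "chr1", start = 1, end = 10000,
                  F_sweep = 0.6, fixation_push = 0.9,
                  swept_population = "pop1")
    pos <- seq_len(m) * 100L
    out <- plant_sweep(freqs, p_anc, rep("chr1", m), pos, sweep)
    inr <- pos <= 10000
    het_in <- mean(2 * out[inr, "pop1"] * (1 - out[inr, "pop1"]))
    het_bg <- mean(2 * freqs[!inr, "pop1"] * (1 - freqs[!inr, "pop1"]))
    ratios[r] <- het_bg / het_in
  }
  expect_gte(mean(ratios), 5)
})

test_that("sample_genotypes draws HWE genotypes with missingness", {
  expect_error(sample_genotypes(cbind(pop1 = 0.5), c(pop1 = 0)), "positive")
  set.seed(505)
  # p = 0: everything reference
  g0 <- sample_genotypes(cbind(pop1 = rep(0, 50)), c(pop1 = 20))
  expect_true(all(g0$dosage == 0L))
  # p = 0.5, n = 1e4: genotype proportions near 1/4, 1/2, 1/4
  g <- sample_genotypes(cbind(pop1 = 0.5), c(pop1 = 10000))
  props <- tabulate(g$dosage + 1L, 3) / 10000
  expect_true(all(abs(props - c(0.25, 0.5, 0.25)) < 0.02))
  # missingness hits the requested fraction of cells
  gm <- sample_genotypes(cbind(pop1 = rep(0.5, 100)), c(pop1 = 1000),
                         missing_rate = 0.1)
  expect_lt(abs(mean(is.na(gm$dosage)) - 0.1), 0.01)
})

test_that("per-population HWE holds at simulated loci", {
  set.seed(506)
  cfg <- sim_config(seed = 99, n_snps = 4000, contigs = c(chr1 = 2e6),
                    sweep = NULL, deletion_loci = NULL, missing_rate = 0)
  gm <- simulate_dataset(cfg)$gm
  d <- gm$dosage[gm$meta$population == "pop1", ]
  stat <- vapply(seq_len(ncol(d)), function(j) {
    g <- d[, j]
    p <- mean(g) / 2
    if (p == 0 || p == 1) return(0)
    exp_n <- length(g) * c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs_n <- tabulate(g + 1L, 3)
    sum((obs_n - exp_n)^2 / exp_n)
  }, numeric(1))
  # 1 df goodness-of-fit; alpha = 0.001
  expect_gte(mean(stat < qchisq(0.999, df = 1)), 0.99)
})

test_that("simulate_trait builds the stated linear model", {
  set.seed(507)
  gm <- assoc_gm(40)
  trait0 <- list(name = "t0", b0 = 5, sex_effect = 0,
                 batch_effects = c(b1 = 0, b2 = 0), residual_sd = 0,
                 interaction = 0)
  loci <- data.frame(id = "locus1", effect = 1)
  out <- simulate_trait(gm, trait0, loci)
  expect_equal(out$meta$t0 - 5, as.numeric(gm$dosage[, "locus1"]))
  # missing causal dosage gives a missing trait
  gm$dosage[3, 1] <- NA
  out2 <- simulate_trait(gm, trait0, loci)
  expect_true(is.na(out2$meta$t0[3]))
  expect_error(simulate_trait(gm, trait0, data.frame(id = "zzz", effect = 1)),
               "not found")
})

test_that("planted single-locus effects are recovered without bias", {
  set.seed(508)
  est <- numeric(100)
  for (r in 1:100) {
    gm <- assoc_gm(500, b1 = 0.3)
    est[r] <- reported_term(associate_variant(gm, "locus1", "trait"))$estimate
  }
  expect_lt(abs(mean(est) - 0.3), 0.02)
})

test_that("simulate_dataset is deterministic and writes consistent files", {
  cfg <- sim_config(seed = 7, n_snps = 300, contigs = c(chr1 = 500000),
                    sweep = list(contig = "chr1", start = 200001,
                                 end = 250000, F_sweep = 0.6,
                                 fixation_push = 0.9,
                                 swept_population = "pop1"),
                    n_pop1 = 10, n_pop2 = 10,
                    deletion_loci = data.frame(
                      id = "del1", contig = "chr1", pos = 225000,
                      freq_pop1 = 0.8, freq_pop2 = 0.1, effect = 0.3,
                      stringsAsFactors = FALSE))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  out1 <- simulate_dataset(cfg, out_dir = d1)
  out2 <- simulate_dataset(cfg, out_dir = d2)
  expect_identical(readLines(out1$paths$vcf), readLines(out2$paths$vcf))
  expect_identical(out1$gm$meta, out2$gm$meta)
  # variant count = SNPs + deletion loci
  expect_equal(nrow(out1$gm$variants), 301)
  # the truth file round-trips
  truth <- jsonlite::read_json(out1$paths$truth, simplifyVector = TRUE)
  expect_equal(truth$sweep$start, 200001)
  expect_equal(truth$deletion_loci$effect, 0.3)
  # written files reload into the same dataset
  gm_back <- read_vcf(out1$paths$vcf)
  gm_back <- attach_metadata(gm_back, read_sample_metadata(out1$paths$meta))
  expect_identical(unname(gm_back$dosage), unname(out1$gm$dosage))
  genes <- read_bed_genes(out1$paths$bed)
  expect_identical(genes$gene_id, out1$genes$gene_id)
  expect_identical(genes$start, out1$genes$start)
  expect_identical(genes$end, out1$genes$end)
})

test_that("no-sweep scans show no directional artifacts", {
  set.seed(509)
  cfg <- sim_config(seed = 17, n_snps = 5000, contigs = c(chr1 = 3e6),
                    sweep = NULL, deletion_loci = NULL)
  gm <- simulate_dataset(cfg)$gm
  st <- scan_windows(gm, "pop1", "pop2")
  expect_lt(abs(mean(st$zfst, na.rm = TRUE)), 0.05)
  # Tajima's D shows no positional trend: slope CI covers 0.
  # Nonoverlapping windows, since overlapping ones share SNPs and the
  # induced autocorrelation would invalidate the OLS interval.
  st_ind <- scan_windows(gm, "pop1", "pop2",
                         window_spec(150000, 150000, 10))
  fit <- lm(tajd_a ~ start, data = as.data.frame(st_ind))
  ci <- confint(fit)["start", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})
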