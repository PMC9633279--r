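# In-code fixture builders shared across test files.

# random two-population genotype matrix on one contig
random_gm <- function(n_per_pop = 10, n_variants = 20, missing_rate = 0.05,
                      contig_len = 100000) {
  n <- 2 * n_per_pop
  pos <- sort(sample.int(contig_len, n_variants))
  p <- runif(n_variants, 0.1, 0.9)
  dosage <- matrix(rbinom(n * n_variants, 2, rep(p, each = n)), nrow = n)
  if (missing_rate > 0)
    dosage[runif(length(dosage)) < missing_rate] <- NA_integer_
  rownames(dosage) <- sprintf("s%02d", seq_len(n))
  variants <- data.frame(
    chrom = "chr1", pos = pos, id = sprintf("v%03d", seq_len(n_variants)),
    ref = "A", alt = "G", multiallelic = FALSE, stringsAsFactors = FALSE)
  meta <- data.frame(
    sample = rownames(dosage),
    population = rep(c("popA", "popB"), each = n_per_pop),
    sex = sample(c("F", "M"), n, replace = TRUE),
    batch = sample(c("b1", "b2"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  genotype_matrix(dosage, variants, meta = meta,
                  contigs = c(chr1 = contig_len))
}

# genotype matrix from an explicit dosage matrix (samples x variants)
gm_from_dosage <- function(dosage, pos = NULL, populations = NULL,
                           contig_len = NULL) {
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 10L
  if (is.null(contig_len)) contig_len <- max(pos) + 10
  if (is.null(rownames(dosage)) || anyDuplicated(rownames(dosage)))
    rownames(dosage) <- sprintf("s%02d", seq_len(n))
  variants <- data.frame(
    chrom = "chr1", pos = as.integer(pos),
    id = sprintf("v%03d", seq_len(m)), ref = "A", alt = "G",
    multiallelic = FALSE, stringsAsFactors = FALSE)
  meta <- data.frame(
    sample = rownames(dosage),
    population = if (is.null(populations)) rep("popA", n) else populations,
    sex = rep(c("F", "M"), length.out = n),
    batch = rep(c("b1", "b2"), length.out = n),
    stringsAsFactors = FALSE)
  genotype_matrix(dosage, variants, meta = meta,
                  contigs = c(chr1 = contig_len))
}

# minimal two-locus dataset for association fits
assoc_gm <- function(n, p1 = 0.3, p2 = 0.4, b1 = 0, b2 = 0, b12 = 0,
                     sd = 1, b0 = 10, sex_eff = 0.5, batch_eff = 0.3) {
  g1 <- rbinom(n, 2, p1)
  g2 <- rbinom(n, 2, p2)
  sex <- sample(rep(c("F", "M"), length.out = n))
  batch <- sample(rep(c("b1", "b2"), length.out = n))
  y <- b0 + b1 * g1 + b2 * g2 + b12 * g1 * g2 +
    sex_eff * (sex == "M") + batch_eff * (batch == "b2") + rnorm(n, 0, sd)
  dosage <- cbind(g1, g2)
  rownames(dosage) <- sprintf("s%04d", seq_len(n))
  variants <- data.frame(
    chrom = "chr1", pos = c(100L, 200L), id = c("locus1", "locus2"),
    ref = "N", alt = "<DEL>", multiallelic = FALSE, stringsAsFactors = FALSE)
  meta <- data.frame(sample = rownames(dosage), population = "popA",
                     sex = sex, batch = batch, trait = y,
                     stringsAsFactors = FALSE)
  genotype_matrix(dosage, variants, meta = meta, contigs = c(chr1 = 1000))
}

write_tsv_fixture <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
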