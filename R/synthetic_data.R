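#' Simulation configuration for the two-population generator
#'
#' Bundles every knob of the synthetic dataset: two populations with
#' Balding-Nichols background differentiation, one locally swept region
#' in the focal population, and one or more biallelic deletion loci
#' whose dosage shifts a quantitative trait with sex and batch
#' covariates (and an optional two-locus interaction).  The defaults
#' are the study conditions used throughout the package's tests: 50+50
#' individuals, 20,000 SNPs on a 10-Mb contig, background F = 0.10, a
#' 1-Mb sweep (F_sweep = 0.6, fixation push 0.9) in `pop1`, and two
#' deletion loci of 0.3 trait units per copy.
#'
#' @param seed integer RNG seed; all outputs are pure functions of the
#'   config including this seed.
#' @param n_pop1,n_pop2 individuals per population.
#' @param contigs named numeric vector of contig lengths (bp).
#' @param n_snps number of background SNPs.
#' @param F_background Balding-Nichols differentiation in (0, 1).
#' @param sweep list: `contig`, `start`, `end`, `F_sweep`,
#'   `fixation_push` in `[0, 1]`, `swept_population`; `NULL` for no
#'   sweep.
#' @param deletion_loci data.frame: `id`, `contig`, `pos`, `freq_pop1`,
#'   `freq_pop2`, `effect` (trait units per deletion copy).
#' @param trait list: `name`, `b0` (intercept), `sex_effect` (added for
#'   males), `batch_effects` (named, first is the reference),
#'   `residual_sd`, `interaction` (effect of the product of the first
#'   two deletion dosages; 0 disables).
#' @param missing_rate per-cell missing-call probability in `[0, 1)`.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_pop1 = 50, n_pop2 = 50,
                       contigs = c(chr1 = 10e6),
                       n_snps = 20000,
                       F_background = 0.10,
                       sweep = list(contig = "chr1", start = 4850001,
                                    end = 5150000, F_sweep = 0.6,
                                    fixation_push = 0.9,
                                    swept_population = "pop1"),
                       deletion_loci = data.frame(
                         id = c("del_sweep", "del_distal"),
                         contig = "chr1",
                         pos = c(5000000, 8000000),
                         freq_pop1 = c(0.80, 0.60),
                         freq_pop2 = c(0.10, 0.20),
                         effect = c(0.3, 0.3),
                         stringsAsFactors = FALSE),
                       trait = list(name = "trait", b0 = 15,
                                    sex_effect = 0.5,
                                    batch_effects = c(batch1 = 0,
                                                      batch2 = 0.3),
                                    residual_sd = 1,
                                    interaction = 0),
                       missing_rate = 0.02) {
  stopifnot(n_pop1 > 0, n_pop2 > 0, n_snps > 0,
            F_background > 0, F_background < 1,
            missing_rate >= 0, missing_rate < 1,
            trait$residual_sd > 0)
  if (!is.null(sweep)) {
    stopifnot(sweep$contig %in% names(contigs),
              sweep$start >= 1, sweep$end <= contigs[[sweep$contig]],
              sweep$start < sweep$end,
              sweep$F_sweep > 0, sweep$F_sweep < 1,
              sweep$fixation_push >= 0, sweep$fixation_push <= 1,
              sweep$swept_population %in% c("pop1", "pop2"))
  }
  if (!is.null(deletion_loci) && nrow(deletion_loci) > 0) {
    stopifnot(all(deletion_loci$contig %in% names(contigs)),
              all(deletion_loci$freq_pop1 >= 0 & deletion_loci$freq_pop1 <= 1),
              all(deletion_loci$freq_pop2 >= 0 & deletion_loci$freq_pop2 <= 1))
  }
  structure(list(seed = as.integer(seed), n_pop1 = n_pop1, n_pop2 = n_pop2,
                 contigs = contigs, n_snps = n_snps,
                 F_background = F_background, sweep = sweep,
                 deletion_loci = deletion_loci, trait = trait,
                 missing_rate = missing_rate),
            class = "sim_config")
}

#' Balding-Nichols population allele frequencies
#'
#' Draws each population's frequency from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`, independently per
#' population: mean `p`, variance `p (1 - p) F`.  Uses the R global
#' RNG; seed upstream.
#'
#' @param p_anc ancestral allele frequency vector, each in (0, 1).
#' @param F differentiation coefficient in (0, 1).
#' @param n_pops number of populations.
#' @return matrix `length(p_anc)` x `n_pops` of frequencies.
#' @export
balding_nichols_freqs <- function(p_anc, F, n_pops = 2) {
  if (F <= 0 || F >= 1)
    stop("F must lie strictly in (0, 1); the Beta is degenerate at 0 or 1")
  if (any(p_anc <= 0 | p_anc >= 1))
    stop("ancestral frequencies must lie strictly in (0, 1)")
  k <- (1 - F) / F
  m <- length(p_anc)
  out <- matrix(NA_real_, m, n_pops)
  for (pop in seq_len(n_pops))
    out[, pop] <- stats::rbeta(m, p_anc * k, (1 - p_anc) * k)
  out
}

#' Plant a selective sweep into population frequencies
#'
#' For SNPs inside the sweep region, the swept population's frequency
#' is redrawn with the (much larger) sweep differentiation `F_sweep`
#' around the ancestral frequency, then pushed toward the nearer of 0
#' or 1 by the fixation factor: `p' = p (1 - push)` when `p < 0.5`,
#' else `1 - (1 - p)(1 - push)`.  With `push = 1` in-region
#' frequencies become exactly 0 or 1; diversity collapses locally while
#' differentiation rises — the classic sweep signature.
#'
#' @param freqs matrix from [balding_nichols_freqs()] with population
#'   columns named.
#' @param p_anc ancestral frequencies (same length as rows of `freqs`).
#' @param chrom,pos per-SNP coordinates.
#' @param sweep the sweep component of [sim_config()].
#' @return `freqs` with the swept population's column modified inside
#'   the region.
#' @export
plant_sweep <- function(freqs, p_anc, chrom, pos, sweep) {
  in_region <- chrom == sweep$contig & pos >= sweep$start & pos <= sweep$end
  if (!any(in_region)) {
    warning("sweep region contains no SNPs; nothing planted")
    return(freqs)
  }
  col <- match(sweep$swept_population, colnames(freqs))
  if (is.na(col)) stop("swept population not found among frequency columns")
  p <- balding_nichols_freqs(p_anc[in_region], sweep$F_sweep, 1)[, 1]
  push <- sweep$fixation_push
  p <- ifelse(p < 0.5, p * (1 - push), 1 - (1 - p) * (1 - push))
  freqs[in_region, col] <- p
  freqs
}

#' Sample genotypes from population frequencies
#'
#' Dosage is Binomial(2, p_pop) per individual (Hardy-Weinberg within
#' population); cells are then knocked out to missing independently
#' with `missing_rate`.
#'
#' @param freqs SNPs x populations frequency matrix, columns named.
#' @param n_per_pop named integer vector of sample sizes, names
#'   matching `colnames(freqs)`.
#' @param missing_rate per-cell missing probability.
#' @return list: `dosage` (samples x SNPs integer matrix, rownames
#'   `<pop>_<k>`), `population` (per-sample labels).
#' @export
sample_genotypes <- function(freqs, n_per_pop, missing_rate = 0) {
  if (any(n_per_pop <= 0)) stop("sample sizes must be positive")
  if (any(freqs < 0 | freqs > 1)) stop("frequencies must lie in [0, 1]")
  m <- nrow(freqs)
  blocks <- lapply(names(n_per_pop), function(pop) {
    n <- n_per_pop[[pop]]
    p <- freqs[, pop]
    matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n)
  })
  dosage <- do.call(rbind, blocks)
  storage.mode(dosage) <- "integer"
  population <- rep(names(n_per_pop), times = n_per_pop)
  rownames(dosage) <- paste0(population, "_",
                             unlist(lapply(n_per_pop, seq_len)))
  if (missing_rate > 0) {
    drop <- stats::runif(length(dosage)) < missing_rate
    dosage[drop] <- NA_integer_
  }
  list(dosage = dosage, population = population)
}

#' Simulate a quantitative trait from deletion dosages
#'
#' `y = b0 + sum(b_k g_k) + b12 g1 g2 + sex_effect 1[male] +
#' batch_effect[batch] + e`, with Gaussian residuals.  Samples with a
#' missing dosage at any causal locus get a missing trait (their
#' genetic value is unknown).
#'
#' @param gm a [genotype_matrix()] with metadata carrying `sex` and
#'   `batch`.
#' @param trait the trait component of [sim_config()].
#' @param deletion_loci data.frame with `id` and `effect` columns.
#' @return the genotype matrix with the trait column added to `$meta`.
#' @export
simulate_trait <- function(gm, trait, deletion_loci) {
  idx <- match(deletion_loci$id, gm$variants$id)
  if (anyNA(idx))
    stop("causal locus not found: ",
         deletion_loci$id[is.na(idx)][1])
  G <- gm$dosage[, idx, drop = FALSE]
  n <- nrow(G)
  genetic <- as.numeric(G %*% deletion_loci$effect)
  b12 <- trait$interaction
  if (!is.null(b12) && b12 != 0) {
    if (length(idx) < 2)
      stop("interaction effect needs at least two deletion loci")
    genetic <- genetic + b12 * G[, 1] * G[, 2]
  }
  be <- trait$batch_effects
  y <- trait$b0 + genetic +
    trait$sex_effect * (gm$meta$sex == "M") +
    unname(be[gm$meta$batch]) +
    stats::rnorm(n, 0, trait$residual_sd)
  y[apply(is.na(G), 1, any)] <- NA_real_
  gm$meta[[trait$name]] <- y
  gm
}

#' Simulate a complete two-population dataset
#'
#' Orchestrates the generator deterministically from the config seed:
#' ancestral frequencies Uniform(0.05, 0.95); SNP positions uniform
#' without replacement per contig (deletion positions excluded), then
#' sorted; Balding-Nichols background frequencies; the planted sweep;
#' deletion loci appended at their configured per-population
#' frequencies; HWE genotype sampling with missingness; balanced
#' random sex (F/M) and batch labels; the simulated trait; and three
#' fixture genes for annotation tests — one inside the sweep region,
#' one 250-300 kb beyond its end, one 800-850 kb beyond.
#'
#' When `out_dir` is given, writes `genotypes.vcf`, `samples.tsv`,
#' `genes.bed` and `truth.json` (the planted parameters for recovery
#' testing) and records the paths in the result.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory (created if needed).
#' @return list: `gm` (genotype matrix with metadata and trait),
#'   `genes` (fixture annotation), `truth` (planted parameters),
#'   `paths` (when written).
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  del <- config$deletion_loci
  # SNP coordinates, avoiding deletion positions
  chroms <- names(config$contigs)
  alloc <- table(factor(
    sample(chroms, config$n_snps, replace = TRUE,
           prob = config$contigs / sum(config$contigs)),
    levels = chroms))
  pos_list <- lapply(chroms, function(chr) {
    n <- alloc[[chr]]
    taken <- if (is.null(del)) integer(0) else del$pos[del$contig == chr]
    repeat {
      p <- sort(sample.int(config$contigs[[chr]], n))
      if (!any(p %in% taken)) return(p)
    }
  })
  chrom <- rep(chroms, times = vapply(pos_list, length, 1L))
  pos <- unlist(pos_list)
  p_anc <- stats::runif(length(pos), 0.05, 0.95)
  freqs <- balding_nichols_freqs(p_anc, config$F_background, 2)
  colnames(freqs) <- c("pop1", "pop2")
  if (!is.null(config$sweep))
    freqs <- plant_sweep(freqs, p_anc, chrom, pos, config$sweep)
  variants <- data.frame(
    chrom = chrom, pos = pos,
    id = sprintf("snp%05d", seq_along(pos)),
    ref = "A", alt = "G", multiallelic = FALSE,
    stringsAsFactors = FALSE)
  if (!is.null(del) && nrow(del) > 0) {
    variants <- rbind(variants, data.frame(
      chrom = del$contig, pos = del$pos, id = del$id,
      ref = "N", alt = "<DEL>", multiallelic = FALSE,
      stringsAsFactors = FALSE))
    freqs <- rbind(freqs, as.matrix(del[, c("freq_pop1", "freq_pop2")],
                                    dimnames = NULL))
    colnames(freqs) <- c("pop1", "pop2")
  }
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  freqs <- freqs[ord, , drop = FALSE]
  sg <- sample_genotypes(freqs, c(pop1 = config$n_pop1,
                                  pop2 = config$n_pop2),
                         config$missing_rate)
  n <- nrow(sg$dosage)
  meta <- data.frame(
    sample = rownames(sg$dosage),
    population = sg$population,
    sex = sample(rep(c("F", "M"), length.out = n)),
    batch = sample(rep(names(config$trait$batch_effects),
                       length.out = n)),
    stringsAsFactors = FALSE)
  gm <- genotype_matrix(sg$dosage, variants, meta = meta,
                        contigs = config$contigs)
  if (!is.null(del) && nrow(del) > 0)
    gm <- simulate_trait(gm, config$trait, del)
  genes <- fixture_genes(config)
  truth <- list(
    seed = config$seed,
    sweep = config$sweep,
    deletion_loci = if (is.null(del)) NULL else del,
    interaction = config$trait$interaction,
    trait = config$trait[c("name", "b0", "sex_effect", "residual_sd")])
  out <- list(gm = gm, genes = genes, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      vcf = file.path(out_dir, "genotypes.vcf"),
      meta = file.path(out_dir, "samples.tsv"),
      bed = file.path(out_dir, "genes.bed"),
      truth = file.path(out_dir, "truth.json"))
    write_vcf(gm, paths$vcf)
    utils::write.table(gm$meta, paths$meta, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                       genes$chrom, genes$start - 1L, genes$end,
                       genes$gene_id, genes$strand),
               paths$bed)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE,
                         digits = NA)
    out$paths <- paths
  }
  out
}

# three fixture genes keyed to the sweep region (or contig midpoint
# when no sweep is configured): inside / within 500 kb / beyond 500 kb
fixture_genes <- function(config) {
  if (!is.null(config$sweep)) {
    chr <- config$sweep$contig
    mid <- floor((config$sweep$start + config$sweep$end) / 2)
    sweep_end <- config$sweep$end
  } else {
    chr <- names(config$contigs)[1]
    mid <- floor(config$contigs[[1]] / 2)
    sweep_end <- mid
  }
  data.frame(
    gene_id = c("gene_in_sweep", "gene_near", "gene_far"),
    chrom = chr,
    start = as.integer(c(mid - 25000, sweep_end + 250001,
                         sweep_end + 800001)),
    end = as.integer(c(mid + 25000, sweep_end + 300000,
                       sweep_end + 850000)),
    strand = ".",
    stringsAsFactors = FALSE)
}
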