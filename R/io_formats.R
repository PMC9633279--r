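#' Read a VCF into a genotype matrix
#'
#' Parses diploid GT fields into alt-allele dosage codes.  `./.` and
#' half-calls (e.g. `./1`) become missing; phased separators `|` are
#' treated like `/`.  Multiallelic records are retained and flagged so
#' that [filter_variants()] can drop them later; their dosage is the
#' count of non-reference alleles.
#'
#' @param path path to a VCF 4.x file (plain or bgzipped).
#' @return a [genotype_matrix()] without sample metadata attached.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e)))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no variant records: ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  # dosage from GT strings; validate ploidy record by record
  gt_chr <- as.character(gt)
  gt_chr[is.na(gt_chr)] <- "./."
  alleles <- strsplit(gt_chr, "[/|]")
  n_all <- lengths(alleles)
  if (any(n_all != 2)) {
    bad <- which(n_all != 2)[1]
    stop("unsupported ploidy: GT '", gt_chr[bad], "' is not diploid")
  }
  amat <- matrix(unlist(alleles), nrow = 2)
  a1 <- amat[1, ]; a2 <- amat[2, ]
  half <- a1 == "." | a2 == "."
  dose <- (a1 != "0") + (a2 != "0")
  dose[half] <- NA_integer_
  dosage <- matrix(as.integer(dose), nrow = nrow(gt), ncol = ncol(gt))
  dosage <- t(dosage)                       # samples x variants
  rownames(dosage) <- samples
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos)) stop("malformed POS field in VCF record ",
                       which(is.na(pos))[1])
  ids <- fix$ID
  blank <- is.na(ids) | ids == "."
  ids[blank] <- sprintf("%s_%d", fix$CHROM[blank], pos[blank])
  variants <- data.frame(
    chrom = fix$CHROM, pos = pos, id = ids, ref = fix$REF, alt = fix$ALT,
    multiallelic = grepl(",", fix$ALT, fixed = TRUE),
    stringsAsFactors = FALSE)
  contigs <- parse_contig_lengths(vcf@meta)
  genotype_matrix(dosage, variants,
                  contigs = if (length(contigs)) contigs else NULL)
}

parse_contig_lengths <- function(meta_lines) {
  ln <- grep("^##contig=", meta_lines, value = TRUE)
  if (length(ln) == 0) return(numeric(0))
  ids <- sub('.*ID=([^,>]+).*', '\\1', ln)
  lens <- suppressWarnings(as.numeric(sub('.*length=([0-9]+).*', '\\1', ln)))
  ok <- !is.na(lens)
  stats::setNames(lens[ok], ids[ok])
}

#' Write a genotype matrix as VCF
#'
#' Emits a sorted, GT-only VCF 4.2 file.  Missing dosage becomes `./.`.
#' Multiallelic records cannot be reconstructed from dosage codes and
#' must be removed (see [filter_variants()]) before writing.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  v <- gm$variants
  if (any(v$multiallelic))
    stop("cannot write multiallelic records from dosage codes; ",
         "run filter_variants() first")
  key <- paste(v$chrom, v$pos, v$alt)
  if (anyDuplicated(key))
    stop("duplicate (chrom, pos, alt) record: ", key[duplicated(key)][1])
  gt_code <- c("0/0", "0/1", "1/1")
  body <- character(nrow(v))
  d <- gm$dosage
  for (j in seq_len(nrow(v))) {
    g <- d[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    body[j] <- paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j],
                       ".", "PASS", ".", "GT", gt), collapse = "\t")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(gm$contigs),
            as.integer(gm$contigs)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", gm$samples), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read sample metadata from a TSV file
#'
#' Expects a header with at least `sample` and `population`; optional
#' `sex` (F/M/NA), `batch` and numeric trait columns.
#'
#' @param path path to a tab-separated file with a header row.
#' @return data.frame keyed by `sample`.
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = NA, check.names = FALSE)
  req <- c("sample", "population")
  miss <- setdiff(req, names(meta))
  if (length(miss) > 0)
    stop("metadata is missing required column(s): ",
         paste(miss, collapse = ", "))
  meta$sample <- as.character(meta$sample)
  if (anyDuplicated(meta$sample))
    stop("duplicate sample id: ", meta$sample[duplicated(meta$sample)][1])
  if (!is.null(meta$sex)) {
    bad <- !(meta$sex %in% c("F", "M") | is.na(meta$sex))
    if (any(bad))
      stop("sex must be 'F', 'M' or NA; got '", meta$sex[bad][1], "'")
  }
  meta
}

#' Read gene annotation from a BED file
#'
#' BED intervals (0-based, half-open) are converted to the 1-based
#' inclusive coordinates used throughout the package, so a BED line
#' `chr11 94272263 94272845 del582` yields start 94272264, end 94272845.
#' At least four columns (chrom, start, end, name) are required.
#'
#' @param path path to a BED4+ file.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_bed_genes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (length(readLines(path, n = 1)) == 0)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
  if (nrow(gr) > 0 &&
      (is.null(gr$name) || any(is.na(gr$name) | gr$name == "")))
    stop("BED gene file needs a non-empty name (4th) column")
  if (any(gr$width <= 0))
    stop("BED interval with start >= end at record ",
         which(gr$width <= 0)[1])
  out <- data.frame(
    gene_id = as.character(gr$name),
    chrom = as.character(gr$seqnames),
    start = gr$start,
    end = gr$end,
    strand = as.character(gr$strand),
    stringsAsFactors = FALSE)
  out$strand[out$strand == "*"] <- "."
  if (anyDuplicated(out$gene_id))
    stop("duplicate gene_id: ", out$gene_id[duplicated(out$gene_id)][1])
  out
}

#' Filter variants on biallelism, call rate and minor allele frequency
#'
#' Mirrors the standard resequencing-panel site filter (call rate at
#' least `max_missing_ok`, MAF at least `maf_min`, biallelic SNPs only).
#' Both thresholds are inclusive, and both statistics are computed over
#' non-missing calls only.  Loci named in `keep_ids` (e.g. structural
#' deletion loci genotyped separately) bypass the MAF filter but still
#' must be biallelic and well called.
#'
#' @param gm a [genotype_matrix()].
#' @param max_missing_ok minimum fraction of non-missing calls (default
#'   0.9).
#' @param maf_min minimum minor allele frequency among non-missing
#'   alleles (default 0.05).
#' @param keep_ids variant ids exempted from the MAF threshold.
#' @return the filtered genotype matrix; variant order is preserved.
#' @export
filter_variants <- function(gm, max_missing_ok = 0.9, maf_min = 0.05,
                            keep_ids = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosage
  called <- colSums(!is.na(d))
  call_rate <- called / nrow(d)
  alt <- colSums(d, na.rm = TRUE)
  f <- ifelse(called > 0, alt / (2 * called), NA_real_)
  maf <- pmin(f, 1 - f)
  keep <- !gm$variants$multiallelic &
    call_rate >= max_missing_ok &
    (!is.na(maf) & maf >= maf_min | gm$variants$id %in% keep_ids)
  subset_variants(gm, which(keep))
}
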