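#' Construct a genotype matrix
#'
#' The central container of the package: a samples x variants matrix of
#' dosage codes (0, 1, 2 copies of the alternate allele; `NA` = missing
#' call) together with the variant table, per-sample metadata and contig
#' lengths.  Variants are kept sorted by (chrom, pos); the dosage columns
#' are reordered to match.
#'
#' @param dosage integer matrix, samples in rows, variants in columns.
#'   Values must be 0, 1, 2 or `NA`.
#' @param variants data.frame with columns `chrom`, `pos` (1-based bp),
#'   `id`, `ref`, `alt` (comma-joined for multiallelic records) and
#'   logical `multiallelic`.
#' @param meta optional data.frame of sample metadata with at least
#'   columns `sample` and `population`; may carry `sex`, `batch` and
#'   numeric trait columns.  Attach later with [attach_metadata()] if the
#'   genotypes and metadata come from separate files.
#' @param contigs optional named numeric vector of contig lengths (bp);
#'   inferred from the largest position per contig when absent.
#' @return an object of class `genotype_matrix`: a list with elements
#'   `dosage`, `variants`, `meta`, `contigs`, `samples`.
#' @export
genotype_matrix <- function(dosage, variants, meta = NULL, contigs = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  stopifnot(is.data.frame(variants))
  req <- c("chrom", "pos", "id", "ref", "alt")
  miss <- setdiff(req, names(variants))
  if (length(miss) > 0)
    stop("variant table is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(variants$multiallelic))
    variants$multiallelic <- grepl(",", variants$alt, fixed = TRUE)
  if (ncol(dosage) != nrow(variants))
    stop("dosage has ", ncol(dosage), " columns but variant table has ",
         nrow(variants), " rows")
  if (any(variants$pos < 1)) stop("variant positions must be >= 1")
  bad <- !(dosage %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad, na.rm = TRUE)) stop("dosage codes must be 0, 1, 2 or NA")
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("sample%03d", seq_len(nrow(dosage)))
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  dosage <- dosage[, ord, drop = FALSE]
  colnames(dosage) <- variants$id
  if (is.null(contigs)) {
    contigs <- tapply(variants$pos, variants$chrom, max)
    contigs <- stats::setNames(as.numeric(contigs), names(contigs))
  }
  gm <- structure(
    list(dosage = dosage, variants = variants, meta = NULL,
         contigs = contigs, samples = rownames(dosage)),
    class = "genotype_matrix")
  if (!is.null(meta)) gm <- attach_metadata(gm, meta)
  gm
}

#' Attach sample metadata to a genotype matrix
#'
#' Joins a metadata table (see [read_sample_metadata()]) onto the samples
#' of a genotype matrix.  Every genotyped sample must be present in the
#' metadata; rows are reordered to the sample order of the matrix.
#'
#' @param gm a [genotype_matrix()].
#' @param meta data.frame with a `sample` column and a non-empty
#'   `population` column.
#' @return the genotype matrix with `$meta` filled in.
#' @export
attach_metadata <- function(gm, meta) {
  stopifnot(inherits(gm, "genotype_matrix"), is.data.frame(meta))
  if (is.null(meta$sample) || is.null(meta$population))
    stop("metadata must have columns 'sample' and 'population'")
  if (anyDuplicated(meta$sample))
    stop("duplicate sample id in metadata: ",
         meta$sample[duplicated(meta$sample)][1])
  unknown <- setdiff(gm$samples, meta$sample)
  if (length(unknown) > 0)
    stop("samples absent from metadata: ", paste(utils::head(unknown, 5),
                                                 collapse = ", "))
  meta <- meta[match(gm$samples, meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  if (any(is.na(meta$population) | meta$population == ""))
    stop("every sample needs a non-empty population label")
  gm$meta <- meta
  gm
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x",
      ncol(x$dosage), "variants\n")
  cat("contigs:", paste(names(x$contigs), collapse = ", "), "\n")
  if (!is.null(x$meta)) {
    tab <- table(x$meta$population)
    cat("populations:",
        paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
  } else {
    cat("populations: <no metadata attached>\n")
  }
  invisible(x)
}

# row indices of one population; errors on unknown labels
pop_rows <- function(gm, population) {
  if (is.null(gm$meta))
    stop("no sample metadata attached; use attach_metadata()")
  idx <- which(gm$meta$population == population)
  if (length(idx) == 0)
    stop("unknown population label: ", population)
  idx
}

variant_index <- function(gm, variant_id) {
  idx <- match(variant_id, gm$variants$id)
  if (is.na(idx)) stop("variant not found: ", variant_id)
  idx
}

# subset variants by column index, keeping everything consistent
subset_variants <- function(gm, keep) {
  gm$dosage <- gm$dosage[, keep, drop = FALSE]
  gm$variants <- gm$variants[keep, , drop = FALSE]
  rownames(gm$variants) <- NULL
  gm
}
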