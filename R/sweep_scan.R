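#' Window specification for the genome scan
#'
#' Defaults mirror the standard sliding-window sweep scan: 150-kb
#' windows advanced in 10-kb increments, with windows carrying fewer
#' than `min_snps` usable SNPs flagged and excluded from ranking.
#'
#' @param size window size in bp.
#' @param step window step in bp (`size >= step >= 1`).
#' @param min_snps minimum usable SNPs for a window to be retained.
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(size = 150000, step = 10000, min_snps = 10) {
  stopifnot(size >= step, step >= 1, min_snps >= 1)
  structure(list(size = as.integer(size), step = as.integer(step),
                 min_snps = as.integer(min_snps)),
            class = "window_spec")
}

#' Tile contigs into scan windows
#'
#' Windows start at `1 + k * step` and are kept only when they fit
#' entirely inside the contig (`start + size - 1 <= length`).  Contigs
#' shorter than one window contribute no windows (with a warning).
#'
#' @param contigs named numeric vector of contig lengths (bp).
#' @param spec a [window_spec()].
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive).
#' @export
make_windows <- function(contigs, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  out <- lapply(names(contigs), function(chr) {
    L <- contigs[[chr]]
    if (L < spec$size) {
      warning("contig ", chr, " (", L, " bp) is shorter than one window")
      return(NULL)
    }
    k <- 0:floor((L - spec$size) / spec$step)
    starts <- 1 + k * spec$step
    data.frame(chrom = chr, start = starts,
               end = starts + spec$size - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  out
}

#' Two-population selective-sweep window scan
#'
#' For every window, computes per-bp diversity in both populations,
#' weighted Weir-Cockerham Fst (ratio of summed variance components),
#' Tajima's D per population, the focal/reference log2 diversity ratio
#' (`pop_a` is the focal numerator) and, after the whole genome is
#' scanned, the genome-wide Z-transform of Fst over retained windows.
#'
#' Flags: `BELOW_MIN_SNPS` — fewer than `spec$min_snps` SNPs or no
#' usable Fst; such windows get no Z-score and are excluded from
#' outlier ranking.  `RATIO_UNDEFINED` — one of the diversities is zero
#' so the log2 ratio does not exist.
#'
#' @param gm a [genotype_matrix()] with metadata attached.
#' @param pop_a focal population label (e.g. the selected line).
#' @param pop_b reference population label.
#' @param spec a [window_spec()].
#' @return data.frame of class `window_stats` with columns `chrom`,
#'   `start`, `end`, `n_snps`, `pi_a`, `pi_b`, `fst`, `zfst`,
#'   `log2_ratio`, `tajd_a`, `tajd_b`, `flags`.
#' @export
scan_windows <- function(gm, pop_a, pop_b, spec = window_spec()) {
  ia <- pop_rows(gm, pop_a)
  ib <- pop_rows(gm, pop_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("each population needs at least 2 individuals")
  windows <- make_windows(gm$contigs, spec)
  if (nrow(windows) == 0)
    stop("no contig long enough for a single window")
  ss <- site_stats(gm, pop_a, pop_b)
  size <- spec$size
  out <- windows
  out$n_snps <- 0L
  out$pi_a <- 0; out$pi_b <- 0
  out$fst <- NA_real_
  out$tajd_a <- NA_real_; out$tajd_b <- NA_real_
  for (chr in unique(windows$chrom)) {
    wi <- which(windows$chrom == chr)
    si <- which(ss$chrom == chr)
    rg <- window_site_ranges(ss$pos[si], windows$start[wi], windows$end[wi])
    out$n_snps[wi] <- rg$n
    out$pi_a[wi] <- range_sum(ss$pi_a[si], rg$lo, rg$hi) / size
    out$pi_b[wi] <- range_sum(ss$pi_b[si], rg$lo, rg$hi) / size
    num <- range_sum(ss$wc_a[si], rg$lo, rg$hi)
    den <- range_sum(ss$wc_d[si], rg$lo, rg$hi)
    out$fst[wi] <- ifelse(den != 0, num / den, NA_real_)
    # Tajima's D needs a per-window minimum-n, so slice per window
    for (k in seq_along(wi)) {
      if (rg$n[k] == 0) next
      sel <- si[rg$lo[k]:rg$hi[k]]
      out$tajd_a[wi[k]] <- window_tajd(ss$n_a[sel], ss$pi_a[sel], ss$seg_a[sel])
      out$tajd_b[wi[k]] <- window_tajd(ss$n_b[sel], ss$pi_b[sel], ss$seg_b[sel])
    }
  }
  out$log2_ratio <- log2_pi_ratio(out$pi_a, out$pi_b)
  flags <- character(nrow(out))
  low <- out$n_snps < spec$min_snps | is.na(out$fst)
  flags[low] <- "BELOW_MIN_SNPS"
  und <- !low & is.na(out$log2_ratio)
  flags[und] <- "RATIO_UNDEFINED"
  out$flags <- flags
  out$zfst <- NA_real_
  retained <- !low
  if (sum(retained) >= 2 && stats::sd(out$fst[retained]) > 0)
    out$zfst[retained] <- zscore(out$fst[retained])
  out <- out[, c("chrom", "start", "end", "n_snps", "pi_a", "pi_b",
                 "fst", "zfst", "log2_ratio", "tajd_a", "tajd_b", "flags")]
  attr(out, "window_spec") <- spec
  attr(out, "populations") <- c(focal = pop_a, reference = pop_b)
  class(out) <- c("window_stats", "data.frame")
  out
}

window_tajd <- function(n, pi, seg) {
  usable <- n >= 2
  if (!any(usable)) return(NA_real_)
  tajima_d_value(sum(seg[usable]), sum(pi[usable]), min(n[usable]))
}

#' Call joint top-quantile outlier windows
#'
#' Thresholds are the `(1 - q)` quantiles (linear-interpolation type 7)
#' of ZFst and of `|log2 ratio|` over retained windows; outliers are the
#' windows reaching both thresholds simultaneously (ties included).
#' Overlapping or nearly adjacent outlier windows are merged into sweep
#' regions.
#'
#' @param stats a `window_stats` table from [scan_windows()].
#' @param q upper tail mass (default 0.01, the top 1 percent).
#' @param max_gap maximum bp gap between outlier windows merged into
#'   one region; defaults to the scan step.
#' @return an object of class `sweep_callset`: list with `q`,
#'   `zfst_cut`, `abs_log2_cut`, `n_retained`, `outliers` (window
#'   rows), `regions` (merged), `populations`.
#' @export
select_joint_outliers <- function(stats, q = 0.01, max_gap = NULL) {
  spec <- attr(stats, "window_spec")
  if (is.null(max_gap))
    max_gap <- if (!is.null(spec)) spec$step else 10000
  retained <- !is.na(stats$zfst) & !is.na(stats$log2_ratio)
  n_ret <- sum(retained)
  if (n_ret == 0) stop("no retained windows to rank")
  if (n_ret < 1 / q)
    warning("only ", n_ret, " retained windows for q = ", q)
  zfst_cut <- stats::quantile(stats$zfst[retained], 1 - q,
                              type = 7, names = FALSE)
  abs_log2_cut <- stats::quantile(abs(stats$log2_ratio[retained]), 1 - q,
                                  type = 7, names = FALSE)
  sel <- retained & stats$zfst >= zfst_cut &
    abs(stats$log2_ratio) >= abs_log2_cut
  outliers <- as.data.frame(stats)[sel, , drop = FALSE]
  rownames(outliers) <- NULL
  structure(
    list(q = q, zfst_cut = zfst_cut, abs_log2_cut = abs_log2_cut,
         n_retained = n_ret, outliers = outliers,
         regions = merge_outlier_regions(outliers, max_gap = max_gap),
         populations = attr(stats, "populations")),
    class = "sweep_callset")
}

#' @export
print.sweep_callset <- function(x, ...) {
  cat(sprintf(
    "sweep_callset: q = %g over %d retained windows\n", x$q, x$n_retained))
  cat(sprintf("thresholds: ZFst > %.2f, |log2 ratio| > %.2f\n",
              x$zfst_cut, x$abs_log2_cut))
  cat(nrow(x$outliers), "outlier windows in", nrow(x$regions),
      "merged region(s)\n")
  invisible(x)
}

#' Merge outlier windows into sweep regions
#'
#' Windows on the same contig that overlap or are separated by at most
#' `max_gap` bp are unioned into one region spanning from the smallest
#' start to the largest end.
#'
#' @param windows data.frame with `chrom`, `start`, `end`.
#' @param max_gap maximum separating gap in bp.
#' @return data.frame `chrom`, `start`, `end`, `n_windows`, sorted and
#'   disjoint.
#' @export
merge_outlier_regions <- function(windows, max_gap = 10000) {
  if (nrow(windows) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      stringsAsFactors = FALSE))
  windows <- windows[order(windows$chrom, windows$start), , drop = FALSE]
  res <- list()
  cur <- windows[1, c("chrom", "start", "end")]
  cur$n_windows <- 1L
  for (i in seq_len(nrow(windows))[-1]) {
    w <- windows[i, ]
    gap <- w$start - cur$end - 1
    if (w$chrom == cur$chrom && gap <= max_gap) {
      cur$end <- max(cur$end, w$end)
      cur$n_windows <- cur$n_windows + 1L
    } else {
      res[[length(res) + 1]] <- cur
      cur <- w[, c("chrom", "start", "end")]
      cur$n_windows <- 1L
    }
  }
  res[[length(res) + 1]] <- cur
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Annotate candidate genes around sweep regions
#'
#' A gene is a candidate for a region when the gene interval, extended
#' by `flank` bp on each side, intersects the region — i.e. genes
#' overlapping the sweep or within `flank` (default 500 kb) of it.
#'
#' @param regions data.frame `chrom`, `start`, `end` (merged sweep
#'   regions).
#' @param genes gene annotation from [read_bed_genes()].
#' @param flank search distance beyond the region edges, bp.
#' @return long data.frame: one row per (region, gene) hit with region
#'   coordinates and `gene_id`, `gene_start`, `gene_end`, sorted by
#'   position and deduplicated within region.
#' @export
annotate_candidate_genes <- function(regions, genes, flank = 500000) {
  hits <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    sel <- genes$chrom == r$chrom &
      genes$start - flank <= r$end &
      genes$end + flank >= r$start
    g <- genes[sel, , drop = FALSE]
    g <- g[!duplicated(g$gene_id), , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) == 0) next
    hits[[length(hits) + 1]] <- data.frame(
      region_chrom = r$chrom, region_start = r$start, region_end = r$end,
      gene_id = g$gene_id, gene_start = g$start, gene_end = g$end,
      stringsAsFactors = FALSE)
  }
  if (length(hits) == 0)
    return(data.frame(region_chrom = character(), region_start = integer(),
                      region_end = integer(), gene_id = character(),
                      gene_start = integer(), gene_end = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Fine-scale confirmation profile across a sweep region
#'
#' Recomputes the scan on genome-wide nonoverlapping windows (default
#' 10 kb), Z-standardizing over the fine-window genome-wide
#' distribution, and returns the rows overlapping the region of
#' interest — the zoom-in used to confirm a candidate sweep with
#' diversity ratios and Tajima's D at higher resolution.
#'
#' @param gm a [genotype_matrix()] with metadata.
#' @param pop_a,pop_b focal and reference population labels.
#' @param region one-row data.frame or list with `chrom`, `start`,
#'   `end`.
#' @param fine_size fine window size (= step; nonoverlapping), bp.
#' @param min_snps minimum SNPs per fine window (default 1).
#' @return the region's fine `window_stats` rows; the genome-wide fine
#'   table is attached as attribute `"genome"`.
#' @export
fine_scale_profile <- function(gm, pop_a, pop_b, region,
                               fine_size = 10000, min_snps = 1) {
  spec <- window_spec(size = fine_size, step = fine_size,
                      min_snps = min_snps)
  genome <- scan_windows(gm, pop_a, pop_b, spec)
  sel <- genome$chrom == region$chrom &
    genome$start <= region$end & genome$end >= region$start
  out <- genome[sel, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "genome") <- genome
  out
}
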