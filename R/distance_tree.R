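#' Individual-level p-distance matrix
#'
#' The p-distance between two individuals is the mean, over
#' pairwise-complete sites, of `|g_i - g_j| / 2`, i.e. the proportion
#' of allele differences under dosage coding.  Under the default
#' convention two heterozygotes contribute 0; set `het_het = "half"` to
#' score that configuration 0.5 instead (both conventions are in use by
#' distance tools for unphased genotypes).
#'
#' @param gm a [genotype_matrix()].
#' @param het_het contribution of a het-vs-het site: `"zero"` (default)
#'   or `"half"`.
#' @return symmetric numeric matrix with sample ids as dimnames; values
#'   in `[0, 1]`, zero diagonal.
#' @export
p_distance_matrix <- function(gm, het_het = c("zero", "half")) {
  het_het <- match.arg(het_het)
  g <- gm$dosage
  n <- nrow(g)
  if (n < 2) stop("need at least 2 samples")
  p <- ncol(g)
  M <- (!is.na(g)) * 1
  n_complete <- M %*% t(M)                 # pairwise-complete site counts
  off <- n_complete[upper.tri(n_complete)]
  if (any(off == 0)) {
    idx <- which(n_complete == 0 & upper.tri(n_complete), arr.ind = TRUE)[1, ]
    stop("samples ", rownames(g)[idx[1]], " and ", rownames(g)[idx[2]],
         " share no non-missing site")
  }
  # dist() rescales sums over incomplete pairs by p / n_used; back it out
  man <- as.matrix(stats::dist(g, method = "manhattan"))
  abs_sum <- man * n_complete / p
  if (het_het == "half") {
    H <- (g == 1L & !is.na(g)) * 1
    abs_sum <- abs_sum + H %*% t(H)        # each het-het pair adds 0.5*2
  }
  d <- abs_sum / (2 * n_complete)
  diag(d) <- 0
  dimnames(d) <- list(rownames(g), rownames(g))
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomeration: repeatedly join the pair (i, j)
#' minimizing `Q(i, j) = (r - 2) d(i, j) - R_i - R_j` (with `R_i` the
#' row sum over the r active nodes), attach them with the standard
#' branch-length formulas, and reduce the matrix.  Exact ties in Q are
#' broken by the lexicographically smallest label pair (internal nodes
#' inherit the smallest leaf label of their clade).  Negative branch
#' lengths are clamped to 0 without redistribution.  The result is the
#' unrooted tree (trifurcating root node), exact on additive matrices.
#'
#' @param d symmetric nonnegative distance matrix with labels as
#'   dimnames (e.g. from [p_distance_matrix()]).
#' @return an [ape][ape::read.tree] `phylo` object.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distance matrix must be nonnegative")
  dimnames(d) <- NULL

  # active nodes: phylo ids (tips 1..n, internals assigned at the end)
  node_id <- seq_len(n)
  tie_key <- labels                         # min leaf label per clade
  edges <- matrix(integer(0), ncol = 2)
  edge_len <- numeric(0)
  next_internal <- -1L                      # provisional negative ids

  while (length(node_id) > 3) {
    r <- length(node_id)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # lexicographically smallest (sorted) label pair among ties
    key <- apply(cand, 1, function(ij) {
      k <- sort(c(tie_key[ij[1]], tie_key[ij[2]]))
      paste(k, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    new_id <- next_internal
    next_internal <- next_internal - 1L
    edges <- rbind(edges, c(new_id, node_id[i]), c(new_id, node_id[j]))
    edge_len <- c(edge_len, li, lj)
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_along(node_id), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    node_id <- c(node_id[keep], new_id)
    tie_key <- c(tie_key[keep], min(tie_key[c(i, j)]))
  }

  # final trifurcation: closed-form star lengths
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  root <- next_internal
  edges <- rbind(edges,
                 c(root, node_id[1]), c(root, node_id[2]),
                 c(root, node_id[3]))
  edge_len <- c(edge_len, max(la, 0), max(lb, 0), max(lc, 0))

  # renumber internals: root -> n+1, others n+2.. in creation order
  internals <- sort(unique(edges[edges < 0]), decreasing = TRUE) # -1,-2,..
  map <- stats::setNames(seq_along(internals) + n, internals)
  map[as.character(root)] <- n + 1L
  other <- setdiff(internals, root)
  map[as.character(other)] <- n + 1L + seq_along(other)
  relabel <- function(x) ifelse(x < 0, map[as.character(x)], x)
  edge <- cbind(relabel(edges[, 1]), relabel(edges[, 2]))
  storage.mode(edge) <- "integer"
  phy <- structure(
    list(edge = edge, edge.length = edge_len, tip.label = labels,
         Nnode = n - 2L),
    class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Write a tree in Newick format
#'
#' Branch lengths are printed at 6 significant digits; labels
#' containing Newick metacharacters (whitespace, parentheses, commas,
#' colons, semicolons, brackets or quotes) are single-quoted with
#' internal quotes doubled, per the standard.
#'
#' @param tree a `phylo` object, e.g. from [neighbor_joining()].
#' @param path output file path, or `NULL` to return the string only.
#' @return the Newick string, invisibly.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  quote_label <- function(x) {
    if (grepl("[][ \t():;,']", x))
      paste0("'", gsub("'", "''", x, fixed = TRUE), "'")
    else x
  }
  fmt <- function(x) sprintf("%.6g", x)
  build <- function(node) {
    rows <- kids[[as.character(node)]]
    if (is.null(rows)) return(quote_label(tree$tip.label[node]))
    parts <- vapply(rows, function(e) {
      paste0(build(tree$edge[e, 2]), ":", fmt(tree$edge.length[e]))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  newick <- paste0(build(n + 1L), ";")
  if (!is.null(path)) writeLines(newick, path)
  invisible(newick)
}
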