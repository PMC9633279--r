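# Independent brute-force oracles. These deliberately avoid the
# package's own code paths: diversity by enumerating allele pairs,
# Fst from the variance-component formulas written out separately,
# Tajima's D with its constants recomputed from scratch, OLS from the
# normal equations, p-distance by a double loop.

# alleles at one site for a set of dosage calls (drop missing)
expand_alleles <- function(dosage) {
  dosage <- dosage[!is.na(dosage)]
  unlist(lapply(dosage, function(g) c(rep(1, g), rep(0, 2 - g))))
}

# per-site pi as the mean mismatch over all unordered allele pairs
oracle_site_pi <- function(dosage) {
  al <- expand_alleles(dosage)
  n <- length(al)
  if (n < 2) return(NA_real_)
  pairs <- utils::combn(n, 2)
  mean(al[pairs[1, ]] != al[pairs[2, ]])
}

oracle_window_pi <- function(dosage_mat, window_size) {
  sum(vapply(seq_len(ncol(dosage_mat)), function(j) {
    v <- oracle_site_pi(dosage_mat[, j])
    if (is.na(v)) 0 else v
  }, numeric(1))) / window_size
}

# Weir & Cockerham (1984) two-population components, a b c spelled out
oracle_wc_components <- function(gA, gB) {
  gA <- gA[!is.na(gA)]; gB <- gB[!is.na(gB)]
  nA <- length(gA); nB <- length(gB)
  if (nA < 1 || nB < 1 || nA + nB <= 2) return(c(a = NA, b = NA, c = NA))
  pA <- sum(gA) / (2 * nA); pB <- sum(gB) / (2 * nB)
  hA <- mean(gA == 1); hB <- mean(gB == 1)
  r <- 2
  nbar <- mean(c(nA, nB))
  nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
  pbar <- (nA * pA + nB * pB) / (r * nbar)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

oracle_windowed_fst <- function(dosA, dosB) {
  num <- den <- 0
  for (j in seq_len(ncol(dosA))) {
    comp <- oracle_wc_components(dosA[, j], dosB[, j])
    if (anyNA(comp)) next
    num <- num + comp["a"]
    den <- den + sum(comp)
  }
  if (den == 0) NA_real_ else unname(num / den)
}

oracle_tajimas_d <- function(dosage_mat) {
  usable <- which(colSums(!is.na(dosage_mat)) >= 1)
  n_per_site <- 2 * colSums(!is.na(dosage_mat[, usable, drop = FALSE]))
  usable <- usable[n_per_site >= 2]
  if (length(usable) == 0) return(NA_real_)
  n <- min(2 * colSums(!is.na(dosage_mat[, usable, drop = FALSE])))
  if (n < 4) return(NA_real_)
  S <- 0; pi_hat <- 0
  for (j in usable) {
    al <- expand_alleles(dosage_mat[, j])
    if (length(unique(al)) > 1) S <- S + 1
    pi_hat <- pi_hat + oracle_site_pi(dosage_mat[, j])
  }
  if (S < 1) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi_hat - S / a1) /
    sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

oracle_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  x <- g1[ok]; y <- g2[ok]
  if (length(x) < 2) return(NA_real_)
  sxx <- sum((x - mean(x))^2); syy <- sum((y - mean(y))^2)
  if (sxx == 0 || syy == 0) return(NA_real_)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy^2 / (sxx * syy)
}

oracle_p_distance <- function(dosage_mat, het_half = FALSE) {
  n <- nrow(dosage_mat)
  d <- matrix(0, n, n, dimnames = list(rownames(dosage_mat),
                                       rownames(dosage_mat)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    gi <- dosage_mat[i, ]; gj <- dosage_mat[j, ]
    ok <- !is.na(gi) & !is.na(gj)
    contrib <- abs(gi[ok] - gj[ok]) / 2
    if (het_half) contrib[gi[ok] == 1 & gj[ok] == 1] <- 0.5
    d[i, j] <- d[j, i] <- mean(contrib)
  }
  d
}

# OLS from the normal equations with t tests
oracle_ols <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(resid^2) / df
  se <- sqrt(s2 * diag(solve(XtX)))
  tval <- beta[, 1] / se
  list(beta = beta[, 1], se = se, t = tval,
       p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE), df = df)
}
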