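#' Genotype frequency table by population
#'
#' Per-group counts of dosage 0/1/2 at one variant plus the alternate
#' (deletion) allele frequency, homozygous-alternate frequency and
#' heterozygote frequency, all computed over non-missing calls — the
#' table used to compare homozygous-deletion frequencies across
#' populations.
#'
#' @param gm a [genotype_matrix()] with metadata.
#' @param variant_id the variant to tabulate.
#' @param grouping metadata column defining the groups (default
#'   `"population"`).
#' @return data.frame: one row per group with `n_called`, `n0`, `n1`,
#'   `n2`, `alt_freq`, `hom_alt_freq`, `het_freq` (frequencies `NA`
#'   when a group has no calls).
#' @export
genotype_frequency_table <- function(gm, variant_id,
                                     grouping = "population") {
  idx <- variant_index(gm, variant_id)
  if (is.null(gm$meta) || is.null(gm$meta[[grouping]]))
    stop("metadata column '", grouping, "' not available")
  g <- gm$dosage[, idx]
  groups <- gm$meta[[grouping]]
  out <- lapply(unique(groups), function(grp) {
    gg <- g[groups == grp]
    gg <- gg[!is.na(gg)]
    n <- length(gg)
    counts <- c(sum(gg == 0L), sum(gg == 1L), sum(gg == 2L))
    data.frame(
      group = grp, n_called = n,
      n0 = counts[1], n1 = counts[2], n2 = counts[3],
      alt_freq = if (n > 0) sum(gg) / (2 * n) else NA_real_,
      hom_alt_freq = if (n > 0) counts[3] / n else NA_real_,
      het_freq = if (n > 0) counts[2] / n else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  attr(out, "variant_id") <- variant_id
  out
}

#' Ordinary least squares fit with t tests
#'
#' Fits `formula` on `data` by QR-based least squares (via
#' [stats::lm()]), returning per-term estimates, standard errors from
#' `s^2 (X'X)^-1`, t statistics and two-sided p-values on
#' `n - rank(X)` degrees of freedom.  Categorical covariates are
#' one-hot encoded with the first level as reference.  A rank-deficient
#' design is an error naming the collinear columns; an exact fit
#' (`SSE = 0`) reports `SE = 0`, `p = 0` and the `PERFECT_FIT` flag
#' rather than NaNs.
#'
#' @param formula model formula, e.g. `y ~ dosage + sex + batch`.
#' @param data data.frame holding the response and predictors
#'   (complete cases only; drop beforehand).
#' @return an `association_result`: data.frame of `term`, `estimate`,
#'   `se`, `t`, `p` with attributes `n`, `df`, `sigma`, `formula`,
#'   `flags`.
#' @export
ols_fit <- function(formula, data) {
  if (anyNA(data))
    stop("ols_fit expects complete cases; drop missing rows first")
  fit <- stats::lm(formula, data = data)
  coefs <- stats::coef(fit)
  if (anyNA(coefs))
    stop("design is rank deficient; collinear column(s): ",
         paste(names(coefs)[is.na(coefs)], collapse = ", "))
  n <- length(fit$residuals)
  df <- fit$df.residual
  if (df <= 0) stop("no residual degrees of freedom (n <= rank)")
  sse <- sum(fit$residuals^2)
  scale_ref <- max(1, sum(stats::model.response(stats::model.frame(fit))^2))
  flags <- character(0)
  R <- qr.R(fit$qr)
  XtX_inv <- chol2inv(R)
  if (sse / scale_ref < 1e-12) {
    flags <- "PERFECT_FIT"
    se <- rep(0, length(coefs))
    tval <- ifelse(coefs == 0, 0, Inf * sign(coefs))
    pval <- rep(0, length(coefs))
    sigma <- 0
  } else {
    sigma2 <- sse / df
    se <- sqrt(sigma2 * diag(XtX_inv))
    tval <- coefs / se
    pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
    sigma <- sqrt(sigma2)
  }
  out <- data.frame(term = names(coefs), estimate = unname(coefs),
                    se = unname(se), t = unname(tval), p = unname(pval),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, n = n, df = df, sigma = sigma,
            formula = deparse(formula), flags = flags,
            class = c("association_result", "data.frame"))
}

#' @export
print.association_result <- function(x, ...) {
  cat("linear model:", attr(x, "formula"),
      sprintf(" (n = %d, residual df = %d)\n", attr(x, "n"), attr(x, "df")))
  if (length(attr(x, "flags")) > 0)
    cat("flags:", paste(attr(x, "flags"), collapse = ", "), "\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

# assemble the complete-case model frame for association fits
assoc_frame <- function(gm, variant_ids, trait, covariates,
                        transform = "identity") {
  if (is.null(gm$meta)) stop("no sample metadata attached")
  if (is.null(gm$meta[[trait]]))
    stop("trait '", trait, "' not present in metadata; ",
         "association refused")
  y <- gm$meta[[trait]]
  if (transform == "log") {
    if (any(y <= 0, na.rm = TRUE))
      stop("log transform requires strictly positive trait values")
    y <- log(y)
  }
  df <- data.frame(y = y)
  for (k in seq_along(variant_ids)) {
    idx <- variant_index(gm, variant_ids[k])
    df[[paste0("g", k)]] <- gm$dosage[, idx]
  }
  for (cv in covariates) {
    if (is.null(gm$meta[[cv]]))
      stop("covariate '", cv, "' not present in metadata")
    df[[cv]] <- gm$meta[[cv]]
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  # constant covariates (e.g. all-female subsets) are dropped, not fatal
  kept <- covariates
  for (cv in covariates) {
    if (length(unique(df[[cv]])) < 2) {
      message("covariate '", cv, "' is constant after complete-case ",
              "filtering; dropped from the model")
      df[[cv]] <- NULL
      kept <- setdiff(kept, cv)
    }
  }
  for (cv in kept)
    if (!is.numeric(df[[cv]])) df[[cv]] <- factor(df[[cv]])
  attr(df, "covariates") <- kept
  df
}

#' Single-locus dosage association
#'
#' Fits `y ~ dosage + covariates` on complete cases, with dosage the
#' 0/1/2 copy count of the tested (deletion) allele, and reports the
#' full coefficient table with the dosage term flagged as the term of
#' interest.  Covariates that are constant in the analyzed subset
#' (e.g. sex in an all-female panel) are dropped with a note.
#'
#' @param gm a [genotype_matrix()] with metadata carrying the trait.
#' @param variant_id variant to test.
#' @param trait metadata column holding the quantitative trait.
#' @param covariates metadata columns used as covariates (default sex
#'   and batch).
#' @param transform response scale: `"identity"` (default; the raw
#'   trait) or `"log"` (natural log, requires positive values).  The
#'   raw scale is the default analysis; the log option is offered for
#'   right-skewed traits without endorsement.
#' @return an `association_result` with attribute `reported_term =
#'   "g1"` (the dosage row).
#' @export
associate_variant <- function(gm, variant_id, trait,
                              covariates = c("sex", "batch"),
                              transform = c("identity", "log")) {
  transform <- match.arg(transform)
  df <- assoc_frame(gm, variant_id, trait, covariates, transform)
  if (length(unique(df$g1)) < 2)
    stop("dosage at ", variant_id, " is constant; nothing to test")
  rhs <- paste(c("g1", attr(df, "covariates")), collapse = " + ")
  res <- ols_fit(stats::as.formula(paste("y ~", rhs)), df)
  attr(res, "reported_term") <- "g1"
  attr(res, "variant_id") <- variant_id
  res
}

#' Two-locus interaction association
#'
#' Fits `y ~ g1 + g2 + g1:g2 + covariates` on complete cases and
#' reports the product (interaction) term.  A degenerate genotype
#' distribution that makes the product collinear with the main effects
#' is an error.
#'
#' @param gm a [genotype_matrix()] with metadata carrying the trait.
#' @param variant_id_1,variant_id_2 the two loci.
#' @inheritParams associate_variant
#' @return an `association_result` with attribute `reported_term =
#'   "g1:g2"`.
#' @export
interaction_association <- function(gm, variant_id_1, variant_id_2,
                                    trait,
                                    covariates = c("sex", "batch"),
                                    transform = c("identity", "log")) {
  transform <- match.arg(transform)
  df <- assoc_frame(gm, c(variant_id_1, variant_id_2), trait, covariates,
                    transform)
  if (length(unique(df$g1)) < 2 || length(unique(df$g2)) < 2)
    stop("a locus is constant; interaction model is degenerate")
  rhs <- paste(c("g1", "g2", "g1:g2", attr(df, "covariates")),
               collapse = " + ")
  res <- ols_fit(stats::as.formula(paste("y ~", rhs)), df)
  attr(res, "reported_term") <- "g1:g2"
  attr(res, "variant_ids") <- c(variant_id_1, variant_id_2)
  res
}

#' Extract the reported term of an association result
#'
#' Convenience accessor returning the one-row summary (estimate, SE,
#' t, p) of the term an association fit was run for — the dosage term
#' of [associate_variant()] or the product term of
#' [interaction_association()].
#'
#' @param res an `association_result`.
#' @return one-row data.frame.
#' @export
reported_term <- function(res) {
  term <- attr(res, "reported_term")
  if (is.null(term)) stop("result carries no reported term")
  out <- res[res$term == term, , drop = FALSE]
  rownames(out) <- NULL
  out
}
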