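# Per-gene summary statistics and the treatment-effect-removed data used for
# correlation estimation.

#' Validate an expression matrix
#'
#' An expression matrix is a numeric matrix of log-scale expression values
#' with genes in rows and samples in columns. Row names are gene identifiers,
#' column names sample identifiers. Values must be finite: missing values are
#' rejected outright rather than silently imputed.
#'
#' @param X numeric matrix, genes x samples, with row and column names.
#' @return `X`, invisibly, after validation.
#' @export
validate_expression <- function(X) {
  if (!is.matrix(X) || !is.numeric(X))
    stop("EXPR_NOT_MATRIX: expression data must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(X)) || is.null(colnames(X)))
    stop("EXPR_NO_NAMES: expression matrix needs gene row names and sample column names",
         call. = FALSE)
  if (anyNA(X) || any(!is.finite(X)))
    stop("EXPR_NOT_FINITE: expression matrix contains missing or non-finite values",
         call. = FALSE)
  if (nrow(X) < 2L)
    stop("EXPR_TOO_FEW_GENES: need at least 2 genes", call. = FALSE)
  if (ncol(X) < 4L)
    stop("EXPR_TOO_FEW_SAMPLES: need at least 4 samples (2 per group)", call. = FALSE)
  dup <- rownames(X)[duplicated(rownames(X))]
  if (length(dup))
    stop("EXPR_DUP_GENE: duplicate gene ids: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  invisible(X)
}

#' Align two-group labels to the columns of an expression matrix
#'
#' Labels map each sample to treatment group 1 or 2. They may be given as an
#' integer vector aligned positionally with the columns of `X`, or as a named
#' vector keyed by sample id (any order; must cover every column).
#'
#' @param labels integer-like vector of 1s and 2s, optionally named by sample.
#' @param X expression matrix whose columns the labels must cover.
#' @return integer vector of group codes (1/2), one per column of `X`, named
#'   by sample id.
#' @export
align_labels <- function(labels, X) {
  g <- labels
  if (!is.null(names(g))) {
    missing <- setdiff(colnames(X), names(g))
    if (length(missing))
      stop("LABELS_MISSING_SAMPLE: unlabeled sample(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    if (anyDuplicated(names(g)))
      stop("LABELS_DUP_SAMPLE: sample labeled more than once", call. = FALSE)
    g <- g[colnames(X)]
  } else if (length(g) != ncol(X)) {
    stop("LABELS_LENGTH: ", length(g), " labels for ", ncol(X), " samples",
         call. = FALSE)
  }
  g <- as.integer(g)
  if (anyNA(g) || !all(g %in% c(1L, 2L)))
    stop("LABELS_BAD_GROUP: groups must be coded 1 or 2", call. = FALSE)
  if (sum(g == 1L) < 2L || sum(g == 2L) < 2L)
    stop("LABELS_GROUP_TOO_SMALL: each group needs at least 2 samples (got ",
         sum(g == 1L), " and ", sum(g == 2L), ")", call. = FALSE)
  names(g) <- colnames(X)
  g
}

#' Per-gene within-group means
#'
#' @param X expression matrix (genes x samples).
#' @param labels group labels; see [align_labels()].
#' @return numeric matrix with one row per gene and columns `mean1`, `mean2`.
#' @export
group_means <- function(X, labels) {
  validate_expression(X)
  g <- align_labels(labels, X)
  cbind(mean1 = rowMeans(X[, g == 1L, drop = FALSE]),
        mean2 = rowMeans(X[, g == 2L, drop = FALSE]))
}

# Internal: per-gene pooled-sd scale s_g of the unpaired equal-variance t,
# i.e. sqrt(pooled within-group variance) * sqrt(1/M1 + 1/M2). The scale
# factor is included so that the null variance of t is nu/(nu-2) with
# nu = M1 + M2 - 2.
pooled_scale <- function(X, g) {
  M1 <- sum(g == 1L); M2 <- sum(g == 2L)
  X1 <- X[, g == 1L, drop = FALSE]
  X2 <- X[, g == 2L, drop = FALSE]
  ss1 <- rowSums((X1 - rowMeans(X1))^2)
  ss2 <- rowSums((X2 - rowMeans(X2))^2)
  sqrt((ss1 + ss2) / (M1 + M2 - 2) * (1 / M1 + 1 / M2))
}

#' Unpaired pooled-variance t-statistic per gene
#'
#' Computes `t_g = (mean2_g - mean1_g) / s_g` where `s_g` is the pooled
#' within-group sample standard deviation times `sqrt(1/M1 + 1/M2)` — the
#' standard equal-variance two-sample t. Genes that are constant within both
#' groups have no defined scale; their statistic is set to 0 with a warning
#' (an unrankable gene stays deep in the null region).
#'
#' @inheritParams group_means
#' @return numeric vector of t-statistics, named by gene, in input gene order.
#' @export
pooled_t <- function(X, labels) {
  validate_expression(X)
  g <- align_labels(labels, X)
  m <- group_means(X, g)
  s <- pooled_scale(X, g)
  zero <- s == 0
  t <- numeric(nrow(X))
  t[!zero] <- (m[!zero, "mean2"] - m[!zero, "mean1"]) / s[!zero]
  if (any(zero))
    warning(sum(zero), " gene(s) constant within both groups; t set to 0",
            call. = FALSE)
  names(t) <- rownames(X)
  t
}

#' SAM-style t-statistic with exchangeability factor
#'
#' Adds a small nonnegative constant `s0` to the pooled standard deviation in
#' the denominator of the two-sample t, stabilising genes with very small
#' within-group variance: `t'_g = (mean2_g - mean1_g) / (s_g + s0)`. With
#' `s0 = 0` this reduces exactly to [pooled_t()].
#'
#' @inheritParams group_means
#' @param s0 nonnegative exchangeability factor. Default: the median of the
#'   per-gene pooled scales `s_g`, a standard simple choice.
#' @return numeric vector of statistics, named by gene.
#' @export
sam_t <- function(X, labels, s0 = NULL) {
  validate_expression(X)
  g <- align_labels(labels, X)
  s <- pooled_scale(X, g)
  if (is.null(s0)) s0 <- stats::median(s)
  if (!is.numeric(s0) || length(s0) != 1L || is.na(s0) || s0 < 0)
    stop("SAM_BAD_S0: s0 must be a single nonnegative number", call. = FALSE)
  m <- group_means(X, g)
  denom <- s + s0
  if (any(denom == 0))
    warning(sum(denom == 0), " gene(s) with zero denominator (s_g = s0 = 0); statistic set to 0",
            call. = FALSE)
  t <- ifelse(denom == 0, 0, (m[, "mean2"] - m[, "mean1"]) / denom)
  names(t) <- rownames(X)
  t
}

#' Remove treatment effects by within-group centering
#'
#' Subtracts each gene's average response within each treatment group,
#' nullifying genuine group differences so that only null (treatment-
#' independent) correlation structure remains. No variance scaling is applied.
#'
#' @inheritParams group_means
#' @return matrix of the same shape as `X` with every (gene, group) mean zero.
#' @export
remove_treatment_effects <- function(X, labels) {
  validate_expression(X)
  g <- align_labels(labels, X)
  Xc <- X
  for (k in c(1L, 2L)) {
    cols <- g == k
    Xc[, cols] <- X[, cols, drop = FALSE] - rowMeans(X[, cols, drop = FALSE])
  }
  Xc
}

#' Sample correlation matrix of centered expression data
#'
#' For within-group-centered data `Xc`, the (g, g') entry is the normalized
#' inner product of gene rows over all M arrays (both groups pooled):
#' `sum_m x_gm x_g'm / sqrt(sum_m x_gm^2 * sum_m x_g'm^2)`. This is the
#' correlation estimate whose partitions drive the reranking; its constant
#' scale factor relative to the t-score covariance cancels in the
#' decorrelating product, so no degrees-of-freedom correction is applied.
#'
#' Intended for moderate G (the full G x G matrix is materialized); the
#' reranking pipeline itself only ever forms the partitions it needs, see
#' [build_correlation_model()].
#'
#' @param Xc within-group-centered matrix ([remove_treatment_effects()]).
#' @return G x G symmetric correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(Xc) {
  U <- normalize_rows(Xc)
  R <- tcrossprod(U)
  diag(R) <- 1
  R
}

# Internal: rows scaled to unit Euclidean norm; errors on zero-energy rows.
normalize_rows <- function(Xc) {
  energy <- rowSums(Xc^2)
  if (any(energy == 0)) {
    bad <- rownames(Xc)[energy == 0]
    if (is.null(bad)) bad <- which(energy == 0)
    stop("CORR_ZERO_ENERGY: zero-variance gene(s) after centering: ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (sum(energy == 0) > 5L) ", ..." else "",
         " (filter constant genes first)", call. = FALSE)
  }
  Xc / sqrt(energy)
}

#' Degrees of freedom of the two-sample t
#'
#' `nu = M1 + M2 - 2`. Never needed by the reranking itself (the `nu/(nu-2)`
#' scale cancels); exposed for simulation-based checks of the null t variance
#' and t-covariance scaling laws.
#'
#' @param labels group labels (a vector of 1s and 2s).
#' @return integer degrees of freedom.
#' @export
t_dof <- function(labels) {
  g <- as.integer(labels)
  sum(g == 1L) + sum(g == 2L) - 2L
}
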