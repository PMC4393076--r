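# The core method: zero-assumption partition, correlation-partition assembly,
# and the decorrelating projection producing the reranked candidate scores.

#' Partition genes into identified (null) and candidate sets
#'
#' Under the zero assumption, the fraction `p0` of genes with the smallest
#' |t| almost surely satisfies the null hypothesis of no differential
#' expression. Genes are sorted by |t| ascending (ties broken by ascending
#' original gene index, so the partition is deterministic); the first
#' `G0 = round(p0 * G)` form the identified set, the remaining `G1` the
#' candidate set.
#'
#' @param t numeric vector of per-gene t-statistics ([pooled_t()]).
#' @param p0 fraction of genes declared null, in (0, 1). The benchmark
#'   experiments use p0 about 0.5.
#' @return an object of class `corrank_partition`: a list with the sorting
#'   permutation `perm`, identified-set scores `t0` and indices `idx0`,
#'   candidate scores `t1` and indices `idx1`, and sizes `G0`, `G1`.
#' @export
za_partition <- function(t, p0) {
  if (!is.numeric(p0) || length(p0) != 1L || is.na(p0) || p0 <= 0 || p0 >= 1)
    stop("ZA_BAD_P0: p0 must lie strictly in (0, 1)", call. = FALSE)
  if (anyNA(t) || any(!is.finite(t)))
    stop("ZA_NONFINITE_T: t-vector has non-finite entries", call. = FALSE)
  G <- length(t)
  G0 <- as.integer(round(p0 * G))
  if (G0 < 2L)
    stop("ZA_G0_TOO_SMALL: identified set has ", G0,
         " genes; need at least 2 to estimate R00", call. = FALSE)
  if (G0 >= G)
    stop("ZA_NO_CANDIDATES: p0 leaves no candidate genes", call. = FALSE)
  perm <- order(abs(t), seq_along(t))   # ascending |t|, ties by gene index
  idx0 <- perm[seq_len(G0)]
  idx1 <- perm[(G0 + 1L):G]
  structure(list(perm = perm, idx0 = idx0, idx1 = idx1,
                 t0 = t[idx0], t1 = t[idx1],
                 G0 = G0, G1 = G - G0, p0 = p0,
                 gene_ids = names(t)),
            class = "corrank_partition")
}

#' @export
print.corrank_partition <- function(x, ...) {
  cat("Zero-assumption partition: G =", x$G0 + x$G1,
      "genes; identified G0 =", x$G0, "( p0 =", format(x$p0), "), candidates G1 =",
      x$G1, "\n")
  invisible(x)
}

#' Assemble the correlation partitions needed for decorrelation
#'
#' From the within-group-centered matrix `Xc` and a partition, extracts the
#' identified-set correlation block `R00` (G0 x G0, with `epsilon` added to
#' its diagonal so the severely rank-deficient sample estimate becomes
#' positive definite) and the candidate-by-identified block `R10`. `R00` is
#' the only matrix ever factorized; its upper Cholesky factor is computed
#' here. `R10` is kept in factored form `U1 %*% t(U0)` (row-normalized
#' centered data), so the full `G1 x G0` block is never materialized for
#' large problems; set `materialize = TRUE` to store it explicitly.
#'
#' @param Xc centered matrix from [remove_treatment_effects()], rows in the
#'   original gene order.
#' @param part a `corrank_partition`.
#' @param epsilon nonnegative diagonal regularizer for `R00` (default 1e-10).
#' @param materialize store `R10` explicitly (small problems / tests).
#' @return an object of class `corrank_corr_model`.
#' @export
build_correlation_model <- function(Xc, part, epsilon = 1e-10,
                                    materialize = FALSE) {
  stopifnot(inherits(part, "corrank_partition"))
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) || epsilon < 0)
    stop("CM_BAD_EPSILON: epsilon must be a single nonnegative number", call. = FALSE)
  if (nrow(Xc) != part$G0 + part$G1)
    stop("CM_DIM_MISMATCH: centered matrix has ", nrow(Xc),
         " rows but partition covers ", part$G0 + part$G1, " genes", call. = FALSE)
  U <- normalize_rows(Xc)
  U0 <- U[part$idx0, , drop = FALSE]
  U1 <- U[part$idx1, , drop = FALSE]
  R00 <- tcrossprod(U0)
  diag(R00) <- 1 + epsilon
  L <- tryCatch(chol(R00), error = function(e)
    stop("CM_CHOL_FAIL: Cholesky factorization of R00 + epsilon*I failed (",
         conditionMessage(e), "); increase epsilon", call. = FALSE))
  if (min(diag(L)) < 1e-8)
    warning("R00 is near-singular (smallest Cholesky pivot ",
            format(min(diag(L)), digits = 3), "); results may be ill-conditioned",
            call. = FALSE)
  structure(list(R00 = R00, chol00 = L,
                 R10 = if (materialize) tcrossprod(U1, U0) else NULL,
                 U0 = U0, U1 = U1, epsilon = epsilon),
            class = "corrank_corr_model")
}

#' Build a correlation model from explicit matrix partitions
#'
#' Bypasses estimation: wraps user-supplied `R00` and `R10` (for example the
#' population covariance partitions in simulation studies) into the model
#' object consumed by [decorrelate()]. `epsilon` is added to the diagonal of
#' `R00` before factorization.
#'
#' @param R00 G0 x G0 symmetric matrix, positive definite after
#'   regularization.
#' @param R10 G1 x G0 matrix.
#' @param epsilon nonnegative diagonal regularizer (default 0: explicit
#'   partitions are usually already well conditioned).
#' @return an object of class `corrank_corr_model`.
#' @export
correlation_model <- function(R00, R10, epsilon = 0) {
  if (!is.matrix(R00) || nrow(R00) != ncol(R00))
    stop("CM_BAD_R00: R00 must be square", call. = FALSE)
  if (!is.matrix(R10) || ncol(R10) != ncol(R00))
    stop("CM_BAD_R10: R10 must have G0 columns", call. = FALSE)
  A <- R00
  diag(A) <- diag(A) + epsilon
  L <- tryCatch(chol(A), error = function(e)
    stop("CM_CHOL_FAIL: R00 + epsilon*I is not positive definite; increase epsilon",
         call. = FALSE))
  structure(list(R00 = A, chol00 = L, R10 = R10, U0 = NULL, U1 = NULL,
                 epsilon = epsilon),
            class = "corrank_corr_model")
}

#' Decorrelate candidate t-scores against the identified set
#'
#' Computes the reranked candidate scores
#' `tau = t1 - R10 %*% solve(R00 + epsilon*I, t0)`. The linear system
#' `(R00 + epsilon*I) s0 = t0` is solved through the Cholesky factor
#' (triangular forward/back substitution); the explicit inverse is never
#' formed. When the model holds `R10` in factored form the product is
#' computed as `U1 %*% crossprod(U0, s0)`, costing O(G1 * M) memory instead
#' of O(G1 * G0).
#'
#' The component removed from `t1` is the part linearly predictable from the
#' identified-set noise scores; the residual `tau` is (in the population
#' version) orthogonal to `t0`.
#'
#' @param part a `corrank_partition`.
#' @param cm a `corrank_corr_model` with dimensions matching `part`.
#' @return an object of class `corrank_rerank`: a list with `tau`,
#'   `candidate_ids`, `raw_t` (candidate t-scores, aligned with `tau`),
#'   `raw_rank` (rank of each candidate among all G genes by decreasing |t|),
#'   and `ranking` (candidate ids by decreasing |tau|, ties broken by
#'   ascending original gene index).
#' @export
decorrelate <- function(part, cm) {
  stopifnot(inherits(part, "corrank_partition"), inherits(cm, "corrank_corr_model"))
  if (nrow(cm$R00) != part$G0)
    stop("DC_DIM_MISMATCH: R00 is ", nrow(cm$R00), " x ", ncol(cm$R00),
         " but G0 = ", part$G0, call. = FALSE)
  L <- cm$chol00                     # upper triangular, R00 = t(L) %*% L
  s0 <- backsolve(L, forwardsolve(t(L), part$t0))
  correction <- if (!is.null(cm$U1)) {
    drop(cm$U1 %*% crossprod(cm$U0, s0))
  } else {
    if (nrow(cm$R10) != part$G1)
      stop("DC_DIM_MISMATCH: R10 has ", nrow(cm$R10), " rows but G1 = ",
           part$G1, call. = FALSE)
    drop(cm$R10 %*% s0)
  }
  tau <- part$t1 - correction
  if (any(!is.finite(tau)))
    stop("DC_NONFINITE: non-finite reranked scores; R00 is pathologically ",
         "conditioned — increase epsilon", call. = FALSE)
  G <- part$G0 + part$G1
  gene_ids <- if (is.null(part$gene_ids)) as.character(seq_len(G)) else part$gene_ids
  cand_ids <- gene_ids[part$idx1]
  # rank of each candidate among all G genes by decreasing |t| (ties: index)
  full_rank <- integer(G)
  full_rank[rev(part$perm)] <- seq_len(G)
  ord <- order(-abs(tau), part$idx1)
  structure(list(tau = stats::setNames(tau, cand_ids),
                 candidate_ids = cand_ids,
                 raw_t = stats::setNames(part$t1, cand_ids),
                 raw_rank = stats::setNames(full_rank[part$idx1], cand_ids),
                 ranking = cand_ids[ord],
                 order = ord),
            class = "corrank_rerank")
}

#' @export
print.corrank_rerank <- function(x, n = 10L, ...) {
  cat("Reranked candidate scores: G1 =", length(x$tau), "genes\n")
  top <- utils::head(x$ranking, n)
  df <- data.frame(rank = seq_along(top), gene_id = top,
                   tau = unname(x$tau[top]), raw_t = unname(x$raw_t[top]),
                   raw_rank = unname(x$raw_rank[top]))
  print(df, row.names = FALSE)
  invisible(x)
}

#' End-to-end correlation-adjusted reranking
#'
#' Runs the full pipeline on an expression matrix: per-gene pooled t
#' ([pooled_t()]); zero-assumption partition at fraction `p0`
#' ([za_partition()]); within-group centering
#' ([remove_treatment_effects()]); assembly and Cholesky factorization of the
#' identified-set correlation block ([build_correlation_model()]); and the
#' decorrelating projection ([decorrelate()]). The first `G_star` genes of
#' the reranked candidate list are reported as differentially expressed.
#'
#' @inheritParams group_means
#' @param p0 fraction of genes declared null a priori (default 0.5).
#' @param G_star size of the reported discovery list; must not exceed the
#'   candidate-set size `G1`.
#' @param epsilon diagonal regularizer for `R00` (default 1e-10).
#' @return a list with `top` (the reported `G_star` gene ids, best first),
#'   `result` (the full `corrank_rerank`), `partition`, and `t` (the raw
#'   t-vector).
#' @examples
#' td <- make_trial(cov_spec = cov_identity(),
#'                  sp = spike_params(G_plus = 5, G_minus = 5, x_plus = 2, x_minus = -2),
#'                  ep = experiment_params(p0 = 0.5, G = 100, G_star = 10,
#'                                         M1 = 10, M2 = 10),
#'                  seed = 1)
#' fit <- rerank(td$X, td$labels, p0 = 0.5, G_star = 10)
#' fit$top
#' @export
rerank <- function(X, labels, p0 = 0.5, G_star, epsilon = 1e-10) {
  t <- pooled_t(X, labels)
  part <- za_partition(t, p0)
  if (!is.numeric(G_star) || length(G_star) != 1L || is.na(G_star) ||
      G_star < 1L || G_star > part$G1)
    stop("RR_BAD_GSTAR: G_star must lie in [1, G1 = ", part$G1, "]", call. = FALSE)
  Xc <- remove_treatment_effects(X, labels)
  cm <- build_correlation_model(Xc, part, epsilon = epsilon)
  res <- decorrelate(part, cm)
  list(top = utils::head(res$ranking, as.integer(G_star)),
       result = res, partition = part, t = t)
}
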