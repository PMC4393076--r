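# Synthetic expression data with known truth: correlation-preserving spike-in
# protocol on a template matrix, and a fully parametric Gaussian simulator.

#' Spike-in parameters
#'
#' `G_plus` genes are up-regulated by adding `x_plus` and `G_minus` genes
#' down-regulated by adding `x_minus` to their group-2 entries. The total
#' number of truly differential genes is `G_delta = G_plus + G_minus`
#' (fraction `p_delta = G_delta / G`).
#'
#' Benchmark presets: the small-p_delta case uses
#' `{p_delta = 0.025, G_plus = 200, G_minus = 100, x = +-0.1}`; the
#' large-p_delta case `{p_delta = 0.1, G_plus = G_minus = 600, x = +-0.02}`;
#' the Gaussian-simulation preset `{p_delta = 0.031, G_plus = G_minus = 50,
#' x = +-1}`.
#'
#' @param G_plus number of up-regulated genes.
#' @param G_minus number of down-regulated genes.
#' @param x_plus positive offset added to group 2 for up-regulated genes.
#' @param x_minus negative offset for down-regulated genes.
#' @return object of class `corrank_spike_params`.
#' @export
spike_params <- function(G_plus, G_minus, x_plus, x_minus) {
  stopifnot(G_plus >= 0, G_minus >= 0, G_plus + G_minus >= 1)
  if (!(x_plus >= 0 && x_minus <= 0))
    stop("SP_BAD_OFFSETS: need x_plus >= 0 >= x_minus", call. = FALSE)
  structure(list(G_plus = as.integer(G_plus), G_minus = as.integer(G_minus),
                 G_delta = as.integer(G_plus + G_minus),
                 x_plus = x_plus, x_minus = x_minus),
            class = "corrank_spike_params")
}

#' Experiment parameters
#'
#' The per-trial discovery-experiment settings: null fraction `p0`, total
#' genes `G`, reported-list size `G_star`, and group sizes `M1`, `M2`.
#'
#' @param p0 zero-assumption null fraction.
#' @param G total number of genes.
#' @param G_star reported-list size; must not exceed `G - round(p0 * G)`.
#' @param M1,M2 samples per group.
#' @return object of class `corrank_experiment_params`.
#' @export
experiment_params <- function(p0, G, G_star, M1, M2) {
  G0 <- round(p0 * G)
  if (G_star > G - G0)
    stop("EP_BAD_GSTAR: G_star exceeds candidate-set size G - G0 = ", G - G0,
         call. = FALSE)
  stopifnot(M1 >= 2, M2 >= 2)
  structure(list(p0 = p0, G = as.integer(G), G_star = as.integer(G_star),
                 M1 = as.integer(M1), M2 = as.integer(M2)),
            class = "corrank_experiment_params")
}

#' Row-standardize an expression matrix within groups
#'
#' For each gene and each treatment group, centers the entries to mean 0 and
#' scales them so the within-group mean square is 1. All genes then carry
#' equal energy while the within-group intergene correlation structure of the
#' input is preserved exactly. This is a data-construction step for building
#' benchmark matrices from a real template; it is not part of the reranking
#' algorithm itself.
#'
#' Genes with a constant block in either group cannot be standardized and are
#' dropped with a warning reporting the count.
#'
#' @inheritParams group_means
#' @return standardized matrix (possibly with fewer rows than `X`).
#' @export
row_standardize <- function(X, labels) {
  validate_expression(X)
  g <- align_labels(labels, X)
  Xs <- X
  drop <- logical(nrow(X))
  for (k in c(1L, 2L)) {
    cols <- g == k
    block <- X[, cols, drop = FALSE] - rowMeans(X[, cols, drop = FALSE])
    ms <- rowMeans(block^2)
    drop <- drop | ms == 0
    ms[ms == 0] <- 1           # placeholder; rows flagged for dropping
    Xs[, cols] <- block / sqrt(ms)
  }
  if (any(drop)) {
    warning("dropped ", sum(drop), " gene(s) constant within a group; ",
            "cannot standardize", call. = FALSE)
    Xs <- Xs[!drop, , drop = FALSE]
  }
  Xs
}

#' Randomly split M samples into two groups
#'
#' @param M total number of samples.
#' @param M1,M2 group sizes; `M1 + M2` must equal `M`.
#' @param seed integer seed, or `NULL` to draw from the current RNG state.
#' @return integer vector of group codes (1/2) of length `M`.
#' @export
random_split <- function(M, M1, M2, seed = NULL) {
  if (M1 + M2 != M)
    stop("RS_BAD_SIZES: M1 + M2 = ", M1 + M2, " but M = ", M, call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  g <- rep(2L, M)
  g[sample.int(M, M1)] <- 1L
  g
}

#' Spike known differential expression into a matrix
#'
#' Chooses `G_plus + G_minus` distinct genes uniformly at random; adds
#' `x_plus` to every group-2 entry of the first `G_plus` and `x_minus` to
#' every group-2 entry of the remaining `G_minus`. All other entries are
#' untouched. The chosen genes and their directions are recorded as ground
#' truth.
#'
#' @param Xs expression matrix (typically row-standardized).
#' @param labels group labels aligned to `Xs` columns.
#' @param sp [spike_params()].
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return object of class `corrank_trial`: list with `X`, `labels`, `truth`
#'   (data.frame of `gene_id`, `direction`), and `seed`.
#' @export
spike_in <- function(Xs, labels, sp, seed = NULL) {
  stopifnot(inherits(sp, "corrank_spike_params"))
  g <- align_labels(labels, Xs)
  G <- nrow(Xs)
  if (sp$G_delta > G)
    stop("SI_TOO_MANY: G_delta = ", sp$G_delta, " exceeds G = ", G, call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  chosen <- sample.int(G, sp$G_delta)
  up <- chosen[seq_len(sp$G_plus)]
  down <- chosen[setdiff(seq_len(sp$G_delta), seq_len(sp$G_plus))]
  X <- Xs
  cols2 <- g == 2L
  if (length(up)) X[up, cols2] <- X[up, cols2, drop = FALSE] + sp$x_plus
  if (length(down)) X[down, cols2] <- X[down, cols2, drop = FALSE] + sp$x_minus
  truth <- data.frame(
    gene_id = rownames(Xs)[c(up, down)],
    direction = rep(c("up", "down"), c(length(up), length(down))),
    stringsAsFactors = FALSE)
  structure(list(X = X, labels = g, truth = truth,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "corrank_trial")
}

# ---- parametric covariance specifications -----------------------------------

#' Covariance specifications for the Gaussian simulator
#'
#' Families of G x G covariance (correlation) matrices for
#' [simulate_gaussian()]:
#' * `cov_identity()` — independent genes;
#' * `cov_block(rho, size)` — equicorrelated blocks of `size` consecutive
#'   genes with within-block correlation `rho` (0 <= rho < 1), independent
#'   across blocks;
#' * `cov_ar1(rho)` — first-order autoregressive, corr(g, g') = rho^|g-g'|;
#' * `cov_factor(k, loading)` — `k` latent factors with per-gene loading
#'   vectors of norm `loading` (< 1), unit total variance;
#' * `cov_matrix(Lambda)` — any user-supplied positive semi-definite matrix
#'   (e.g. an empirical covariance).
#'
#' @param rho correlation parameter.
#' @param size block size.
#' @param k number of latent factors.
#' @param loading common loading-vector norm, in [0, 1).
#' @param Lambda user-supplied G x G positive semi-definite matrix.
#' @return object of class `corrank_cov_spec`.
#' @name cov_spec
NULL

#' @rdname cov_spec
#' @export
cov_identity <- function() {
  structure(list(type = "identity"), class = "corrank_cov_spec")
}

#' @rdname cov_spec
#' @export
cov_block <- function(rho, size) {
  stopifnot(rho >= 0, rho < 1, size >= 1)
  structure(list(type = "block", rho = rho, size = as.integer(size)),
            class = "corrank_cov_spec")
}

#' @rdname cov_spec
#' @export
cov_ar1 <- function(rho) {
  stopifnot(abs(rho) < 1)
  structure(list(type = "ar1", rho = rho), class = "corrank_cov_spec")
}

#' @rdname cov_spec
#' @export
cov_factor <- function(k, loading) {
  stopifnot(k >= 1, loading >= 0, loading < 1)
  structure(list(type = "factor", k = as.integer(k), loading = loading),
            class = "corrank_cov_spec")
}

#' @rdname cov_spec
#' @export
cov_matrix <- function(Lambda) {
  if (!is.matrix(Lambda) || nrow(Lambda) != ncol(Lambda))
    stop("COV_BAD_MATRIX: Lambda must be square", call. = FALSE)
  structure(list(type = "matrix", Lambda = Lambda), class = "corrank_cov_spec")
}

#' Simulate a null expression matrix from a multivariate Gaussian
#'
#' Columns are i.i.d. draws from N(0, Lambda): gene expression is stationary
#' across arrays with mean zero and covariance given by `cov_spec`. The
#' identity, block, AR(1) and factor families are sampled by construction
#' (no G x G factorization); a user-supplied matrix is sampled through its
#' Cholesky factor and rejected if not positive semi-definite.
#'
#' @param G number of genes.
#' @param M1,M2 samples per group (columns `1..M1` then `M1+1..M1+M2`; the
#'   draw is group-independent — this is null data).
#' @param cov_spec a [cov_spec] object (default identity).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return G x (M1 + M2) matrix with gene ids `g1..gG` and sample ids
#'   `s1..sM`.
#' @export
simulate_gaussian <- function(G, M1, M2, cov_spec = cov_identity(), seed = NULL) {
  stopifnot(inherits(cov_spec, "corrank_cov_spec"), G >= 2, M1 >= 2, M2 >= 2)
  if (!is.null(seed)) set.seed(seed)
  M <- M1 + M2
  X <- switch(cov_spec$type,
    identity = matrix(stats::rnorm(G * M), G, M),
    block = {
      rho <- cov_spec$rho
      nb <- ceiling(G / cov_spec$size)
      shared <- matrix(stats::rnorm(nb * M), nb, M)
      block_of <- rep(seq_len(nb), each = cov_spec$size)[seq_len(G)]
      sqrt(rho) * shared[block_of, , drop = FALSE] +
        sqrt(1 - rho) * matrix(stats::rnorm(G * M), G, M)
    },
    ar1 = {
      rho <- cov_spec$rho
      X <- matrix(stats::rnorm(G * M), G, M)
      for (g in 2:G) X[g, ] <- rho * X[g - 1L, ] + sqrt(1 - rho^2) * X[g, ]
      X
    },
    factor = {
      k <- cov_spec$k
      L <- matrix(stats::rnorm(G * k), G, k)
      L <- L / sqrt(rowSums(L^2)) * cov_spec$loading
      Fm <- matrix(stats::rnorm(k * M), k, M)
      L %*% Fm + sqrt(1 - cov_spec$loading^2) * matrix(stats::rnorm(G * M), G, M)
    },
    matrix = {
      Lambda <- cov_spec$Lambda
      if (nrow(Lambda) != G)
        stop("COV_DIM: Lambda is ", nrow(Lambda), " x ", ncol(Lambda),
             " but G = ", G, call. = FALSE)
      Lch <- tryCatch(chol(Lambda), error = function(e)
        stop("COV_NOT_PSD: user covariance is not positive semi-definite",
             call. = FALSE))
      crossprod(Lch, matrix(stats::rnorm(G * M), G, M))
    })
  dimnames(X) <- list(paste0("g", seq_len(G)), paste0("s", seq_len(M)))
  X
}

#' Generate one benchmark trial with known truth
#'
#' Two generation paths:
#' * **template** — emulates the protocol used on real microarray data. The
#'   template matrix comes with its *own* two-group labels
#'   (`template_labels`). Columns are (optionally) subsampled per original
#'   group to `M1` + `M2` arrays; the matrix is row-standardized within the
#'   *original* groups ([row_standardize()]); the columns are then randomly
#'   re-split into fresh groups of `M1` and `M2` ([random_split()]), which
#'   destroys the alignment between standardization groups and test groups
#'   so null genes keep realistic between-group noise; finally known offsets
#'   are spiked into the new group 2 ([spike_in()]). The within-group
#'   intergene correlation of the template is preserved throughout.
#' * **gaussian** — a parametric null matrix is drawn from N(0, Lambda)
#'   ([simulate_gaussian()]), split `M1 | M2`, and spiked. The data are
#'   already zero-mean with unit variance, so no standardization is applied.
#'
#' All randomness (split, truth genes, column subset, Gaussian draw) derives
#' from `seed`, so trials are bit-reproducible.
#'
#' @param template expression matrix to use as the template, or `NULL` for
#'   the Gaussian path.
#' @param template_labels the template's own group labels (required with
#'   `template`): standardization groups, e.g. the real study's case/control
#'   assignment.
#' @param cov_spec covariance specification for the Gaussian path.
#' @param sp [spike_params()].
#' @param ep [experiment_params()].
#' @param seed integer seed.
#' @param subsample if `TRUE` (template path), draw `M1` columns from
#'   template group 1 and `M2` from template group 2 at random before
#'   standardizing — the small-sample robustness protocol. Automatic when
#'   the template has more than `M1 + M2` columns.
#' @return object of class `corrank_trial` (see [spike_in()]).
#' @export
make_trial <- function(template = NULL, template_labels = NULL,
                       cov_spec = NULL, sp, ep, seed, subsample = NULL) {
  stopifnot(inherits(sp, "corrank_spike_params"),
            inherits(ep, "corrank_experiment_params"))
  set.seed(seed)
  if (!is.null(template)) {
    validate_expression(template)
    if (is.null(template_labels))
      stop("MT_NO_TEMPLATE_LABELS: the template path needs the template's ",
           "own group labels (template_labels)", call. = FALSE)
    tlab <- align_labels(template_labels, template)
    M <- ep$M1 + ep$M2
    if (is.null(subsample)) subsample <- ncol(template) > M
    if (subsample) {
      i1 <- which(tlab == 1L); i2 <- which(tlab == 2L)
      if (length(i1) < ep$M1 || length(i2) < ep$M2)
        stop("MT_TOO_FEW_COLS: template groups have ", length(i1), " + ",
             length(i2), " columns; need ", ep$M1, " + ", ep$M2, call. = FALSE)
      keep <- c(i1[sample.int(length(i1), ep$M1)],
                i2[sample.int(length(i2), ep$M2)])
      template <- template[, keep, drop = FALSE]
      tlab <- tlab[keep]
    } else if (ncol(template) != M) {
      stop("MT_COLS_MISMATCH: template has ", ncol(template),
           " columns but M1 + M2 = ", M, call. = FALSE)
    }
    Xs <- row_standardize(template, tlab)
    labels <- random_split(M, ep$M1, ep$M2, seed = NULL)
    names(labels) <- colnames(Xs)
    td <- spike_in(Xs, labels, sp, seed = NULL)
  } else {
    if (is.null(cov_spec))
      stop("MT_NO_SOURCE: supply a template matrix or a cov_spec", call. = FALSE)
    X <- simulate_gaussian(ep$G, ep$M1, ep$M2, cov_spec, seed = NULL)
    labels <- random_split(ep$M1 + ep$M2, ep$M1, ep$M2, seed = NULL)
    names(labels) <- colnames(X)
    td <- spike_in(X, labels, sp, seed = NULL)
  }
  td$seed <- as.integer(seed)
  td
}

#' @export
print.corrank_trial <- function(x, ...) {
  cat("Benchmark trial: ", nrow(x$X), " genes x ", ncol(x$X), " samples (",
      sum(x$labels == 1L), "/", sum(x$labels == 2L), " split); ",
      nrow(x$truth), " truly differential (",
      sum(x$truth$direction == "up"), " up, ",
      sum(x$truth$direction == "down"), " down)\n", sep = "")
  invisible(x)
}
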