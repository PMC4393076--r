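# Shared fixtures: all test data is built in code.

# 3 genes x 4 samples with exactly representable values (bit-exact round trips)
tiny_X <- function() {
  X <- matrix(c(0, 2, 3, 5,
                1, 1, 1, 1,
                0.5, -0.5, 1.25, -1.25), nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:4)))
  X
}

tiny_labels <- function() c(s1 = 1L, s2 = 1L, s3 = 2L, s4 = 2L)

# random expression instance with a balanced-ish split
rand_instance <- function(G, M, seed) {
  set.seed(seed)
  X <- matrix(rnorm(G * M), G, M,
              dimnames = list(paste0("g", seq_len(G)), paste0("s", seq_len(M))))
  M1 <- floor(M / 2)
  labels <- rep(c(1L, 2L), c(M1, M - M1))
  names(labels) <- colnames(X)
  list(X = X, labels = labels)
}

# hand-built partition object for population-level checks where the
# identified/candidate membership is fixed by design, not by observed |t|
fixed_partition <- function(t0, t1, gene_ids = NULL) {
  G0 <- length(t0); G1 <- length(t1); G <- G0 + G1
  structure(list(perm = seq_len(G), idx0 = seq_len(G0), idx1 = G0 + seq_len(G1),
                 t0 = t0, t1 = t1, G0 = G0, G1 = G1, p0 = G0 / G,
                 gene_ids = if (is.null(gene_ids)) paste0("g", seq_len(G)) else gene_ids),
            class = "corrank_partition")
}

# random symmetric positive-definite matrix with unit-ish diagonal
rand_spd <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * (n + 2)), n, n + 2)
  S <- tcrossprod(A) / (n + 2)
  D <- diag(1 / sqrt(diag(S)))
  D %*% S %*% D
}
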