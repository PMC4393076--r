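test_that("za_partition splits by ascending |t| with index tie-break", {
  t <- c(g1 = 3, g2 = -1, g3 = 0.5, g4 = -2)
  p <- za_partition(t, 0.5)
  expect_equal(p$G0, 2L)
  expect_setequal(p$idx0, c(3L, 2L))           # |t| in {0.5, 1}
  expect_setequal(p$idx1, c(4L, 1L))           # {-2, 3}
  expect_equal(unname(sort(abs(p$t0))), c(0.5, 1))
  expect_true(max(abs(p$t0)) <= min(abs(p$t1)))
  # perm is a bijection
  expect_setequal(p$perm, seq_along(t))
})

test_that("za_partition handles G0 rounding, ties, and bad input", {
  # the benchmark's exact fraction: p0 = 6312/12625 on G = 12625
  t <- rnorm(12625)
  p <- za_partition(t, 6312 / 12625)
  expect_equal(p$G0, 6312L)
  # all-equal |t|: sizes still (G0, G1), tie-break by ascending index
  p2 <- za_partition(rep(1, 10), 0.5)
  expect_equal(p2$idx0, 1:5)
  expect_equal(p2$idx1, 6:10)
  expect_error(za_partition(t, 0), "ZA_BAD_P0")
  expect_error(za_partition(t, 1), "ZA_BAD_P0")
  expect_error(za_partition(c(1, 2, 3), 0.2), "ZA_G0_TOO_SMALL")
  expect_error(za_partition(c(1, NA, 3, 4), 0.5), "ZA_NONFINITE_T")
})

test_that("build_correlation_model extracts the right partitions", {
  inst <- rand_instance(30, 12, seed = 7)
  Xc <- remove_treatment_effects(inst$X, inst$labels)
  suppressWarnings(t <- pooled_t(inst$X, inst$labels))
  part <- za_partition(t, 0.5)
  cm <- build_correlation_model(Xc, part, epsilon = 1e-10, materialize = TRUE)
  R <- sample_correlation(Xc)
  expect_equal(cm$R00, R[part$idx0, part$idx0] + diag(1e-10, part$G0),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(cm$R10, R[part$idx1, part$idx0],
               tolerance = 1e-12, ignore_attr = TRUE)
  # factored form agrees with the explicit block
  expect_equal(tcrossprod(cm$U1, cm$U0), cm$R10, tolerance = 1e-12)
})

test_that("orthogonal rows give R10 = 0 and R00 = (1+eps) I", {
  # disjoint supports: rows exactly orthogonal
  Xc <- matrix(0, 4, 8, dimnames = list(paste0("g", 1:4), paste0("s", 1:8)))
  for (g in 1:4) Xc[g, (2 * g - 1):(2 * g)] <- c(1, -1)
  part <- fixed_partition(t0 = c(0.1, -0.2), t1 = c(2, -3))
  cm <- build_correlation_model(Xc, part, epsilon = 1e-10, materialize = TRUE)
  expect_equal(cm$R00, diag(1 + 1e-10, 2), ignore_attr = TRUE)
  expect_equal(cm$R10, matrix(0, 2, 2), ignore_attr = TRUE)
})

test_that("regularization rescues the rank-deficient sample correlation", {
  # G0 = 300 >> M = 20: raw R00 has rank <= M - 2 but Cholesky succeeds
  inst <- rand_instance(400, 20, seed = 13)
  Xc <- remove_treatment_effects(inst$X, inst$labels)
  suppressWarnings(t <- pooled_t(inst$X, inst$labels))
  part <- za_partition(t, 0.75)
  expect_equal(part$G0, 300L)
  cm <- build_correlation_model(Xc, part, epsilon = 1e-10)
  # pivots of the regularized factor are ~sqrt(epsilon), small but positive
  expect_gt(min(diag(cm$chol00)), 0)
  expect_true(all(is.finite(cm$chol00)))
  R00 <- tcrossprod(cm$U0)
  expect_lte(qr(R00)$rank, 18)
  # epsilon = 0 on this rank-deficient block must fail with guidance
  expect_error(
    suppressWarnings(correlation_model(R00, tcrossprod(cm$U1, cm$U0), epsilon = 0)),
    "CM_CHOL_FAIL")
})

test_that("decorrelate scalar case and null-correction identity", {
  # G0 = G1 = 1: tau = 3 - 0.5 * 2 = 2
  part <- fixed_partition(t0 = 2, t1 = 3)
  cm <- correlation_model(R00 = matrix(1), R10 = matrix(0.5), epsilon = 0)
  res <- decorrelate(part, cm)
  expect_equal(unname(res$tau), 2)
  # R10 = 0 => tau = t1 exactly
  part2 <- fixed_partition(t0 = c(1, -1), t1 = c(3, -2, 0.5))
  cm2 <- correlation_model(diag(2), matrix(0, 3, 2))
  expect_identical(unname(decorrelate(part2, cm2)$tau), c(3, -2, 0.5))
})

test_that("Cholesky-solve path equals explicit-inverse oracle", {
  # M > G so R00 is full rank: with cond(R00) bounded, the two algebraic
  # paths must agree to near machine precision. (At M << G0 both paths are
  # limited to ~cond * eps agreement; see the rank-deficient check below.)
  for (seed in 1:25) {
    set.seed(seed)
    G0 <- 40; G1 <- 60; eps <- 1e-10
    inst <- rand_instance(G0 + G1, 220, seed = seed + 100)
    Xc <- remove_treatment_effects(inst$X, inst$labels)
    suppressWarnings(t <- pooled_t(inst$X, inst$labels))
    part <- za_partition(t, G0 / (G0 + G1))
    cm <- build_correlation_model(Xc, part, epsilon = eps, materialize = TRUE)
    res <- decorrelate(part, cm)
    tau_oracle <- part$t1 - drop(cm$R10 %*% solve(cm$R00) %*% part$t0)
    expect_lt(max(abs(res$tau - tau_oracle)) / max(abs(tau_oracle)), 1e-8)
  }
  # rank-deficient regime (M << G0): agreement limited by conditioning only
  inst <- rand_instance(100, 30, seed = 999)
  Xc <- remove_treatment_effects(inst$X, inst$labels)
  suppressWarnings(t <- pooled_t(inst$X, inst$labels))
  part <- za_partition(t, 0.4)
  cm <- build_correlation_model(Xc, part, epsilon = 1e-10, materialize = TRUE)
  res <- decorrelate(part, cm)
  tau_oracle <- part$t1 - drop(cm$R10 %*% solve(cm$R00) %*% part$t0)
  expect_lt(max(abs(res$tau - tau_oracle)) / max(abs(tau_oracle)), 1e-4)
})

test_that("ranking is monotone in |tau| with index tie-break", {
  part <- fixed_partition(t0 = c(0.1, 0.2), t1 = c(1.5, -1.5, 2, -0.5),
                          gene_ids = paste0("g", 1:6))
  cm <- correlation_model(diag(2), matrix(0, 4, 2))
  res <- decorrelate(part, cm)
  # |tau| = (1.5, 1.5, 2, 0.5); tie between g3 (idx 3) and g4 (idx 4)
  expect_identical(res$ranking, c("g5", "g3", "g4", "g6"))
  expect_true(all(diff(abs(res$tau[res$ranking])) <= 0))
})

test_that("raw_rank reflects |t| ordering over all G genes", {
  inst <- rand_instance(40, 16, seed = 21)
  fit <- rerank(inst$X, inst$labels, p0 = 0.5, G_star = 5)
  t <- fit$t
  full <- rank(-abs(t), ties.method = "first")
  expect_equal(unname(fit$result$raw_rank),
               unname(full[fit$partition$idx1]))
})

test_that("rerank end-to-end contracts hold", {
  inst <- rand_instance(100, 20, seed = 9)
  fit <- rerank(inst$X, inst$labels, p0 = 0.5, G_star = 10)
  expect_length(fit$top, 10)
  # identified genes never appear in the reported list, for any G_star
  identified <- rownames(inst$X)[fit$partition$idx0]
  expect_length(intersect(fit$result$ranking, identified), 0)
  expect_error(rerank(inst$X, inst$labels, p0 = 0.5, G_star = 51), "RR_BAD_GSTAR")
})

test_that("rerank is gene-permutation equivariant", {
  inst <- rand_instance(60, 18, seed = 30)
  fit1 <- rerank(inst$X, inst$labels, p0 = 0.5, G_star = 8)
  set.seed(1); pi <- sample(nrow(inst$X))
  fit2 <- rerank(inst$X[pi, ], inst$labels, p0 = 0.5, G_star = 8)
  expect_identical(fit1$result$ranking, fit2$result$ranking)
  expect_equal(fit1$result$tau[fit2$result$candidate_ids],
               fit2$result$tau, tolerance = 1e-12)
})

test_that("uncorrelated data: reranked top list matches raw-t list on candidates", {
  # large M so R10 is near zero; reranking reduces to raw-t ranking
  inst <- rand_instance(50, 2000, seed = 17)
  fit <- rerank(inst$X, inst$labels, p0 = 0.5, G_star = 10)
  t <- fit$t
  cand <- rownames(inst$X)[fit$partition$idx1]
  raw_top <- cand[order(-abs(t[cand]))][1:10]
  # R10 ~ O(1/sqrt(M)) so tau = t1 up to ~2% noise: the lists agree up to
  # swaps among near-tied scores
  expect_gte(length(intersect(fit$top, raw_top)), 8)
  expect_gt(cor(abs(fit$result$tau), abs(fit$result$raw_t),
                method = "spearman"), 0.95)
})
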