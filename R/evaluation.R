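# Scoring of discovery lists against known truth and the multi-trial
# comparison harness.

#' Score a discovery list against the truth set
#'
#' `F` counts reported genes that are not truly differential; the
#' false-discovery rate is `Fbar = F / G_star` where `G_star` is the reported
#' list size.
#'
#' @param reported character vector of reported gene ids (nonempty).
#' @param truth character vector of truly differential gene ids.
#' @return list with elements `F` (count) and `Fbar` (rate in [0, 1]).
#' @export
score_list <- function(reported, truth) {
  if (length(reported) == 0L)
    stop("EV_EMPTY_LIST: reported list is empty", call. = FALSE)
  F <- sum(!(reported %in% truth))
  list(F = F, Fbar = F / length(reported))
}

# Internal: top-G_star gene list for one method on one trial.
# raw_t / sam_t rank all G genes by decreasing |statistic| (ties by index);
# rerank reports the head of the reranked candidate list.
run_method <- function(method, td, ep, epsilon = 1e-10, s0 = NULL,
                       external_rankings = NULL) {
  switch(method,
    rerank = rerank(td$X, td$labels, p0 = ep$p0, G_star = ep$G_star,
                    epsilon = epsilon)$top,
    raw_t = {
      t <- pooled_t(td$X, td$labels)
      rownames(td$X)[order(-abs(t), seq_along(t))][seq_len(ep$G_star)]
    },
    sam_t = {
      t <- sam_t(td$X, td$labels, s0 = s0)
      rownames(td$X)[order(-abs(t), seq_along(t))][seq_len(ep$G_star)]
    },
    external = utils::head(external_rankings, ep$G_star),
    stop("EV_BAD_METHOD: unknown method '", method, "'", call. = FALSE))
}

#' Run a multi-trial method comparison
#'
#' For each trial `i = 1..n_trials`, generates trial data with seed
#' `base_seed + i - 1` (resampling the group split, truth genes, and — on the
#' subsampled template path — the column subset), runs each method, and
#' scores its reported list against the truth. A method failure aborts only
#' that (trial, method) cell: a diagnostic is logged and `F`/`Fbar` are
#' recorded as `NA`.
#'
#' Externally produced rankings (e.g. from comparator software run outside
#' this package) can be scored identically by passing `external_rankings`, a
#' list of per-trial gene-id vectors, and including `"external"` in
#' `methods`.
#'
#' @param n_trials number of trials (the benchmark experiments use 40).
#' @param sp [spike_params()].
#' @param ep [experiment_params()].
#' @param methods subset of `c("rerank", "raw_t", "sam_t", "external")`.
#' @param base_seed integer; trial `i` uses seed `base_seed + i - 1`.
#' @param template,template_labels,cov_spec trial-generation source, passed
#'   to [make_trial()].
#' @param epsilon regularizer for the reranking method.
#' @param s0 SAM exchangeability factor (`NULL` = per-trial median of `s_g`).
#' @param external_rankings optional list of length `n_trials` of ranked
#'   gene-id vectors for the `"external"` method.
#' @param subsample passed to [make_trial()].
#' @return data.frame with columns `trial`, `seed`, `method`, `F`, `Fbar`,
#'   `G_star`; one row per (trial, method). Summarize with
#'   [summarize_trials()].
#' @export
run_trials <- function(n_trials, sp, ep,
                       methods = c("rerank", "raw_t", "sam_t"),
                       base_seed = 1L, template = NULL, template_labels = NULL,
                       cov_spec = NULL,
                       epsilon = 1e-10, s0 = NULL, external_rankings = NULL,
                       subsample = NULL) {
  methods <- match.arg(methods, c("rerank", "raw_t", "sam_t", "external"),
                       several.ok = TRUE)
  if ("external" %in% methods &&
      (is.null(external_rankings) || length(external_rankings) != n_trials))
    stop("EV_EXTERNAL: external_rankings must be a list with one ranking per trial",
         call. = FALSE)
  rows <- vector("list", n_trials * length(methods))
  r <- 0L
  for (i in seq_len(n_trials)) {
    seed_i <- base_seed + i - 1L
    td <- make_trial(template = template, template_labels = template_labels,
                     cov_spec = cov_spec, sp = sp, ep = ep, seed = seed_i,
                     subsample = subsample)
    for (m in methods) {
      sc <- tryCatch({
        rep_list <- run_method(m, td, ep, epsilon = epsilon, s0 = s0,
                               external_rankings = external_rankings[[i]])
        score_list(rep_list, td$truth$gene_id)
      }, error = function(e) {
        message("trial ", i, " method ", m, " failed: ", conditionMessage(e))
        list(F = NA_integer_, Fbar = NA_real_)
      })
      r <- r + 1L
      rows[[r]] <- data.frame(trial = i, seed = seed_i, method = m,
                              F = sc$F, Fbar = sc$Fbar, G_star = ep$G_star,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Summarize a multi-trial result table
#'
#' @param results data.frame from [run_trials()].
#' @param fbar_thresholds FDR thresholds at which to count trials (e.g. the
#'   benchmark reports counts of trials with `Fbar < 0.15` and `< 0.25`).
#' @return data.frame with one row per method: `mean_F`, `mean_Fbar`,
#'   `n_zero_F` (trials with no false discoveries), and one
#'   `n_Fbar_lt_<thr>` column per threshold.
#' @export
summarize_trials <- function(results, fbar_thresholds = c(0.15, 0.25, 0.5)) {
  stopifnot(is.data.frame(results),
            all(c("method", "F", "Fbar") %in% names(results)))
  out <- lapply(split(results, results$method), function(d) {
    row <- data.frame(method = d$method[1L],
                      n_trials = nrow(d),
                      mean_F = mean(d$F, na.rm = TRUE),
                      mean_Fbar = mean(d$Fbar, na.rm = TRUE),
                      n_zero_F = sum(d$F == 0, na.rm = TRUE),
                      stringsAsFactors = FALSE)
    for (thr in fbar_thresholds)
      row[[paste0("n_Fbar_lt_", thr)]] <- sum(d$Fbar < thr, na.rm = TRUE)
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
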