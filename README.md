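# corrank

Correlation-adjusted gene reranking for two-group differential expression.

## The problem

In a two-group expression study (G genes, M arrays or cells, groups of M1
and M2 samples), genes are conventionally ranked by the magnitude of the
unpaired two-sample t-statistic

    t_g = (x̄_{g|2} − x̄_{g|1}) / s_g,

with s_g the pooled within-group standard deviation scaled by
√(1/M1 + 1/M2). Intergene correlation makes the t_g strongly dependent:
shared noise can push whole groups of null genes to the top of the list,
so short discovery lists carry many false positives even when each
individual test is well calibrated.

corrank implements a reranking procedure that attacks this directly. Under
the **zero assumption**, the fraction p0 of genes with the smallest |t_g|
almost surely contains no differential expression — their t-scores are pure
noise. Partition t into the identified block t⁰ (G0 = p0·G genes) and the
candidate block t¹ (G1 = G − G0 genes), remove the treatment effect from X
by within-group centering (X̆), and estimate the sample correlation matrix
R̂ of X̆. The reranked candidate scores are the residual of the linear
projection of t¹ onto the identified noise scores:

    τ = t¹ − R̂¹⁰ (R̂⁰⁰)⁻¹ t⁰,

where R̂⁰⁰ (G0×G0) and R̂¹⁰ (G1×G0) are the corresponding partitions of R̂.
τ is, in the population version, uncorrelated with t⁰: the component of each
candidate score that was linearly predictable from identified-set noise is
subtracted off. Candidates are ranked by decreasing |τ| and the top G\*
reported. Numerically, R̂⁰⁰ gets 10⁻¹⁰ added to its diagonal (it is severely
rank-deficient when M ≪ G0) and the system is solved by Cholesky
factorization — the inverse is never formed, and the G1×G0 block is applied
in factored form so no G×G matrix is ever materialized.

The package also ships the benchmarking machinery: a correlation-preserving
spike-in simulator (row-standardize a template matrix within its own groups,
randomly re-split the columns, add known offsets x₊/x₋ to group 2 for
randomly chosen genes), a parametric multivariate Gaussian generator
(identity / equicorrelated-block / AR(1) / factor / user covariance), the
SAM-style baseline t′_g = (x̄_{g|2} − x̄_{g|1})/(s_g + s0), and a
multi-trial harness reporting false-discovery counts 𝔉 and rates
𝔉̄ = 𝔉/G\*.

## Worked example

```r
library(corrank)

# A fixed "study" matrix: 400 genes in equicorrelated blocks of 20
# (rho = 0.5), 20 + 20 arrays — then one benchmark trial: standardize,
# re-split, and spike 10 up- and 10 down-regulated genes at +-1.
tmpl <- simulate_gaussian(G = 400, M1 = 20, M2 = 20,
                          cov_spec = cov_block(rho = 0.5, size = 20), seed = 1)
tlab <- rep(c(1L, 2L), each = 20); names(tlab) <- colnames(tmpl)
td <- make_trial(template = tmpl, template_labels = tlab,
                 sp = spike_params(G_plus = 10, G_minus = 10,
                                   x_plus = 1, x_minus = -1),
                 ep = experiment_params(p0 = 0.5, G = 400, G_star = 20,
                                        M1 = 20, M2 = 20),
                 seed = 1, subsample = FALSE)
td
#> Benchmark trial: 400 genes x 40 samples (20/20 split); 20 truly differential (10 up, 10 down)

fit <- rerank(td$X, td$labels, p0 = 0.5, G_star = 20)
print(fit$result, n = 5)
#> Reranked candidate scores: G1 = 200 genes
#>  rank gene_id       tau     raw_t raw_rank
#>     1    g326  3.164413  4.597604        1
#>     2     g89  3.156698  4.520139        2
#>     3    g377 -3.153137 -1.823063       41
#>     4    g289  3.139740  1.943129       28
#>     5    g366  3.134709  4.277337        3

rr <- score_list(fit$top, td$truth$gene_id)
t  <- pooled_t(td$X, td$labels)
tt <- score_list(names(sort(-abs(t)))[1:20], td$truth$gene_id)
sprintf("rerank: F = %d (FDR = %.2f)   raw t: F = %d (FDR = %.2f)",
        rr$F, rr$Fbar, tt$F, tt$Fbar)
#> "rerank: F = 0 (FDR = 0.00)   raw t: F = 4 (FDR = 0.20)"
```

Reading the table: `tau` is the decorrelated score, `raw_t` the original
t-statistic, `raw_rank` the gene's rank among all 400 genes by |raw t|.
Genes g377 and g289 are true signals rescued from raw ranks 41 and 28 into
the top 5; the reported 20-gene list contains no false discoveries, while
ranking by raw t at the same list size yields 4 (FDR 0.20) — the shared
block noise that inflated null t-scores has been projected out.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "corrank.R", package = "corrank"))')
Rscript $CLI simulate --mode gaussian --params params.yaml --seed 7 --out-prefix trial
Rscript $CLI rerank --expr trial_X.tsv --labels trial_labels.tsv \
                    --p0 0.5 --top 100 --epsilon 1e-10 --out ranking.tsv
Rscript $CLI evaluate --config experiment.yaml --trials 40 --seed 7 --out results.tsv
```

Expression input is TSV/CSV (gzip ok): header of sample ids, first column of
gene ids; labels are a two-column TSV mapping sample → group ∈ {1, 2}. All
flags can be mirrored in a YAML config; `--log2` applies
log2(x + pseudocount) for raw-intensity input.

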