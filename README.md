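# ktdFE

Kernel tensor decomposition based unsupervised feature extraction for
multi-omics data.

## The problem

Multi-omics experiments measure K different feature spaces (gene expression,
methylation probes, proteins, ...) on the *same* samples, often with
10^4–10^5 features per block and only tens of samples — a severe
large-*p*-small-*n* regime. Two things make feature selection hard here:
after multiple-testing correction almost nothing stays significant, and any
supervised integration must choose weights between omics blocks, which there
is rarely a principled way to do.

`ktdFE` addresses both with a weight-free, unsupervised construction. Each
omics block `x_{i_k j_1...j_m}` (features × shared sample modes, e.g.
time points × individuals) is reduced to a linear sample kernel

    K^k(j..., j'...) = Σ_{i_k} x_{i_k j...} · x_{i_k j'...}

and the K kernels are stacked into one order-(2m+1) tensor of shape
`K × M_1×...×M_m × M_1×...×M_m`. Its storage never depends on any feature
count, so arbitrarily many, arbitrarily large blocks can be integrated.
Higher-order SVD (HOSVD) of this tensor gives

    x_{k j... j'...} = Σ_ℓ G(ℓ_1,...,ℓ_{2m+1}) · Π_s u_{ℓ_s j_s} · Π_s u_{ℓ_{m+s} j'_s} · u_{ℓ_{2m+1} k}

with orthogonal singular-vector matrices per sample mode and per omics mode;
the omics-mode vector `u_{ℓ k}` *is* the data-driven balance between blocks.
Sample-mode vectors are ranked against the biological hypothesis (Pearson
correlation with a covariate such as time, Welch *t* between two classes, or
constancy for modes that should not matter), features of every block are
projected onto the chosen vectors,

    u_{i_k} = Σ_{j...} x_{i_k j...} · Π_s u_{ℓ_s j_s},

and each feature gets a chi-squared P-value under a zero-mean Gaussian null
(`P = P_χ²[> (u_{i_k}/σ)²]`, σ = RMS of the projections), BH-corrected
within its block. This attaches a defensible significance level to every
selected feature — the capability most multi-omics integration tools lack.

## Worked example: the synthetic benchmark

The package ships a seeded generator for its benchmark: a
`N × M × K = 1000 × 10 × 3` tensor of Uniform(0,1) noise in which features
1–10 carry a monotone covariate `a_j = 1 + (M−1)j/M` in every omics slice
and features `k·10+1 ... (k+1)·10` carry it only in slice k.

```r
library(ktdFE)
spec <- SyntheticSpec(N = 1000, N1 = 10, M = 10, K = 3,
                      nEnsembles = 5, baseSeed = 1000)
runEnsemble(spec, "ktd")
#> ConfusionSummary (ktd, 5 ensemble(s)):
#>   group TP FN FP  TN
#>  common 10  0  0 990
```

All ten common signal features are recovered with zero false positives
among the 990 negatives (the 30 slice-specific signal features count as
negatives for the shared-feature truth). A single run exposes the pieces:

```r
d   <- generateSynthetic(spec, 1)
res <- runKTDPipeline(d$x, d$a)
res$choice
#> AxisChoice: sample l = (1), omics l = 1
head(axisDiagnostics(res$choice)$sample1, 3)
#>    ell           r       pValue
#> 1    1  0.99994725 3.386219e-17
#> 2    2 -0.99968829 4.128673e-14
#> 10  10 -0.01407084 9.692261e-01
```

At this signal strength the two leading sample-mode singular vectors are
both essentially collinear with the covariate (|r| > 0.999); the automatic
ranking takes the top one. The omics-mode vector ℓ=1 is constant across the
three slices, i.e. the blocks are weighted equally without anyone choosing
weights.

Cross-dataset concordance of two selections is tested exactly:

```r
fisherExactConditional(matrix(c(17269, 101, 65, 5), 2, byrow = TRUE))
#> Exact conditional 2x2 test
#>       [,1] [,2]
#> [1,] 17269  101
#> [2,]    65    5
#> conditional-MLE odds ratio: 13.14 (sample OR 13.15)
#> two-sided P = 6.671e-05
```

Real-data runs are driven from a YAML config (`runPipeline(config, outdir)`
→ per-block score TSVs + a JSON manifest; see `?runPipeline`), or from the
thin command-line front end `inst/cli/ktdfe.R` with subcommands `run`,
`simulate`, `overlap`, `report`.

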