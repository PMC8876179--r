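test_that("generateSynthetic follows the stated covariate and signal layout", {
    spec <- defaultSpec()
    d <- generateSynthetic(spec, 1)
    a <- d$a
    expect_equal(a[1], 1.9)
    expect_equal(a[10], 10)
    expect_equal(a, 1 + 9 * (1:10) / 10)

    # each omics slice carries exactly 2*N1 signal features
    for (k in 1:3) {
        expect_identical(sum(d$omicsMasks[[k]]), 20L)
        expect_identical(which(d$omicsMasks[[k]]),
            c(1:10, (k * 10 + 1):((k + 1) * 10)))
    }
    expect_identical(which(d$commonMask), 1:10)

    # noise-only entries in (0,1); signal entries shifted by a_j
    noise <- d$x[21:1000, , 1]
    expect_true(all(noise > 0 & noise < 1))
    for (j in c(1, 5, 10)) {
        sig <- d$x[1:10, j, 1]
        expect_true(all(sig > a[j] & sig < a[j] + 1))
    }
})

test_that("ensembles are reproducible and independent under the seed scheme", {
    spec <- defaultSpec(nEnsembles = 2)
    d1 <- generateSynthetic(spec, 1)
    d1again <- generateSynthetic(spec, 1)
    expect_identical(d1$x, d1again$x)
    d2 <- generateSynthetic(spec, 2)
    expect_false(identical(d1$x, d2$x))
    expect_error(generateSynthetic(SyntheticSpec(N = 30, N1 = 10, K = 3)),
        "N1")
})

test_that("the KTD pipeline selects the common signal and controls FDR", {
    spec <- defaultSpec(baseSeed = 77)
    d <- generateSynthetic(spec, 1)
    res <- runKTDPipeline(d$x, d$a)
    # chosen sample-mode vector is essentially collinear with the covariate
    u <- factorMatrices(res$hosvd)[[2]][, res$choice@sampleAxes]
    expect_gt(abs(cor(u, d$a)), 0.99)
    expect_identical(res$choice@omicsAxis, 1L)
    # strong recovery of the common signal, no false positives
    expect_gte(sum(res$selected[1:10]), 7)
    expect_identical(sum(res$selected[41:1000]), 0L)
})

test_that("common-signal scores factorize as sqrt(K) when slices coincide", {
    spec <- defaultSpec(baseSeed = 5)
    d <- generateSynthetic(spec, 1)
    x <- d$x
    x[, , 2] <- x[, , 1]
    x[, , 3] <- x[, , 1]
    res <- runKTDPipeline(x, d$a)
    uk <- factorMatrices(res$hosvd)[[1]][, res$choice@omicsAxis]
    # identical slices force a constant omics weight 1/sqrt(3)
    expect_equal(uk, rep(1 / sqrt(3), 3), tolerance = 1e-8)
    uj <- factorMatrices(res$hosvd)[[2]][, res$choice@sampleAxes]
    expect_equal(res$scores, sqrt(3) * as.vector(x[, , 1] %*% uj),
        tolerance = 1e-8)
})

test_that("a zero-amplitude tensor yields (almost) no selections", {
    spec <- defaultSpec(nEnsembles = 10, baseSeed = 31, amplitude = 0)
    cs <- runEnsemble(spec, "ktd")
    counts <- cs@counts
    expect_lt(counts$TP + counts$FP, 0.5)
})

test_that("regressionBaseline matches lm and the normal equations", {
    spec <- defaultSpec(baseSeed = 13)
    d <- generateSynthetic(spec, 1)
    fits <- regressionBaseline(d$x, d$a)
    for (i in c(1, 15, 500)) {
        ref <- summary(lm(d$x[i, , 2] ~ d$a))
        expect_equal(fits[[2]]$slope[i], ref$coefficients[2, 1],
            tolerance = 1e-10)
        expect_equal(fits[[2]]$pValue[i], ref$coefficients[2, 4],
            tolerance = 1e-10)
    }
    # hand-computed normal equations on a tiny response
    y <- c(2, 1, 4, 3, 6)
    a <- 1:5
    fit1 <- regressionBaseline(array(y, c(1, 5, 1)), a)
    sxy <- sum((a - 3) * (y - mean(y)))
    sxx <- sum((a - 3)^2)
    expect_equal(fit1[[1]]$slope, sxy / sxx, tolerance = 1e-12)
    # exact linear response drives P toward zero
    exact <- array(rep(2 * a + 1, each = 1), c(1, 5, 1))
    expect_lt(regressionBaseline(exact, a)[[1]]$pValue, 1e-10)
})

test_that("regression null P-values are uniform over noise features", {
    spec <- defaultSpec(baseSeed = 53, amplitude = 0)
    d <- generateSynthetic(spec, 1)
    p <- regressionBaseline(d$x, d$a)[[1]]$pValue
    expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("lassoBaseline obeys the sample-size support bound", {
    spec <- defaultSpec(baseSeed = 19)
    d <- generateSynthetic(spec, 1)
    sel <- lassoBaseline(d$x, d$a)
    for (k in 1:3) {
        expect_lte(length(sel[[k]]), 10)
        expect_gt(length(sel[[k]]), 0)
    }
    # a single perfectly correlated predictor is found
    x1 <- array(0.5, c(2, 10, 1))
    x1[1, , 1] <- d$a
    expect_identical(lassoBaseline(x1, d$a)[[1]], 1L)
})

test_that("rfBaseline selection modes behave as documented", {
    spec <- defaultSpec(baseSeed = 23)
    d <- generateSynthetic(spec, 1)
    top <- rfBaseline(d$x, d$a, mode = "top2N1", N1 = 10, numTrees = 100,
        seed = 1)
    for (k in 1:3) expect_length(top[[k]], 20)
    nz <- rfBaseline(d$x, d$a, mode = "nonzero", N1 = 10, numTrees = 100,
        seed = 1)
    # most of the 20 signal features carry positive importance
    expect_gt(length(intersect(nz[[1]], which(d$omicsMasks[[1]]))), 10)
})

test_that("runEnsemble averages confusion matrices deterministically", {
    spec <- defaultSpec(nEnsembles = 1, baseSeed = 3)
    cs1 <- runEnsemble(spec, "ktd")
    # single ensemble: means equal the run itself (integer counts)
    expect_identical(unlist(cs1@counts[c("TP", "FN", "FP", "TN")]) %% 1,
        c(TP = 0, FN = 0, FP = 0, TN = 0))
    expect_identical(sum(unlist(cs1@counts[c("TP", "FN", "FP", "TN")])), 1000)
    cs2 <- runEnsemble(spec, "ktd")
    expect_identical(cs1@counts, cs2@counts)

    spec3 <- defaultSpec(nEnsembles = 2, baseSeed = 3)
    reg <- runEnsemble(spec3, "regression")
    expect_identical(reg@counts$group, c("k=1", "k=2", "k=3"))
    expect_equal(reg@counts$TP + reg@counts$FN, rep(20, 3))
})
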