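test_that("projectFeatures matches the brute-force loop oracle", {
    set.seed(10)
    b <- randomBlock(10, n = 4, msz = c(3, 3))
    cols <- list(rnorm(3), rnorm(3))
    fake <- new("HOSVDResult",
        factors = list(diag(2), cbind(cols[[1]], rnorm(3), rnorm(3)),
            cbind(cols[[2]], rnorm(3), rnorm(3)), diag(3), diag(3)),
        core = array(0, c(2, 3, 3, 3, 3)),
        modeRoles = c("omics", "sample1", "sample2", "conjugate1", "conjugate2"))
    got <- projectFeatures(b, fake, c(1L, 1L))
    expect_equal(unname(got), bruteProjectPerOmics(blockValues(b), cols),
        tolerance = 1e-12)
})

test_that("basis-vector projection picks out single sample cells", {
    b <- randomBlock(12, n = 5, msz = c(2, 3))
    e1a <- diag(2)
    e1b <- diag(3)
    fake <- new("HOSVDResult",
        factors = list(diag(1), e1a, e1b, e1a, e1b),
        core = array(0, c(1, 2, 3, 2, 3)),
        modeRoles = c("omics", "sample1", "sample2", "conjugate1", "conjugate2"))
    got <- projectFeatures(b, fake, c(1L, 1L))
    expect_equal(unname(got), blockValues(b)[, 1, 1], tolerance = 1e-14)
    # constant feature against a mean-zero vector projects to zero
    v <- array(3, c(2, 2, 3))
    bc <- MultiOmicsBlock(v, omicsId = "const")
    meanZero <- cbind(c(1, -1) / sqrt(2), c(1, 1) / sqrt(2))
    fake2 <- new("HOSVDResult",
        factors = list(diag(1), meanZero, e1b, meanZero, e1b),
        core = array(0, c(1, 2, 3, 2, 3)),
        modeRoles = c("omics", "sample1", "sample2", "conjugate1", "conjugate2"))
    expect_equal(unname(projectFeatures(bc, fake2, c(1L, 1L))),
        rep(0, 2), tolerance = 1e-12)
})

test_that("projectFeaturesShared matches the loop oracle and factorizes", {
    set.seed(11)
    x <- array(rnorm(6 * 4 * 3), c(6, 4, 3))
    uj <- rnorm(4); uk <- rnorm(3)
    fake <- new("HOSVDResult",
        factors = list(cbind(uk, matrix(rnorm(6), 3)),
            cbind(uj, matrix(rnorm(12), 4)), diag(4)),
        core = array(0, c(3, 4, 4)),
        modeRoles = c("omics", "sample1", "conjugate1"))
    got <- projectFeaturesShared(x, fake, list(sample = 1L, omics = 1L))
    expect_equal(got, bruteProjectShared(x, uj, uk), tolerance = 1e-12)

    # identical slices with a constant omics weight factorize to sqrt(K)
    slice <- matrix(rnorm(6 * 4), 6, 4)
    xr <- array(rep(slice, 3), c(6, 4, 3))
    ukc <- rep(1 / sqrt(3), 3)
    fake2 <- new("HOSVDResult",
        factors = list(cbind(ukc, matrix(rnorm(6), 3)),
            cbind(uj, matrix(rnorm(12), 4)), diag(4)),
        core = array(0, c(3, 4, 4)),
        modeRoles = c("omics", "sample1", "conjugate1"))
    expect_equal(projectFeaturesShared(xr, fake2, list(sample = 1L, omics = 1L)),
        sqrt(3) * as.vector(slice %*% uj), tolerance = 1e-12)
})

test_that("estimateSigma is the RMS about zero", {
    expect_equal(estimateSigma(c(3, 4)), sqrt(25 / 2), tolerance = 1e-12)
    expect_equal(estimateSigma(c(3, 4)), 3.535534, tolerance = 1e-6)
    expect_equal(estimateSigma(rep(-2.5, 7)), 2.5)
    sc <- rnorm(50)
    expect_equal(estimateSigma(3 * sc), 3 * estimateSigma(sc),
        tolerance = 1e-12)
    expect_error(estimateSigma(rep(0, 5)), "zero")
    expect_error(estimateSigma(1), "at least 2")
})

test_that("chi2Pvalues matches closed forms and the chi-squared tail", {
    expect_equal(chi2Pvalues(0, 1), 1)
    expect_equal(chi2Pvalues(1.959964, 1), 0.05, tolerance = 1e-6)
    # d = 2: upper tail is exp(-x/2)
    sc2 <- matrix(c(1, 1), 1)
    expect_equal(chi2Pvalues(sc2, 1, df = 2), exp(-1), tolerance = 1e-12)
    expect_equal(chi2Pvalues(matrix(c(0.6, 1.2), 1), 1, df = 2),
        exp(-(0.36 + 1.44) / 2), tolerance = 1e-12)
    expect_error(chi2Pvalues(1, 1, df = 0), "df")
    expect_error(chi2Pvalues(1, 0), "sigma")
    # sign invariance: scores enter squared
    sc <- rnorm(20)
    expect_equal(chi2Pvalues(sc, 1.3), chi2Pvalues(-sc, 1.3))
})

test_that("bhAdjust agrees with an independent step-up oracle", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(c(0.001, 0.5)), c(0.002, 0.5))
    expect_equal(bhAdjust(0.2), 0.2)
    set.seed(12)
    for (rep in 1:1000) {
        p <- runif(sample(1:40, 1))
        expect_equal(bhAdjust(p), stepUpBH(p), tolerance = 1e-12)
    }
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
    expect_error(bhAdjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("raw P-values are near-uniform under a pure Gaussian null", {
    set.seed(13)
    sc <- rnorm(2000)
    p <- chi2Pvalues(sc, estimateSigma(sc))
    # sigma is estimated from the same scores, so only approximate uniformity
    expect_gt(stats::ks.test(p, "punif")$p.value, 0.001)
})

test_that("scoreFeatures assembles per-block tables with thresholds", {
    blks <- list(randomBlock(1, 30, 5, "expr"), randomBlock(2, 50, 5, "meth"))
    set <- MultiOmicsTensorSet(blks)
    h <- hosvd(stackKernels(set))
    choice <- chooseAxes(h, list(NULL))
    fst <- scoreFeatures(set, h, choice,
        thresholds = c(expr = 0.01, meth = 0.05))
    tab <- scoreTable(fst)
    expect_identical(nrow(tab), 80L)
    expect_setequal(unique(tab$threshold), c(0.01, 0.05))
    expect_true(all(tab$adjustedP >= tab$pValue - 1e-12))
    expect_identical(tab$selected, tab$adjustedP <= tab$threshold)
    # per-block sigma differs between blocks of different size/content
    expect_length(unique(tab$sigma), 2L)
    expect_error(scoreFeatures(set, h, choice, thresholds = c(expr = 0.01)),
        "meth")

    # selection flags at a new threshold
    fst2 <- selectFeatures(fst, 0.5)
    expect_identical(scoreTable(fst2)$selected,
        scoreTable(fst2)$adjustedP <= 0.5)

    # all-adjusted-P-=1 edge: nothing selected
    expect_length(selectedFeatures(fst2, omicsId = "nope"), 0L)
})

test_that("selection boundary uses adjustedP <= threshold", {
    tab <- data.frame(omicsId = "b", featureId = c("f1", "f2"),
        score = c(1, 2), sigma = 1, pValue = c(0.001, 0.01),
        adjustedP = c(0.005, 0.02), selected = FALSE, threshold = 0.01)
    fst <- new("FeatureScoreTable", table = tab, df = 1,
        axes = new("AxisChoice", sampleAxes = 1L, omicsAxis = 1L,
            diagnostics = list()))
    out <- scoreTable(selectFeatures(fst, c(b = 0.01)))
    expect_identical(out$selected, c(TRUE, FALSE))
    # boundary equality is selected
    tab$adjustedP <- c(0.01, 0.02)
    fst2 <- new("FeatureScoreTable", table = tab, df = 1, axes = fst@axes)
    expect_identical(scoreTable(selectFeatures(fst2, c(b = 0.01)))$selected,
        c(TRUE, FALSE))
})
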