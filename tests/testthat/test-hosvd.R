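test_that("modeUnfold and modeFold are exact inverses", {
    m <- matrix(1:6, 2, 3)
    expect_identical(modeUnfold(array(m, dim(m)), 1), m)

    t3 <- array(rnorm(8), c(2, 2, 2))
    for (mode in 1:3) {
        u <- modeUnfold(t3, mode)
        expect_identical(dim(u), c(2L, 4L))
        expect_equal(modeFold(u, mode, dim(t3)), t3)
    }
    t4 <- array(rnorm(120), c(2, 3, 4, 5))
    for (mode in 1:4) {
        expect_equal(modeFold(modeUnfold(t4, mode), mode, dim(t4)), t4)
    }
    expect_error(modeUnfold(t3, 4), "mode")
})

test_that("hosvd recovers rank-1 structure", {
    u <- c(3, 4) / 5
    v <- c(1, 2, 2) / 3
    w <- c(2, 1, 2, 4) / 5
    t3 <- outer(outer(u, v), w) * 7
    h <- hosvd(t3)
    core <- coreTensor(h)
    expect_equal(abs(core[1, 1, 1]), 7, tolerance = 1e-12)
    expect_lt(max(abs(core[-1])), 1e-10)
    expect_equal(abs(factorMatrices(h)[[1]][, 1]), abs(u), tolerance = 1e-12)
    expect_equal(abs(factorMatrices(h)[[2]][, 1]), abs(v), tolerance = 1e-12)

    # single-entry tensor: permutation-identity factors, core carries it
    t0 <- array(0, c(2, 2, 2)); t0[1, 1, 1] <- 2
    h0 <- hosvd(t0)
    expect_equal(abs(coreTensor(h0)[1, 1, 1]), 2)
    expect_lt(max(abs(coreTensor(h0)[-1])), 1e-12)
})

test_that("full HOSVD is exact, orthonormal and norm-preserving", {
    for (seed in 1:4) {
        set.seed(seed)
        x <- array(rnorm(3 * 5 * 5), c(3, 5, 5))
        h <- hosvd(x)
        expect_lt(max(abs(reconstruct(h) - x)) / max(abs(x)), 1e-8)
        for (f in factorMatrices(h)) {
            expect_lt(max(abs(crossprod(f) - diag(nrow(f)))), 1e-8)
        }
        expect_equal(sqrt(sum(coreTensor(h)^2)), sqrt(sum(x^2)),
            tolerance = 1e-10)
    }
    expect_error(hosvd(array(0, c(2, 2))), "degenerate")
})

test_that("perturbing one core entry moves the reconstruction by that norm", {
    set.seed(5)
    x <- array(rnorm(24), c(2, 3, 4))
    h <- hosvd(x)
    core <- coreTensor(h)
    core[2, 1, 3] <- core[2, 1, 3] + 0.37
    h2 <- new("HOSVDResult", factors = factorMatrices(h), core = core,
        modeRoles = h@modeRoles)
    expect_equal(sqrt(sum((reconstruct(h2) - x)^2)), 0.37, tolerance = 1e-10)
})

test_that("symmetric-in-last-two-modes tensors give paired factors (eigen oracle)", {
    set.seed(6)
    x <- array(0, c(3, 4, 4))
    for (k in 1:3) {
        a <- matrix(rnorm(16), 4)
        x[k, , ] <- a + t(a)
    }
    h <- hosvd(x)
    u2 <- factorMatrices(h)[[2]]
    u3 <- factorMatrices(h)[[3]]
    for (j in 1:4) {
        expect_lt(min(max(abs(u2[, j] - u3[, j])),
            max(abs(u2[, j] + u3[, j]))), 1e-8)
    }
    # mode-2 factor equals the eigenvectors of the unfolding's Gram matrix
    unf <- modeUnfold(x, 2)
    ev <- eigen(tcrossprod(unf), symmetric = TRUE)$vectors
    for (j in 1:4) {
        expect_lt(min(max(abs(u2[, j] - ev[, j])),
            max(abs(u2[, j] + ev[, j]))), 1e-8)
    }
})

test_that("K=1, m=1 kernel HOSVD reproduces the kernel eigendecomposition", {
    b <- randomBlock(8, n = 20, msz = 6)
    kt <- stackKernels(MultiOmicsTensorSet(b))
    h <- hosvd(kt)
    kmat <- matrix(kernelValues(kt)[1, , ], 6, 6)
    eg <- eigen(kmat, symmetric = TRUE)
    u <- factorMatrices(h)[[2]]
    for (j in 1:6) {
        expect_lt(min(max(abs(u[, j] - eg$vectors[, j])),
            max(abs(u[, j] + eg$vectors[, j]))), 1e-8)
    }
    # core diagonal carries the eigenvalues (up to sign from the omics factor)
    core <- coreTensor(h)
    expect_equal(abs(vapply(1:6, function(l) core[1, l, l], numeric(1))),
        abs(eg$values), tolerance = 1e-8)
    # core is symmetric in the paired sample modes
    expect_equal(core[1, , ], t(core[1, , ]), tolerance = 1e-8)
})

test_that("checkSymmetry flags symmetric and asymmetric inputs correctly", {
    blks <- lapply(1:3, function(k) randomBlock(k, 10, 5, paste0("o", k)))
    kt <- stackKernels(MultiOmicsTensorSet(blks))
    rep1 <- checkSymmetry(hosvd(kt))
    expect_lt(rep1$factorDeviation, 1e-6)
    expect_lt(rep1$coreDeviation, 1e-6)

    set.seed(42)
    asym <- kernelValues(kt) + array(runif(length(kernelValues(kt))), dim(kernelValues(kt)))
    kt2 <- new("KernelTensor", values = asym, modeRoles = kt@modeRoles,
        omicsIds = kt@omicsIds)
    rep2 <- checkSymmetry(hosvd(kt2))
    expect_gt(rep2$coreDeviation, 1e-3)
})
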