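# Independent oracles used across the test files. These stay deliberately
# naive (explicit loops, textbook definitions) so they cannot share a bug
# with the vectorized implementation.

# u_i = sum over all sample-mode index tuples of x[i, j...] * prod_s u_s[j_s]
bruteProjectPerOmics <- function(values, cols) {
    d <- dim(values)
    msz <- d[-1L]
    out <- numeric(d[1L])
    grid <- expand.grid(lapply(msz, seq_len))
    for (i in seq_len(d[1L])) {
        acc <- 0
        for (g in seq_len(nrow(grid))) {
            idx <- as.integer(grid[g, ])
            w <- 1
            for (s in seq_along(idx)) w <- w * cols[[s]][idx[s]]
            acc <- acc + do.call(`[`, c(list(values), i, as.list(idx))) * w
        }
        out[i] <- acc
    }
    out
}

# u_i = sum_{j,k} x[i,j,k] uj[j] uk[k] (m = 1 shared-feature case)
bruteProjectShared <- function(x, uj, uk) {
    d <- dim(x)
    out <- numeric(d[1L])
    for (i in seq_len(d[1L])) {
        acc <- 0
        for (j in seq_len(d[2L])) {
            for (k in seq_len(d[3L])) {
                acc <- acc + x[i, j, k] * uj[j] * uk[k]
            }
        }
        out[i] <- acc
    }
    out
}

# step-up BH from the definition: sort ascending, p * n / rank, cumulative
# minimum from the largest rank down, cap at 1, restore input order
stepUpBH <- function(p) {
    n <- length(p)
    o <- order(p)
    scaled <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(scaled)))
    adj <- pmin(adj, 1)
    out <- numeric(n)
    out[o] <- adj
    out
}

# tiny helper: random block with reproducible values
randomBlock <- function(seed, n, msz, omicsId = "x") {
    set.seed(seed)
    MultiOmicsBlock(array(rnorm(n * prod(msz)), dim = c(n, msz)),
        omicsId = omicsId)
}

defaultSpec <- function(nEnsembles = 1L, baseSeed = 7L, amplitude = 1) {
    SyntheticSpec(nEnsembles = nEnsembles, baseSeed = baseSeed,
        amplitude = amplitude)
}
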