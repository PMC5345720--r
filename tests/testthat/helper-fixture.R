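# Frozen simulated fixture shared across the suite: 60 lines x 200 markers,
# target heritability 0.5, genotype seed 11, trait seed 12. Built once per
# test run and cached.
.fixtureCache <- new.env(parent = emptyenv())

fixtureData <- function() {
    if (is.null(.fixtureCache$fx)) {
        G <- simulateGenotypes(n = 60, m = 200, seed = 11)
        K <- eigenKinship(computeKinship(G))
        sim <- simulateTrait(K, h2 = 0.5, seed = 12)
        fit <- remlFit(sim$y, eig = K)
        .fixtureCache$fx <- list(G = G, K = K, sim = sim, fit = fit)
    }
    .fixtureCache$fx
}

# Brute-force fold-deletion BLUP residuals at fixed lambda and a fixed
# beta: the independent oracle for the leverage-corrected residuals.
# Predicts each fold from the remaining individuals through the kinship
# block inverse, no hat matrix involved.
bruteForceFoldResiduals <- function(y, X, A, folds, lambda, beta) {
    n <- length(y)
    xi <- y - drop(as.matrix(X) %*% beta)
    out <- numeric(n)
    for (k in seq_len(folds@K)) {
        te <- which(folds@assignment == k)
        tr <- setdiff(seq_len(n), te)
        pred <- A[te, tr, drop = FALSE] %*%
            solve(A[tr, tr] + diag(lambda, length(tr)), xi[tr])
        out[te] <- xi[te] - drop(pred)
    }
    out
}

# Direct (unrotated) evaluation of the restricted log-likelihood with the
# same additive constant convention as the package: profiles beta and
# sigmaXi2 at fixed lambda using explicit V = sigmaXi2 (A + lambda I).
directRemlLoglik <- function(lambda, y, X, A) {
    n <- length(y); p <- ncol(X)
    M <- A + diag(lambda, n)
    Mi <- solve(M)
    XtMiX <- t(X) %*% Mi %*% X
    beta <- solve(XtMiX, t(X) %*% Mi %*% y)
    r <- y - X %*% beta
    s2xi <- drop(t(r) %*% Mi %*% r) / (n - p)
    -0.5 * ((n - p) * log(s2xi) +
            as.numeric(determinant(M)$modulus) +
            as.numeric(determinant(XtMiX)$modulus) + (n - p))
}
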