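test_that("fixed-model hat matrix is an idempotent projector of rank p", {
    set.seed(42)
    X <- cbind(1, matrix(stats::rnorm(30), 10, 3))
    H <- hatFixed(X)
    expect_lt(max(abs(H %*% H - H)), 1e-10)
    expect_equal(sum(diag(H)), ncol(X), tolerance = 1e-10)

    W <- crossprod(matrix(stats::rnorm(100), 10, 10)) + diag(10)
    Hw <- hatFixed(X, W)
    expect_lt(max(abs(Hw %*% Hw - Hw)), 1e-8)
    expect_equal(sum(diag(Hw)), ncol(X), tolerance = 1e-8)

    # mean-only model: uniform leverage 1/n
    Hm <- hatFixed(matrix(1, 3, 1))
    expect_equal(Hm, matrix(1 / 3, 3, 3))
})

test_that("random hat matrix shrinkage follows delta/(delta+lambda)", {
    KI <- eigenKinship(diag(4))
    hr <- hatRandom(KI, lambda = 1)
    expect_equal(hatDiag(hr), rep(0.5, 4))
    expect_lt(max(abs(hatFull(hr) - diag(0.5, 4))), 1e-12)

    fx <- fixtureData()
    expect_lt(max(hatDiag(hatRandom(fx$K, 1e9))), 1e-6)
    expect_error(hatRandom(fx$K, 0), "positive")
    expect_error(hatRandom(fx$K, -1), "positive")
})

test_that("eigen-shortcut leverages equal the explicit covariance route", {
    # H_R = sigmaXi2 A (A sigmaXi2 + I sigma2)^-1 computed two ways
    G <- simulateGenotypes(n = 40, m = 90, seed = 8)
    K <- eigenKinship(computeKinship(G))
    sxi2 <- 0.7; s2 <- 0.4; lam <- s2 / sxi2
    HRexplicit <- sxi2 * K@A %*% solve(K@A * sxi2 + diag(s2, 40))
    hr <- hatRandom(K, lam)
    expect_lt(max(abs(hatDiag(hr) - diag(HRexplicit))), 1e-10)
    expect_lt(max(abs(hatFull(hr) - HRexplicit)), 1e-10)
    idx <- c(3, 17, 25)
    expect_lt(max(abs(hatBlock(hr, idx) - HRexplicit[idx, idx])), 1e-10)
    # spectrum and effective degrees of freedom
    expect_equal(sort(eigen(hatFull(hr), symmetric = TRUE,
                            only.values = TRUE)$values),
                 sort(eigenValues(K) / (eigenValues(K) + lam)),
                 tolerance = 1e-10)
})

test_that("trace of H_R is monotone decreasing in lambda", {
    fx <- fixtureData()
    lams <- c(0.01, 0.1, 1, 10, 100)
    tr <- vapply(lams, function(l) sum(hatDiag(hatRandom(fx$K, l))),
                 numeric(1))
    expect_true(all(diff(tr) < 0))
})

test_that("mixed hat matrix limits and fitted-value identity hold", {
    n <- 30
    G <- simulateGenotypes(n = n, m = 70, seed = 15)
    K <- eigenKinship(computeKinship(G))
    sim <- simulateTrait(K, h2 = 0.5, seed = 16)
    X <- cbind(1, stats::rnorm(n))
    lam <- 0.8
    bb <- blueBlup(sim$y, X, K, lam)
    # V^-1-weighted fixed hat (scale of V cancels in H_F)
    Vs <- K@A + diag(lam, n)
    HF <- hatFixed(X, solve(Vs))
    HR <- hatFull(hatRandom(K, lam))
    HM <- hatMixed(HF, HR)
    fitted <- drop(X %*% bb$beta) + bb$xiHat
    expect_lt(max(abs(drop(HM %*% sim$y) - fitted)), 1e-8)

    # limits: H_R -> 0 gives H_F; H_R -> I gives I
    expect_lt(max(abs(hatMixed(HF, matrix(0, n, n)) - HF)), 1e-12)
    expect_lt(max(abs(hatMixed(HF, diag(n)) - diag(n))), 1e-12)
})

test_that("leave-one-out PRESS corrects residuals by leverage", {
    r <- pressLoo(c(1, 1), c(0.5, 0.5), ss = 10)
    expect_equal(press(r), 8)
    expect_equal(predictedResiduals(r), c(2, 2))
    # zero leverage: PRESS = ERESS
    r0 <- pressLoo(c(1, -2), c(0, 0), ss = 10)
    expect_equal(press(r0), 5)
    expect_error(pressLoo(c(1, 1), c(1, 0.5), ss = 1), "saturated")
})

test_that("LOO corrected residuals equal brute-force delete-one refits", {
    n <- 30
    G <- simulateGenotypes(n = n, m = 60, seed = 21)
    K <- eigenKinship(computeKinship(G))
    sim <- simulateTrait(K, h2 = 0.5, seed = 22)
    lam <- 0.6
    fit <- remlFit(sim$y, NULL, K, lambdaFixed = lam)
    xi <- centeredPhenotypes(fit)
    ehat <- xi - blup(fit)
    r <- pressLoo(ehat, hatDiag(hatRandom(K, lam)), xiObs = xi)
    folds <- new("FoldAssignment", n = as.integer(n), K = as.integer(n),
                 assignment = seq_len(n), seed = NA_integer_)
    oracle <- bruteForceFoldResiduals(sim$y, matrix(1, n, 1), K@A, folds,
                                      lam, fixedEffects(fit))
    expect_lt(max(abs(predictedResiduals(r) - oracle)), 1e-8)
})

test_that("K-fold PRESS with K = n is identical to leave-one-out", {
    fx <- fixtureData()
    lam <- varianceRatio(fx$fit)
    xi <- centeredPhenotypes(fx$fit)
    ehat <- xi - blup(fx$fit)
    hr <- hatRandom(fx$K, lam)
    loo <- pressLoo(ehat, hatDiag(hr), xiObs = xi)
    kf <- pressKfold(ehat, hr, makeFolds(60, 60, seed = 2), xiObs = xi)
    expect_equal(press(kf), press(loo), tolerance = 1e-12)
    expect_lt(max(abs(predictedResiduals(kf) - predictedResiduals(loo))),
              1e-12)
})

test_that("fixed-model K-fold toy reproduces the hand calculation", {
    # mean-only model, y = (0, 0, 3): beta = 1, ehat = (-1, -1, 2),
    # leverages 1/3, predicted residuals (-1.5, -1.5, 3), PRESS = 13.5;
    # deleting obs 3 refits the mean to 0 and predicts residual 3
    y <- c(0, 0, 3)
    X <- matrix(1, 3, 1)
    H <- hatFixed(X)
    ehat <- y - drop(H %*% y)
    folds <- new("FoldAssignment", n = 3L, K = 3L,
                 assignment = 1:3, seed = NA_integer_)
    r <- pressKfold(ehat, H, folds, ss = sum((y - mean(y))^2))
    expect_equal(predictedResiduals(r), c(-1.5, -1.5, 3))
    expect_equal(press(r), 13.5)
    expect_equal(y[3] - mean(y[1:2]), 3)  # delete-one refit agrees
})

test_that("K-fold corrected residuals equal brute-force fold deletion", {
    n <- 40
    G <- simulateGenotypes(n = n, m = 100, seed = 31)
    K <- eigenKinship(computeKinship(G))
    sim <- simulateTrait(K, h2 = 0.4, seed = 32)
    lam <- 1.2
    fit <- remlFit(sim$y, NULL, K, lambdaFixed = lam)
    xi <- centeredPhenotypes(fit)
    ehat <- xi - blup(fit)
    folds <- makeFolds(n, 5, seed = 9)
    r <- pressKfold(ehat, hatRandom(K, lam), folds, xiObs = xi)
    oracle <- bruteForceFoldResiduals(sim$y, matrix(1, n, 1), K@A, folds,
                                      lam, fixedEffects(fit))
    expect_lt(max(abs(predictedResiduals(r) - oracle)), 1e-8)
})

test_that("GCV equals LOO PRESS under equal leverages and ERESS at hbar 0", {
    # A = I: every leverage equals the mean leverage
    KI <- eigenKinship(diag(12))
    y <- local({ set.seed(3); stats::rnorm(12) })
    lam <- 2
    bb <- blueBlup(y, NULL, KI, lam)
    xi <- y - bb$beta
    ehat <- xi - bb$xiHat
    hr <- hatRandom(KI, lam)
    expect_equal(press(gcvGress(ehat, hr, xiObs = xi)),
                 press(pressLoo(ehat, hatDiag(hr), xiObs = xi)),
                 tolerance = 1e-12)

    # matrix form [n^-1 tr(I - H_R)]^-2 * ERESS equals the scalar form
    fx <- fixtureData()
    lamf <- varianceRatio(fx$fit)
    xif <- centeredPhenotypes(fx$fit)
    ef <- xif - blup(fx$fit)
    hrf <- hatRandom(fx$K, lamf)
    gress <- press(gcvGress(ef, hrf, xiObs = xif))
    HR <- hatFull(hrf)
    expect_equal(gress,
                 sum(ef^2) / (mean(diag(diag(60) - HR)))^2 / 1,
                 tolerance = 1e-12)

    expect_equal(press(gcvGress(c(1, 2), leverages = c(0, 0), ss = 9)), 5)
})

test_that("PRESS never falls below ERESS (leverages deflate residuals)", {
    for (s in 1:5) {
        n <- 35
        G <- simulateGenotypes(n = n, m = 80, seed = 40 + s)
        K <- eigenKinship(computeKinship(G))
        sim <- simulateTrait(K, h2 = 0.3 + 0.1 * s, seed = 50 + s)
        fit <- remlFit(sim$y, NULL, K)
        lam <- varianceRatio(fit)
        xi <- centeredPhenotypes(fit)
        ehat <- xi - blup(fit)
        r <- pressLoo(ehat, hatDiag(hatRandom(K, lam)), xiObs = xi)
        expect_gte(press(r), sum(ehat^2))
        expect_lte(predictability(r), modelFit(fit)[["eress"]])
    }
})

test_that("lambda tuning dominates the REML point and matches a dense grid", {
    fx <- fixtureData()
    tn <- tuneLambda(fx$sim$y, eig = fx$K, fit = fx$fit)
    expect_gte(tn$r2Max, tn$r2AtREML - 1e-12)

    # dense-grid oracle around the MPE
    dense <- 10^seq(log10(tn$lambdaREML) - 3, log10(tn$lambdaREML) + 3,
                    length.out = 1000)
    r2d <- vapply(dense, function(l)
        hatpress:::.r2Profile(l, fx$sim$y, matrix(1, 60, 1), fx$K,
                              "HAT_LOO"), numeric(1))
    expect_gte(tn$r2Max, max(r2d) - 1e-8)
    spacing <- diff(log10(dense))[1]
    expect_lte(abs(log10(tn$lambdaMPE) - log10(dense[which.max(r2d)])),
               2 * spacing)

    # GCV objective obeys the same dominance
    tg <- tuneLambda(fx$sim$y, eig = fx$K, fit = fx$fit, objective = "GCV")
    expect_gte(tg$r2Max, tg$r2AtREML - 1e-12)
})

test_that("predictability decays toward zero as lambda grows", {
    fx <- fixtureData()
    r2far <- hatpress:::.r2Profile(1e8, fx$sim$y, matrix(1, 60, 1), fx$K,
                                   "HAT_LOO")
    # predictions shrink to the mean; R2 approaches -n/(n-1) correction
    # of the mean-only model, i.e. about 0 up to LOO inflation
    expect_lt(abs(r2far), 0.15)
})
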