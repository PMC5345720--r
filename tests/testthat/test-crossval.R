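test_that("fold construction is balanced, exhaustive, and seeded", {
    f <- makeFolds(10, 5, seed = 1)
    expect_equal(unname(tabulate(f@assignment, 5)), rep(2L, 5))

    f2 <- makeFolds(10, 3, seed = 1)
    expect_equal(sort(tabulate(f2@assignment, 3)), c(3L, 3L, 4L))

    expect_identical(makeFolds(50, 7, seed = 99)@assignment,
                     makeFolds(50, 7, seed = 99)@assignment)
    expect_false(identical(makeFolds(50, 7, seed = 1)@assignment,
                           makeFolds(50, 7, seed = 2)@assignment))
    expect_error(makeFolds(10, 1), "K must")
    expect_error(makeFolds(10, 11), "K must")
})

test_that("zero between-fold kinship predicts nothing (R2 near 0)", {
    # block-diagonal A aligned with the folds: A_{k,-k} = 0
    n <- 30
    blocks <- lapply(1:3, function(b) {
        set.seed(b)
        M <- matrix(stats::rnorm(100), 10, 10)
        crossprod(M) / 10
    })
    A <- matrix(0, n, n)
    for (b in 1:3)
        A[(b - 1) * 10 + 1:10, (b - 1) * 10 + 1:10] <- blocks[[b]]
    A <- A * n / sum(diag(A))
    K <- eigenKinship(A)
    y <- local({ set.seed(77); stats::rnorm(n) })
    folds <- new("FoldAssignment", n = 30L, K = 3L,
                 assignment = rep(1:3, each = 10), seed = NA_integer_)
    beta0 <- 0
    res <- kfoldCV(y, matrix(1, n, 1), K, folds, reestimate = FALSE,
                   lambdaFixed = 1, betaFixed = beta0)
    xi <- y - beta0
    expect_equal(press(res), sum(xi^2), tolerance = 1e-10)
    expect_equal(predictedResiduals(res), xi, tolerance = 1e-10)
})

test_that("fixed-lambda CV with whole-sample beta matches HAT exactly", {
    fx <- fixtureData()
    lam <- varianceRatio(fx$fit)
    xi <- centeredPhenotypes(fx$fit)
    ehat <- xi - blup(fx$fit)
    hr <- hatRandom(fx$K, lam)
    for (Kf in c(3, 6, 15)) {
        folds <- makeFolds(60, Kf, seed = Kf)
        hatres <- pressKfold(ehat, hr, folds, xiObs = xi)
        cvres <- kfoldCV(fx$sim$y, NULL, fx$K, folds, reestimate = FALSE,
                         lambdaFixed = lam,
                         betaFixed = fixedEffects(fx$fit))
        expect_lt(max(abs(predictedResiduals(hatres) -
                          predictedResiduals(cvres))), 1e-10)
        expect_equal(press(hatres), press(cvres), tolerance = 1e-10)
    }
})

test_that("re-estimating CV stays close to HAT on simulated data", {
    fx <- fixtureData()
    folds <- makeFolds(60, 10, seed = 4)
    cvres <- kfoldCV(fx$sim$y, NULL, fx$K, folds, reestimate = TRUE)
    hatres <- pressKfold(
        centeredPhenotypes(fx$fit) - blup(fx$fit),
        hatRandom(fx$K, varianceRatio(fx$fit)), folds,
        xiObs = centeredPhenotypes(fx$fit))
    # per-fold lambda re-estimation perturbs, but does not transform,
    # the predictability; FIT bounds the HAT value from above
    expect_lt(abs(predictability(cvres) - predictability(hatres)), 0.25)
    expect_lte(predictability(hatres), modelFit(fx$fit)[["eress"]] + 1e-12)
})

test_that("total SS is invariant to the fold assignment at fixed beta", {
    fx <- fixtureData()
    lam <- varianceRatio(fx$fit)
    beta <- fixedEffects(fx$fit)
    sss <- vapply(1:4, function(s)
        totalSS(kfoldCV(fx$sim$y, NULL, fx$K, makeFolds(60, 5, seed = s),
                        reestimate = FALSE, lambdaFixed = lam,
                        betaFixed = beta)), numeric(1))
    expect_lt(diff(range(sss)), 1e-10)
})

test_that("replicated partitions report mean and SE correctly", {
    fx <- fixtureData()
    one <- replicateCV(fx$sim$y, NULL, fx$K, K = 5, reps = 1, seed = 1,
                       method = "HAT", fit = fx$fit)
    expect_true(is.na(one$se))

    # K = n: the partition is unique, so replicate R2 has zero spread
    loo <- replicateCV(fx$sim$y, NULL, fx$K, K = 60, reps = 3, seed = 1,
                       method = "HAT", fit = fx$fit)
    expect_equal(loo$se, 0, tolerance = 1e-15)

    many <- replicateCV(fx$sim$y, NULL, fx$K, K = 5, reps = 8, seed = 1,
                        method = "HAT", fit = fx$fit)
    expect_length(many$r2, 8)
    expect_equal(many$mean, mean(many$r2))
    expect_equal(many$se, stats::sd(many$r2) / sqrt(8))
})

test_that("replicate SE shrinks roughly like 1/sqrt(reps)", {
    fx <- fixtureData()
    few <- replicateCV(fx$sim$y, NULL, fx$K, K = 4, reps = 4, seed = 10,
                       method = "HAT", fit = fx$fit)
    lots <- replicateCV(fx$sim$y, NULL, fx$K, K = 4, reps = 36, seed = 10,
                        method = "HAT", fit = fx$fit)
    # SE ratio should be near sqrt(36/4) = 3; allow wide Monte Carlo slack
    expect_gt(few$se / lots$se, 1.2)
})

test_that("fold files round-trip bit-exactly", {
    f <- makeFolds(20, 4, seed = 6)
    ids <- paste0("ind", 1:20)
    path <- tempfile(fileext = ".tsv")
    writeFolds(f, ids, path)
    f2 <- readFolds(path, ids)
    expect_identical(f2@assignment, f@assignment)
    # shuffled id order is honored by id join
    shuf <- sample(ids)
    f3 <- readFolds(path, shuf)
    expect_identical(f3@assignment, f@assignment[match(shuf, ids)])
})
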