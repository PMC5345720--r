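# Run code under a temporary seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    force(code)
}

#' Random balanced K-way partition
#'
#' Shuffles 1..n with the seeded generator and deals fold labels
#' round-robin, so fold sizes differ by at most one and the same
#' (n, K, seed) always reproduces the same partition.
#'
#' @param n number of individuals
#' @param K number of folds, 2 <= K <= n
#' @param seed integer seed
#' @return a [FoldAssignment-class]
#' @export
makeFolds <- function(n, K, seed = 1L) {
    n <- as.integer(n); K <- as.integer(K)
    if (is.na(K) || K < 2L || K > n)
        stop("K must satisfy 2 <= K <= n")
    perm <- .withSeed(seed, sample.int(n))
    assignment <- integer(n)
    assignment[perm] <- rep_len(seq_len(K), n)
    new("FoldAssignment", n = n, K = K, assignment = assignment,
        seed = as.integer(seed))
}

# GLS fixed effects at fixed lambda with V proportional to (A + lambda I),
# solved by Cholesky on the training block (no eigendecomposition needed).
.glsBeta <- function(y, X, M) {
    ch <- chol(M)
    Miy <- backsolve(ch, forwardsolve(t(ch), y))
    MiX <- backsolve(ch, forwardsolve(t(ch), X))
    drop(solve(crossprod(X, MiX), crossprod(X, Miy)))
}

#' True K-fold cross-validation for GBLUP
#'
#' The reference ("oracle") cross-validation: for each fold k the model is
#' fitted on the training individuals only and the held-out polygenic
#' effects are predicted from the between-fold kinship,
#' xiHat_k = A_(k,-k) (A_(-k,-k) + lambda I)^-1 (y_-k - X_-k beta_-k),
#' the held-out observed effects are xi_k = y_k - X_k beta_-k, and
#' PRESS = sum_k |xi_k - xiHat_k|^2 with R2 = 1 - PRESS/SS. SS is the sum
#' of squares of the concatenated per-fold xi about their mean. The
#' training kinship is the sub-block of the whole-sample matrix.
#'
#' With `reestimate = TRUE` the variance ratio is re-estimated by REML in
#' every training fold (each fold pays its own eigendecomposition).
#' With `reestimate = FALSE` a fixed `lambdaFixed` is used and, if
#' `betaFixed` is supplied, the whole-sample fixed effects as well — the
#' configuration under which the result coincides exactly with the
#' leverage-corrected residuals of [pressKfold()].
#'
#' @inheritParams remlFit
#' @param folds a [FoldAssignment-class]
#' @param reestimate re-fit REML per training fold
#' @param lambdaFixed variance ratio used when `reestimate = FALSE`
#' @param betaFixed optional fixed-effect vector used for every fold
#'   (otherwise beta is re-estimated by GLS per training fold)
#' @return a [PredictabilityResult-class] with method "CV"
#' @export
kfoldCV <- function(y, X = NULL, eig, folds, reestimate = TRUE,
                    lambdaFixed = NULL, betaFixed = NULL) {
    y <- as.numeric(y)
    n <- length(y)
    if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
    X <- as.matrix(X)
    if (folds@n != n) stop("fold assignment does not match data size")
    A <- if (is(eig, "KinshipEigen")) eig@A else as.matrix(eig)
    if (!reestimate && is.null(lambdaFixed))
        stop("lambdaFixed is required when reestimate = FALSE")

    xiAll <- numeric(n)
    residAll <- numeric(n)
    lambdas <- numeric(folds@K)
    for (k in seq_len(folds@K)) {
        te <- which(folds@assignment == k)
        tr <- setdiff(seq_len(n), te)
        Atr <- A[tr, tr, drop = FALSE]
        if (reestimate) {
            fitk <- tryCatch(
                remlFit(y[tr], X[tr, , drop = FALSE], eigenKinship(Atr)),
                error = function(e)
                    stop("REML failed in training fold ", k, ": ",
                         conditionMessage(e)))
            if (!fitk@identifiable)
                stop("variance ratio unidentifiable in training fold ", k)
            lamk <- varianceRatio(fitk)
            betak <- fixedEffects(fitk)
        } else {
            lamk <- lambdaFixed
            betak <- betaFixed
        }
        M <- Atr + diag(lamk, length(tr))
        if (is.null(betak))
            betak <- .glsBeta(y[tr], X[tr, , drop = FALSE], M)
        xiTr <- y[tr] - drop(X[tr, , drop = FALSE] %*% betak)
        pred <- drop(A[te, tr, drop = FALSE] %*% solve(M, xiTr))
        xiTe <- y[te] - drop(X[te, , drop = FALSE] %*% betak)
        xiAll[te] <- xiTe
        residAll[te] <- xiTe - pred
        lambdas[k] <- lamk
    }
    ss <- sum((xiAll - mean(xiAll))^2)
    .newPredictability("CV", folds@K, sum(residAll^2), ss, residAll,
                       mean(lambdas))
}

#' Replicated random partitions: mean predictability and its SE
#'
#' Repeats a K-fold analysis over `reps` independent random partitions
#' (seeds seed, seed+1, ...) and reports the per-replicate R2 values with
#' their mean and standard error. `method = "HAT"` corrects whole-sample
#' residuals by fold leverages (one model fit in total, via
#' [pressKfold()]); `method = "CV"` runs the full per-fold re-estimation
#' engine ([kfoldCV()]). With K = n the partition is unique, so the SE is
#' zero by construction.
#'
#' @inheritParams kfoldCV
#' @param K number of folds per replicate
#' @param reps number of random partitions (>= 1)
#' @param seed seed of the first partition
#' @param method "HAT" or "CV"
#' @param fit optional whole-sample [MixedModelFit-class] reused for the
#'   HAT method (fitted here when absent)
#' @return list with `r2` (per replicate), `mean`, `se` (NA when
#'   reps = 1), `method`, `K`, and `last` (the last replicate's
#'   [PredictabilityResult-class])
#' @export
replicateCV <- function(y, X = NULL, eig, K, reps = 20L, seed = 1L,
                        method = c("HAT", "CV"), fit = NULL,
                        reestimate = TRUE, lambdaFixed = NULL) {
    method <- match.arg(method)
    if (reps < 1L) stop("reps must be >= 1")
    y <- as.numeric(y)
    n <- length(y)
    if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
    if (method == "HAT") {
        if (is.null(fit)) fit <- remlFit(y, X, eig)
        lam <- if (is.null(lambdaFixed)) varianceRatio(fit) else lambdaFixed
        hr <- hatRandom(eig, lam)
        xiObs <- centeredPhenotypes(fit)
        ehat <- xiObs - blup(fit)
    }
    r2s <- numeric(reps)
    res <- NULL
    for (r in seq_len(reps)) {
        folds <- makeFolds(n, K, seed = seed + r - 1L)
        res <- if (method == "HAT")
            pressKfold(ehat, hr, folds, xiObs = xiObs, lambda = lam)
        else
            kfoldCV(y, X, eig, folds, reestimate = reestimate,
                    lambdaFixed = lambdaFixed)
        r2s[r] <- predictability(res)
    }
    list(r2 = r2s, mean = mean(r2s),
         se = if (reps > 1L) stats::sd(r2s) / sqrt(reps) else NA_real_,
         method = method, K = as.integer(K), last = res)
}
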