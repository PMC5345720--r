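#' Fixed-model hat matrix
#'
#' H_F = X (X'WX)^-1 X'W, the (weighted) least-squares projector mapping
#' observed to fitted values. H_F is idempotent with trace equal to the
#' number of fixed effects. With `Vinv` from a mixed-model fit the weight
#' is W = V^-1 and H_F becomes the marginal fixed-effect hat matrix
#' X (X'V^-1X)^-1 X'V^-1 used when combining with the random part (see
#' [hatMixed()]).
#'
#' @param X n x p full-rank design matrix
#' @param W optional n x n symmetric positive-definite weight matrix
#'   (default identity)
#' @return the n x n fixed-model hat matrix
#' @export
hatFixed <- function(X, W = NULL) {
    X <- as.matrix(X)
    n <- nrow(X)
    if (qr(X)$rank < ncol(X)) stop("X is rank deficient")
    if (is.null(W)) {
        XtWX <- crossprod(X)
        XtW <- t(X)
    } else {
        W <- as.matrix(W)
        if (!isTRUE(all.equal(W, t(W), tolerance = 1e-8)))
            stop("W must be symmetric")
        XtW <- crossprod(X, W)
        XtWX <- XtW %*% X
    }
    ch <- tryCatch(chol(XtWX), error = function(e)
        stop("X'WX is singular"))
    X %*% chol2inv(ch) %*% XtW
}

#' Random-effect hat matrix from the kinship eigen pair
#'
#' Builds H_R = sigmaXi2 A V^-1 = U diag(delta_j/(delta_j+lambda)) U' in
#' factored form. The shrinkage form delta/(delta+lambda) remains valid
#' when eigenvalues are exactly zero (where the matrix inverse form
#' through D^-1 would not exist). H_R maps the centered phenotypes to the
#' BLUPs; its diagonal entries are the leverages ("conflict-of-interest
#' factors") that deflate the estimated residuals.
#'
#' @param eig a [KinshipEigen-class] with the eigen pair filled
#' @param lambda variance ratio sigma2/sigmaXi2, finite and > 0 (lambda = 0
#'   with a full-rank kinship would give unit leverages and undefined
#'   leave-one-out residuals)
#' @return a [HatRandom-class]
#' @export
hatRandom <- function(eig, lambda) {
    if (!is.numeric(lambda) || length(lambda) != 1L ||
        !is.finite(lambda) || lambda <= 0)
        stop("lambda must be a finite positive scalar")
    d <- eigenValues(eig)
    new("HatRandom", lambda = lambda, shrink = d / (d + lambda),
        U = eigenVectors(eig))
}

#' @describeIn hatRandom leverages (diagonal of H_R) without forming H_R
#' @param hat a [HatRandom-class]
#' @export
hatDiag <- function(hat) {
    drop((hat@U^2) %*% hat@shrink)
}

#' @describeIn hatRandom a diagonal block H_kk of H_R for the given rows
#' @param idx integer indices of the block
#' @export
hatBlock <- function(hat, idx) {
    Uk <- hat@U[idx, , drop = FALSE]
    Uk %*% (hat@shrink * t(Uk))
}

#' @describeIn hatRandom materialize the full n x n H_R (guarded: refuse
#'   above `maxN` rows unless `force = TRUE`)
#' @param maxN,force guard against materializing huge matrices
#' @export
hatFull <- function(hat, maxN = 10000L, force = FALSE) {
    n <- nrow(hat@U)
    if (n > maxN && !force)
        stop("refusing to materialize a ", n, " x ", n,
             " hat matrix; use hatDiag()/hatBlock() or force = TRUE")
    hat@U %*% (hat@shrink * t(hat@U))
}

#' Mixed-model hat matrix
#'
#' Combines the fixed and random parts as H_M = H_F + H_R (I - H_F),
#' where H_F must be the V^-1-weighted fixed-effect hat matrix. H_M maps
#' the observed phenotypes to the fitted values X beta_hat + xi_hat; the
#' conditional residuals y - X beta_hat - xi_hat are (I - H_M) y.
#'
#' @param HF n x n fixed-model hat matrix built with W = V^-1
#' @param HR n x n random-effect hat matrix (a [HatRandom-class] or a
#'   materialized matrix)
#' @return the n x n mixed-model hat matrix
#' @export
hatMixed <- function(HF, HR) {
    if (is(HR, "HatRandom")) HR <- hatFull(HR)
    HF <- as.matrix(HF); HR <- as.matrix(HR)
    if (!all(dim(HF) == dim(HR)))
        stop("H_F and H_R must have the same dimension")
    HF + HR %*% (diag(nrow(HF)) - HF)
}

.newPredictability <- function(method, folds, press, ss, resid, lambda,
                               repMean = NA_real_, repSE = NA_real_) {
    new("PredictabilityResult", method = method, folds = as.integer(folds),
        press = press, ss = ss, r2 = 1 - press / ss,
        residualsPred = resid, lambdaUsed = lambda,
        repMean = repMean, repSE = repSE)
}

#' Leave-one-out PRESS by leverage correction
#'
#' Corrects each estimated residual e_hat_j = xi_j - xiHat_j by its
#' leverage: e_j = e_hat_j / (1 - h_jj). PRESS = sum e_j^2 and the
#' predictability is R2 = 1 - PRESS/SS. Because every h_jj lies in
#' [0, 1), PRESS >= ERESS always, so the HAT predictability never exceeds
#' the model fit.
#'
#' @param residualsEst estimated residuals xi - xiHat from the whole-sample
#'   fit
#' @param leverages diagonal entries of the random-effect (or mixed) hat
#'   matrix, all < 1
#' @param ss total sum of squares of the centered phenotypes about their
#'   mean; computed from `xiObs` when that is supplied instead
#' @param xiObs optional centered phenotypes used to compute `ss`
#' @param lambda the variance ratio used (recorded in the result)
#' @return a [PredictabilityResult-class] with method "HAT"
#' @export
pressLoo <- function(residualsEst, leverages, ss = NULL, xiObs = NULL,
                     lambda = NA_real_) {
    if (length(residualsEst) != length(leverages))
        stop("residuals and leverages must have equal length")
    sat <- which(leverages >= 1 - 1e-10)
    if (length(sat))
        stop("conflict-of-interest factor saturated (h_jj >= 1 - 1e-10) ",
             "for observation(s): ", paste(sat, collapse = ", "))
    if (is.null(ss)) {
        if (is.null(xiObs)) stop("supply ss or xiObs")
        ss <- sum((xiObs - mean(xiObs))^2)
    }
    e <- residualsEst / (1 - leverages)
    .newPredictability("HAT", length(e), sum(e^2), ss, e, lambda)
}

#' K-fold PRESS by blockwise leverage correction
#'
#' Per fold k, the predicted residuals are e_k = (I - H_kk)^-1 e_hat_k
#' with H_kk the diagonal block of the hat matrix for that fold. For the
#' random model PRESS = sum_k e_k'e_k; for the fixed weighted model
#' PRESS = sum_k e_k' W_k e_k with H_kk = X_k (X'WX)^-1 X_k' W_k. With
#' K = n this reduces exactly to [pressLoo()]. At a fixed lambda and
#' whole-sample beta_hat these corrected residuals are algebraically
#' identical to refitting the BLUP with the fold deleted.
#'
#' @param residualsEst estimated residuals from the whole-sample fit
#' @param hat a [HatRandom-class], or a full n x n hat matrix (e.g. from
#'   [hatFixed()] or [hatMixed()])
#' @param folds a [FoldAssignment-class] (see [makeFolds()])
#' @param W optional n x n weight matrix (fixed weighted model); PRESS
#'   then accumulates e_k' W_k e_k
#' @inheritParams pressLoo
#' @return a [PredictabilityResult-class] with method "HAT"
#' @export
pressKfold <- function(residualsEst, hat, folds, W = NULL, ss = NULL,
                       xiObs = NULL, lambda = NA_real_) {
    n <- length(residualsEst)
    if (folds@n != n) stop("fold assignment does not match data size")
    if (is.null(ss)) {
        if (is.null(xiObs)) stop("supply ss or xiObs")
        ss <- sum((xiObs - mean(xiObs))^2)
    }
    if (is(hat, "HatRandom")) {
        if (is.na(lambda)) lambda <- hat@lambda
        getBlock <- function(idx) hatBlock(hat, idx)
    } else {
        hat <- as.matrix(hat)
        getBlock <- function(idx) hat[idx, idx, drop = FALSE]
    }
    e <- numeric(n)
    pressTot <- 0
    for (k in seq_len(folds@K)) {
        idx <- which(folds@assignment == k)
        Hkk <- getBlock(idx)
        ek <- tryCatch(
            solve(diag(length(idx)) - Hkk, residualsEst[idx]),
            error = function(err)
                stop("(I - H_kk) singular in fold ", k))
        e[idx] <- ek
        pressTot <- pressTot + if (is.null(W)) sum(ek^2) else
            drop(crossprod(ek, W[idx, idx, drop = FALSE] %*% ek))
    }
    .newPredictability("HAT", folds@K, pressTot, ss, e, lambda)
}

#' Generalized cross-validation: GRESS and its predictability
#'
#' GRESS divides every estimated residual by the average retained fraction
#' (1 - hbar), hbar = mean of the leverages: GRESS =
#' sum e_hat_j^2 / (1 - hbar)^2, a rotation-invariant analogue of the
#' leave-one-out PRESS. When all leverages are equal (A proportional to
#' I), GRESS equals the leave-one-out PRESS exactly.
#'
#' @inheritParams pressLoo
#' @param hat a [HatRandom-class]; alternatively supply `leverages`
#' @param leverages leverages to average when `hat` is absent
#' @return a [PredictabilityResult-class] with method "GCV" (no
#'   per-observation residuals: GRESS is a pooled correction)
#' @export
gcvGress <- function(residualsEst, hat = NULL, leverages = NULL, ss = NULL,
                     xiObs = NULL, lambda = NA_real_) {
    if (is.null(leverages)) {
        if (is.null(hat)) stop("supply hat or leverages")
        leverages <- hatDiag(hat)
        if (is.na(lambda)) lambda <- hat@lambda
    }
    hbar <- mean(leverages)
    if (hbar >= 1 - 1e-10)
        stop("mean leverage saturated (hbar >= 1 - 1e-10)")
    if (is.null(ss)) {
        if (is.null(xiObs)) stop("supply ss or xiObs")
        ss <- sum((xiObs - mean(xiObs))^2)
    }
    gress <- sum(residualsEst^2) / (1 - hbar)^2
    .newPredictability("GCV", NA_integer_, gress, ss, numeric(), lambda)
}

# Predictability profile in lambda for a fixed dataset: phenotypes are
# re-centered by the GLS beta_hat at each candidate lambda.
.r2Profile <- function(lambda, y, X, eig, objective) {
    bb <- blueBlup(y, X, eig, lambda)
    xiObs <- drop(y - as.matrix(X) %*% bb$beta)
    ehat <- xiObs - bb$xiHat
    ss <- sum((xiObs - mean(xiObs))^2)
    hr <- hatRandom(eig, lambda)
    h <- hatDiag(hr)
    if (objective == "HAT_LOO") {
        if (any(h >= 1 - 1e-10)) return(-Inf)
        1 - sum((ehat / (1 - h))^2) / ss
    } else {
        hbar <- mean(h)
        if (hbar >= 1 - 1e-10) return(-Inf)
        1 - sum(ehat^2) / (1 - hbar)^2 / ss
    }
}

#' Tune the variance ratio for maximum predictability
#'
#' Treats lambda as a free tuning parameter and maximizes the
#' leave-one-out HAT predictability (or the GCV predictability) over a
#' log-scale bracket around the REML estimate: a coarse log-grid scan
#' followed by Brent refinement around the best grid point. The maximizer
#' is the maximum predictability estimate (MPE) of lambda. The REML
#' estimate itself is always included as a candidate, so the returned
#' maximum never falls below the predictability at the REML lambda.
#'
#' @inheritParams remlFit
#' @param fit optional [MixedModelFit-class] from [remlFit()]; fitted
#'   here when absent
#' @param objective "HAT_LOO" (default) or "GCV"
#' @param span half-width of the search bracket in log10 units around the
#'   REML lambda
#' @param gridPoints number of coarse grid points
#' @return list with `lambdaMPE`, `r2Max`, `r2AtREML`, `lambdaREML`, and
#'   `profile` (data frame of evaluated lambda, r2 pairs)
#' @export
tuneLambda <- function(y, X = NULL, eig, fit = NULL,
                       objective = c("HAT_LOO", "GCV"), span = 3,
                       gridPoints = 201L) {
    objective <- match.arg(objective)
    y <- as.numeric(y)
    if (is.null(X)) X <- matrix(1, length(y), 1)
    if (is.null(fit)) fit <- remlFit(y, X, eig)
    lam0 <- varianceRatio(fit)
    if (!is.finite(lam0))
        stop("REML lambda unavailable (unidentifiable fit); cannot seed bracket")
    grid <- 10^seq(log10(lam0) - span, log10(lam0) + span,
                   length.out = gridPoints)
    grid <- sort(unique(c(grid, lam0)))
    r2g <- vapply(grid, function(l)
        .r2Profile(l, y, X, eig, objective), numeric(1))
    if (any(!is.finite(r2g) & r2g > -Inf))
        stop("non-finite predictability on the tuning grid")
    j <- which.max(r2g)
    lo <- log(grid[max(1L, j - 1L)])
    hi <- log(grid[min(length(grid), j + 1L)])
    opt <- stats::optimize(function(l)
        .r2Profile(exp(l), y, X, eig, objective),
        interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
    cand <- rbind(c(exp(opt$maximum), opt$objective),
                  c(grid[j], r2g[j]))
    best <- cand[which.max(cand[, 2L]), ]
    r2AtREML <- r2g[match(lam0, grid)]
    list(lambdaMPE = best[1L], r2Max = best[2L],
         r2AtREML = r2AtREML, lambdaREML = lam0,
         profile = data.frame(lambda = grid, r2 = r2g))
}
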