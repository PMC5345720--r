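# Profiled restricted likelihood in the rotated basis.
# With V = sigmaXi2 (D + lambda I), rotating (y, X) by U' diagonalizes V;
# beta and sigmaXi2 profile out, leaving a 1-D criterion in lambda.
.remlProfile <- function(lambda, ys, Xs, d) {
    n <- length(ys); p <- ncol(Xs)
    w <- d + lambda
    Xw <- Xs / w
    XtWiX <- crossprod(Xs, Xw)
    XtWiy <- crossprod(Xw, ys)
    ch <- tryCatch(chol(XtWiX), error = function(e) NULL)
    if (is.null(ch)) return(list(loglik = -Inf))
    beta <- backsolve(ch, forwardsolve(t(ch), XtWiy))
    r <- ys - Xs %*% beta
    q <- sum(r^2 / w)
    s2xi <- q / (n - p)
    ll <- -0.5 * ((n - p) * log(s2xi) + sum(log(w)) +
                  2 * sum(log(diag(ch))) + (n - p))
    list(loglik = ll, beta = drop(beta), sigmaXi2 = s2xi)
}

#' Fit the single-kinship mixed model by REML (eigen-rotation)
#'
#' Fits y = X beta + xi + e with xi ~ N(0, A sigmaXi2), e ~ N(0, I sigma2)
#' by restricted maximum likelihood. Rotating the data by the transposed
#' eigenvectors of A turns the covariance V = A sigmaXi2 + I sigma2 into
#' the diagonal sigmaXi2 (D + lambda I); beta and sigmaXi2 are profiled
#' out analytically and the remaining one-dimensional restricted
#' likelihood in lambda = sigma2/sigmaXi2 is maximized by Brent search on
#' the log scale over `bracket`. One n x n eigendecomposition therefore
#' pays for any number of traits and any number of lambda evaluations.
#'
#' @param y numeric phenotype vector of length n
#' @param X fixed-effect design matrix (default: intercept only); must be
#'   full column rank with p < n
#' @param eig a [KinshipEigen-class] with the eigen pair filled
#'   (see [eigenKinship()])
#' @param lambdaFixed optional variance ratio; when given the optimization
#'   is skipped and the model is profiled at that lambda
#' @param bracket search interval for lambda (log-scale Brent)
#' @param tol convergence tolerance on log(lambda)
#' @return a [MixedModelFit-class]
#' @details When the restricted likelihood is flat in lambda (e.g. A = I,
#'   where only sigmaXi2 + sigma2 is identifiable) the fit is returned
#'   with `identifiable = FALSE`, lambda and the variance split set to NA,
#'   and a warning, rather than an arbitrary argmax. An optimum at a
#'   bracket edge is flagged `boundary = TRUE` (upper edge: sigmaXi2 -> 0;
#'   lower edge: sigma2 -> 0).
#' @examples
#' set.seed(1)
#' G <- simulateGenotypes(n = 60, m = 120, seed = 1)
#' K <- eigenKinship(computeKinship(G))
#' sim <- simulateTrait(K, h2 = 0.5, seed = 2)
#' fit <- remlFit(sim$y, eig = K)
#' heritability(fit)
#' @export
remlFit <- function(y, X = NULL, eig, lambdaFixed = NULL,
                    bracket = c(1e-6, 1e6), tol = 1e-8) {
    y <- as.numeric(y)
    n <- length(y)
    if (any(!is.finite(y))) stop("phenotypes must be finite")
    if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
    X <- as.matrix(X)
    p <- ncol(X)
    if (nrow(X) != n) stop("nrow(X) must equal length(y)")
    if (p >= n) stop("need p < n fixed effects")
    if (qr(X)$rank < p) stop("fixed-effect design X is rank deficient")
    U <- eigenVectors(eig)
    d <- eigenValues(eig)
    if (length(d) != n) stop("kinship dimension does not match phenotypes")

    ys <- drop(crossprod(U, y))
    Xs <- crossprod(U, X)

    boundary <- FALSE
    identifiable <- TRUE
    if (is.null(lambdaFixed)) {
        lb <- log(bracket)
        # flatness scan: A = I (all eigenvalues equal) leaves only the
        # total variance identifiable and the profile constant in lambda
        grid <- seq(lb[1L], lb[2L], length.out = 9L)
        gll <- vapply(grid, function(l)
            .remlProfile(exp(l), ys, Xs, d)$loglik, numeric(1))
        if (all(is.finite(gll)) &&
            diff(range(gll)) < 1e-8 * max(1, abs(mean(gll)))) {
            warning("restricted likelihood is flat in lambda; ",
                    "variance ratio not identifiable (is A proportional to I?)")
            pr <- .remlProfile(1, ys, Xs, d)
            xiObs <- y - X %*% pr$beta
            return(new("MixedModelFit", beta = pr$beta,
                       sigmaXi2 = NA_real_, sigma2 = NA_real_,
                       lambda = NA_real_, h2 = NA_real_,
                       xiHat = rep(NA_real_, n), xiObs = drop(xiObs),
                       fitR2Corr = NA_real_, fitR2Eress = NA_real_,
                       loglik = pr$loglik, boundary = FALSE,
                       identifiable = FALSE, n = n, p = p))
        }
        opt <- stats::optimize(function(l) .remlProfile(exp(l), ys, Xs, d)$loglik,
                               interval = lb, maximum = TRUE, tol = tol)
        # a grid point can beat Brent if the profile is multimodal
        if (max(gll) > opt$objective) {
            j <- which.max(gll)
            opt <- stats::optimize(function(l)
                .remlProfile(exp(l), ys, Xs, d)$loglik,
                interval = c(grid[max(1L, j - 1L)],
                             grid[min(length(grid), j + 1L)]),
                maximum = TRUE, tol = tol)
        }
        loglam <- opt$maximum
        if (min(abs(loglam - lb)) < 1e-3) boundary <- TRUE
        lambda <- exp(loglam)
    } else {
        if (!is.numeric(lambdaFixed) || lambdaFixed <= 0)
            stop("lambdaFixed must be a positive scalar")
        lambda <- lambdaFixed
    }

    pr <- .remlProfile(lambda, ys, Xs, d)
    if (!is.finite(pr$loglik))
        stop("REML profile evaluation failed at lambda = ", format(lambda))
    beta <- pr$beta
    names(beta) <- colnames(X)
    sigmaXi2 <- pr$sigmaXi2
    sigma2 <- lambda * sigmaXi2
    h2 <- 1 / (1 + lambda)

    xiObs <- drop(y - X %*% beta)
    shrink <- d / (d + lambda)
    xiHat <- drop(U %*% (shrink * crossprod(U, xiObs)))
    eress <- sum((xiObs - xiHat)^2)
    ss <- sum((xiObs - mean(xiObs))^2)
    fitCorr <- if (stats::sd(xiHat) > 0)
        stats::cor(xiObs, xiHat)^2 else 0
    new("MixedModelFit", beta = beta, sigmaXi2 = sigmaXi2, sigma2 = sigma2,
        lambda = lambda, h2 = h2, xiHat = xiHat, xiObs = xiObs,
        fitR2Corr = fitCorr, fitR2Eress = 1 - eress / ss,
        loglik = pr$loglik, boundary = boundary, identifiable = identifiable,
        n = n, p = p)
}

#' BLUE and BLUP at a given variance ratio
#'
#' Computes the best linear unbiased estimates of the fixed effects,
#' beta = (X'V^-1X)^-1 X'V^-1 y, and the best linear unbiased predictions
#' of the polygenic effects, xi_hat = sigmaXi2 A V^-1 (y - X beta), with
#' the variance components held fixed. All algebra runs in the rotated
#' basis, so no n x n inverse is formed. Note xi_hat depends on the
#' variance components only through lambda = sigma2/sigmaXi2.
#'
#' @inheritParams remlFit
#' @param lambda variance ratio sigma2/sigmaXi2 (> 0)
#' @return list with components `beta` and `xiHat`
#' @export
blueBlup <- function(y, X = NULL, eig, lambda) {
    y <- as.numeric(y)
    n <- length(y)
    if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
    X <- as.matrix(X)
    if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
        stop("lambda must be a positive scalar")
    U <- eigenVectors(eig)
    d <- eigenValues(eig)
    pr <- .remlProfile(lambda, drop(crossprod(U, y)), crossprod(U, X), d)
    if (!is.finite(pr$loglik)) stop("singular X'V^-1X")
    beta <- pr$beta
    names(beta) <- colnames(X)
    xiObs <- drop(y - X %*% beta)
    shrink <- d / (d + lambda)
    xiHat <- drop(U %*% (shrink * crossprod(U, xiObs)))
    list(beta = beta, xiHat = xiHat)
}

#' Broad-sense heritability from balanced replicated trials
#'
#' One-way-per-factor ANOVA of a complete genotype x environment layout
#' with a single observation per cell: y_ij = mu + g_i + r_j + e_ij. The
#' expected mean squares give sigmaE2 = MS_E and
#' sigmaG2 = (MS_G - MS_E) / r for r environments, and the trait
#' heritability H2 = sigmaG2 / (sigmaG2 + sigmaE2). When MS_G < MS_E the
#' genotypic variance is clamped at zero (H2 = 0).
#'
#' @param pheno data frame with columns `genotype`, `env`, `value`: one
#'   phenotype per genotype-environment combination
#' @return named numeric vector (sigmaG2, sigmaE2, H2, MSG, MSE, r)
#' @examples
#' ph <- data.frame(genotype = rep(c("g1", "g2"), each = 2),
#'                  env = rep(c("e1", "e2"), 2), value = c(1, 3, 5, 7))
#' anovaHeritability(ph)  # sigmaG2 = 8, H2 = 1
#' @export
anovaHeritability <- function(pheno) {
    need <- c("genotype", "env", "value")
    if (!all(need %in% names(pheno)))
        stop("pheno must have columns genotype, env, value")
    pheno$genotype <- factor(pheno$genotype)
    pheno$env <- factor(pheno$env)
    r <- nlevels(pheno$env)
    if (r < 2L) stop("need at least 2 environments")
    tab <- table(pheno$genotype, pheno$env)
    if (any(tab != 1L))
        stop("unbalanced layout: need exactly one value per genotype x env")
    fit <- stats::aov(value ~ genotype + env, data = pheno)
    ms <- summary(fit)[[1L]][["Mean Sq"]]
    names(ms) <- trimws(rownames(summary(fit)[[1L]]))
    msg <- ms[["genotype"]]
    mse <- ms[["Residuals"]]
    sigmaG2 <- max(0, (msg - mse) / r)
    H2 <- if (sigmaG2 + mse > 0) sigmaG2 / (sigmaG2 + mse) else 0
    c(sigmaG2 = sigmaG2, sigmaE2 = mse, H2 = H2, MSG = msg, MSE = mse, r = r)
}
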