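#' Simulate biallelic marker genotypes
#'
#' Draws, per marker, an allele frequency uniformly from `maf` and then
#' two independent alleles per individual (Hardy-Weinberg), mapping the
#' allele count \{0, 1, 2\} to codes \{-1, 0, +1\}. Fully deterministic
#' under `seed`.
#'
#' @param n number of individuals (>= 2)
#' @param m number of markers
#' @param maf allele-frequency range, a sub-interval of (0, 0.5]; a single
#'   value fixes the frequency for every marker
#' @param seed integer seed
#' @return a [GenotypeMatrix-class]
#' @export
simulateGenotypes <- function(n, m, maf = c(0.05, 0.5), seed = 1L) {
    if (length(maf) == 1L) maf <- c(maf, maf)
    if (maf[1L] <= 0 || maf[2L] > 0.5 || maf[1L] > maf[2L])
        stop("maf must be a sub-interval of (0, 0.5]")
    if (n < 2L || m < 1L) stop("need n >= 2 and m >= 1")
    codes <- .withSeed(seed, {
        p <- stats::runif(m, maf[1L], maf[2L])
        matrix(stats::rbinom(n * m, 2L, rep(p, each = n)) - 1,
               nrow = n, ncol = m)
    })
    dimnames(codes) <- list(paste0("ind", seq_len(n)),
                            paste0("m", seq_len(m)))
    new("GenotypeMatrix", codes)
}

#' Simulate a polygenic trait with target heritability
#'
#' Generates y = X beta + xi + e under the GBLUP model: xi ~ N(0, A
#' sigmaXi2) drawn through the eigen factorization U sqrt(D) z, and
#' e ~ N(0, I sigma2), with sigmaXi2 = h2 and sigma2 = 1 - h2 so the
#' expected heritability is `h2` on unit total variance. The true xi and
#' beta are returned for parameter-recovery checks. With `nEnv` > 1,
#' environment replicates share xi and redraw e, producing the balanced
#' genotype x environment layout consumed by [anovaHeritability()].
#'
#' In `mode = "marker"` xi is instead built from marker effects
#' b ~ N(0, (sigmaXi2 / a) I) as xi = Z b, whose covariance is exactly
#' A sigmaXi2 under the kinship normalization; this exercises the full
#' genotype-to-kinship pipeline rather than the model covariance alone.
#'
#' @param x a [KinshipEigen-class] (eigendecomposed) or, for
#'   `mode = "marker"`, a [GenotypeMatrix-class]
#' @param h2 target heritability in [0, 1]
#' @param X fixed-effect design (default intercept); `beta` must conform
#' @param beta fixed-effect values (default 0 for each column of X)
#' @param nEnv number of replicated environments (1 = single trial)
#' @param seed integer seed
#' @param mode "kinship" (default) draws xi from N(0, A sigmaXi2);
#'   "marker" sums marker effects
#' @return list with `y` (vector, or n x nEnv matrix when nEnv > 1, whose
#'   rowMeans give the line means), `xiTrue`, `beta`, `sigmaXi2`,
#'   `sigma2`, `ids`, and `pheno` (long genotype/env/value data frame
#'   when nEnv > 1)
#' @export
simulateTrait <- function(x, h2, X = NULL, beta = NULL, nEnv = 1L,
                          seed = 1L, mode = c("kinship", "marker")) {
    mode <- match.arg(mode)
    if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
    sigmaXi2 <- h2
    sigma2 <- 1 - h2
    if (mode == "kinship") {
        if (!is(x, "KinshipEigen"))
            stop("mode = 'kinship' needs a KinshipEigen object")
        U <- eigenVectors(x)
        d <- eigenValues(x)
        n <- nrow(U)
        ids <- individualIds(x)
        draw <- function() drop(U %*% (sqrt(d * sigmaXi2) * stats::rnorm(n)))
    } else {
        if (!is(x, "GenotypeMatrix"))
            stop("mode = 'marker' needs a GenotypeMatrix object")
        Z <- x@.Data
        n <- nrow(Z)
        ids <- rownames(Z)
        a <- sum(Z^2) / n      # kinship normalization factor
        if (a <= 0) stop("degenerate genotype matrix")
        draw <- function()
            drop(Z %*% stats::rnorm(ncol(Z), sd = sqrt(sigmaXi2 / a)))
    }
    if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
    X <- as.matrix(X)
    if (is.null(beta)) beta <- rep(0, ncol(X))
    mu <- drop(X %*% beta)

    out <- .withSeed(seed, {
        xi <- draw()
        ys <- vapply(seq_len(nEnv), function(r)
            mu + xi + stats::rnorm(n, sd = sqrt(sigma2)), numeric(n))
        list(xi = xi, ys = ys)
    })
    y <- if (nEnv == 1L) drop(out$ys) else out$ys
    pheno <- NULL
    if (nEnv > 1L) {
        rownames(y) <- ids
        colnames(y) <- paste0("env", seq_len(nEnv))
        pheno <- data.frame(genotype = rep(ids, nEnv),
                            env = rep(colnames(y), each = n),
                            value = as.vector(y))
    } else {
        names(y) <- ids
    }
    list(y = y, xiTrue = out$xi, beta = beta, sigmaXi2 = sigmaXi2,
         sigma2 = sigma2, ids = ids, pheno = pheno)
}
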