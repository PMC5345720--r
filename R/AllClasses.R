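#' @import methods
NULL

#' GenotypeMatrix: coded biallelic marker genotypes
#'
#' An n x m numeric matrix of marker codes with individuals in rows and
#' markers in columns. Codes follow the -1/0/+1 convention: the two
#' homozygotes map to -1 (A1A1) and +1 (A2A2) and the heterozygote to 0.
#' Imputed cells may hold the per-marker mean of observed codes, hence any
#' value in [-1, 1]. Row names are individual ids, column names marker ids.
#'
#' @slot .Data numeric matrix of codes in [-1, 1]
#' @seealso [codeGenotypes()], [computeKinship()], [simulateGenotypes()]
#' @export
setClass("GenotypeMatrix", contains = "matrix")

setValidity("GenotypeMatrix", function(object) {
    msg <- character()
    codes <- object@.Data
    if (!is.numeric(codes))
        msg <- c(msg, "codes must be numeric")
    if (nrow(codes) < 2L)
        msg <- c(msg, "need at least 2 individuals")
    if (ncol(codes) < 1L)
        msg <- c(msg, "need at least 1 marker")
    if (is.null(rownames(codes)) || is.null(colnames(codes)))
        msg <- c(msg, "individual and marker ids (dimnames) are required")
    if (!is.null(rownames(codes)) && anyDuplicated(rownames(codes)))
        msg <- c(msg, "duplicate individual ids")
    if (anyNA(codes) || any(!is.finite(codes)))
        msg <- c(msg, "codes must be finite (impute missing values first)")
    else if (any(codes < -1 - 1e-9) || any(codes > 1 + 1e-9))
        msg <- c(msg, "codes must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
})

#' KinshipEigen: marker-inferred kinship and its eigendecomposition
#'
#' Holds the normalized kinship matrix A = (1/a) sum_k Z_k Z_k', the
#' normalization scalar a = n^-1 tr(sum_k Z_k Z_k') (which forces
#' trace(A) = n), and, once [eigenKinship()] has been applied, the
#' orthonormal eigenvectors U and nonnegative eigenvalues D (descending)
#' with A = U D U'. The eigen pair is what makes single-pass REML and the
#' random-effect hat matrix cheap: the model covariance becomes diagonal
#' after rotation by U'.
#'
#' @slot A n x n symmetric positive semidefinite kinship matrix
#' @slot a normalization scalar
#' @slot U n x n orthonormal eigenvector matrix (0 x 0 until decomposed)
#' @slot values n eigenvalues, descending, negatives clipped to 0
#' @slot ids individual ids, in the row order of A
#' @export
setClass("KinshipEigen",
    representation(A = "matrix", a = "numeric", U = "matrix",
                   values = "numeric", ids = "character"))

setValidity("KinshipEigen", function(object) {
    msg <- character()
    n <- nrow(object@A)
    if (n == 0L) msg <- c(msg, "empty kinship matrix")
    if (ncol(object@A) != n) msg <- c(msg, "A must be square")
    if (length(object@ids) != n) msg <- c(msg, "ids length must equal nrow(A)")
    if (max(abs(object@A - t(object@A))) > 1e-6 * max(1, max(abs(object@A))))
        msg <- c(msg, "A must be symmetric")
    if (length(object@values)) {
        if (length(object@values) != n || nrow(object@U) != n)
            msg <- c(msg, "eigen pair dimensions must match A")
        if (any(object@values < 0))
            msg <- c(msg, "eigenvalues must be nonnegative (clipped)")
        if (is.unsorted(rev(object@values)))
            msg <- c(msg, "eigenvalues must be in descending order")
    }
    if (length(msg)) msg else TRUE
})

#' MixedModelFit: REML estimates for the single-kinship mixed model
#'
#' Result of fitting y = X beta + xi + e with xi ~ N(0, A sigma_xi^2) and
#' e ~ N(0, I sigma^2) by restricted maximum likelihood in the rotated
#' (eigen) basis. Carries the BLUE of the fixed effects, variance
#' components, variance ratio lambda = sigma^2/sigma_xi^2, genomic
#' heritability, the BLUP xi_hat, the centered ("observed") polygenic
#' values xi = y - X beta_hat, and two goodness-of-fit statistics.
#'
#' @slot beta fixed-effect estimates (BLUE)
#' @slot sigmaXi2 polygenic variance estimate, >= 0
#' @slot sigma2 residual variance estimate
#' @slot lambda variance ratio sigma2/sigmaXi2 (Inf when sigmaXi2 = 0,
#'   NA when unidentifiable)
#' @slot h2 genomic heritability sigmaXi2/(sigmaXi2+sigma2)
#' @slot xiHat BLUP of the polygenic effects
#' @slot xiObs centered phenotypes y - X beta_hat
#' @slot fitR2Corr model fit as squared correlation of (xiObs, xiHat)
#' @slot fitR2Eress model fit as 1 - ERESS/SS
#' @slot loglik restricted log-likelihood at the optimum (constant omitted)
#' @slot boundary TRUE when the lambda optimum hit the search bracket edge
#' @slot identifiable FALSE when the profile is flat in lambda (e.g. A = I)
#' @slot n,p sample size and number of fixed effects
#' @export
setClass("MixedModelFit",
    representation(beta = "numeric", sigmaXi2 = "numeric", sigma2 = "numeric",
                   lambda = "numeric", h2 = "numeric",
                   xiHat = "numeric", xiObs = "numeric",
                   fitR2Corr = "numeric", fitR2Eress = "numeric",
                   loglik = "numeric", boundary = "logical",
                   identifiable = "logical", n = "integer", p = "integer"))

setValidity("MixedModelFit", function(object) {
    msg <- character()
    if (length(object@xiHat) != object@n || length(object@xiObs) != object@n)
        msg <- c(msg, "xiHat/xiObs must have length n")
    if (!is.na(object@h2) && (object@h2 < -1e-12 || object@h2 > 1 + 1e-12))
        msg <- c(msg, "h2 must lie in [0, 1]")
    if (!is.na(object@sigmaXi2) && object@sigmaXi2 < 0)
        msg <- c(msg, "sigmaXi2 must be >= 0")
    if (length(msg)) msg else TRUE
})

#' HatRandom: the random-effect hat matrix in factored form
#'
#' Represents H_R = U diag(delta_j/(delta_j+lambda)) U', the linear map
#' from centered phenotypes to BLUPs, without materializing the n x n
#' matrix. The shrinkage factors delta_j/(delta_j+lambda) all lie in
#' [0, 1), so the leverages (diagonal entries) lie in [0, 1]. Use
#' [hatDiag()] for the leverages, [hatBlock()] for a diagonal block, and
#' [hatFull()] to materialize the matrix when n is small.
#'
#' @slot lambda variance ratio sigma2/sigmaXi2
#' @slot shrink n shrinkage factors delta_j/(delta_j+lambda)
#' @slot U eigenvectors of the kinship matrix
#' @export
setClass("HatRandom",
    representation(lambda = "numeric", shrink = "numeric", U = "matrix"))

setValidity("HatRandom", function(object) {
    msg <- character()
    if (length(object@shrink) != nrow(object@U))
        msg <- c(msg, "shrink length must match nrow(U)")
    if (any(object@shrink < 0 | object@shrink >= 1))
        msg <- c(msg, "shrinkage factors must lie in [0, 1)")
    if (object@lambda <= 0) msg <- c(msg, "lambda must be > 0")
    if (length(msg)) msg else TRUE
})

#' FoldAssignment: a seed-reproducible K-way partition
#'
#' Partition of individuals 1..n into K disjoint folds whose sizes differ
#' by at most one. The same (n, K, seed) always yields the same partition.
#'
#' @slot n number of individuals
#' @slot K number of folds
#' @slot assignment integer fold label in 1..K per individual
#' @slot seed the seed that generated the partition (NA if supplied by hand)
#' @export
setClass("FoldAssignment",
    representation(n = "integer", K = "integer", assignment = "integer",
                   seed = "integer"))

setValidity("FoldAssignment", function(object) {
    msg <- character()
    if (length(object@assignment) != object@n)
        msg <- c(msg, "assignment length must equal n")
    if (object@K < 2L || object@K > object@n)
        msg <- c(msg, "K must satisfy 2 <= K <= n")
    tab <- tabulate(object@assignment, nbins = object@K)
    if (any(tab == 0L))
        msg <- c(msg, "every fold must be non-empty")
    if (length(tab) && diff(range(tab)) > 1L)
        msg <- c(msg, "fold sizes must differ by at most 1")
    if (any(object@assignment < 1L | object@assignment > object@K))
        msg <- c(msg, "fold labels must lie in 1..K")
    if (length(msg)) msg else TRUE
})

#' PredictabilityResult: PRESS (or GRESS) and predictability
#'
#' Output of the HAT, CV, GCV, or FIT computations: the predicted residual
#' error sum of squares, the total sum of squares of the centered
#' phenotypes, and the predictability R2 = 1 - PRESS/SS. R2 is reported
#' as-is and may be negative (the model predicts worse than the mean).
#'
#' @slot method one of "HAT", "CV", "GCV", "FIT"
#' @slot folds number of folds K (n for leave-one-out; NA for GCV/FIT)
#' @slot press PRESS, GRESS, or ERESS depending on method
#' @slot ss total sum of squares of centered phenotypes about their mean
#' @slot r2 1 - press/ss, never clamped
#' @slot residualsPred per-observation predicted residuals (length 0 for GCV)
#' @slot lambdaUsed the variance ratio at which residuals were computed
#' @slot repMean,repSE mean and standard error of R2 over replicated
#'   partitions (NA when a single partition was used)
#' @export
setClass("PredictabilityResult",
    representation(method = "character", folds = "integer",
                   press = "numeric", ss = "numeric", r2 = "numeric",
                   residualsPred = "numeric", lambdaUsed = "numeric",
                   repMean = "numeric", repSE = "numeric"))

setValidity("PredictabilityResult", function(object) {
    msg <- character()
    if (!object@method %in% c("HAT", "CV", "GCV", "FIT"))
        msg <- c(msg, "method must be one of HAT, CV, GCV, FIT")
    if (object@press < 0) msg <- c(msg, "press must be >= 0")
    if (object@ss < 0) msg <- c(msg, "ss must be >= 0")
    if (length(msg)) msg else TRUE
})
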