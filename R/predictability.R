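#' Predictability of genomic prediction for one or many traits
#'
#' Trait-major driver: joins phenotypes to the kinship by individual id,
#' pays the kinship eigendecomposition once, and for each trait fits the
#' mixed model by REML and evaluates model fit (FIT), leave-one-out or
#' K-fold HAT predictability, GCV predictability, optionally the true
#' cross-validation oracle, and optionally the lambda that maximizes
#' predictability (MPE). Traits with missing phenotypes are analyzed on
#' the complete-case subset, with the kinship sub-block eigendecomposed
#' for that trait only; the returned `eigenCount` attribute records how
#' many eigendecompositions the whole run performed (1 when no trait had
#' missing values).
#'
#' @param pheno data frame with an `id` column and one column per trait
#'   (see [readPhenotypes()])
#' @param kin a [KinshipEigen-class] (decomposed or not) or a
#'   [GenotypeMatrix-class] (kinship computed here)
#' @param traits trait column names (default: every non-id, non-covariate
#'   column)
#' @param covariates column names used as fixed-effect covariates (an
#'   intercept is always included)
#' @param method which predictability estimates to compute: any subset of
#'   c("hat", "gcv", "cv")
#' @param K folds ("loo" or an integer)
#' @param reps replicated random partitions for K < n (mean and SE
#'   reported); ignored for LOO
#' @param seed partition seed
#' @param tune also maximize the HAT predictability over lambda
#' @param center,standardize kinship construction flags when `kin` is a
#'   genotype matrix
#' @return data frame, one row per trait, with columns trait, n, lambda,
#'   h2, fitCorr, fitEress, r2Hat, seHat, r2Gcv, r2Cv, seCv, lambdaMPE,
#'   r2MPE (NA where not requested); attribute `eigenCount` counts the
#'   eigendecompositions paid
#' @export
genomicPredictability <- function(pheno, kin, traits = NULL,
                                  covariates = character(),
                                  method = c("hat", "gcv"),
                                  K = "loo", reps = 1L, seed = 1L,
                                  tune = FALSE, center = FALSE,
                                  standardize = FALSE) {
    method <- match.arg(method, c("hat", "gcv", "cv"), several.ok = TRUE)
    if (is(kin, "GenotypeMatrix"))
        kin <- computeKinship(kin, center = center, standardize = standardize)
    eigenCount <- 0L
    if (!length(kin@values)) {
        kin <- eigenKinship(kin)
        eigenCount <- eigenCount + 1L
    }
    ids <- individualIds(kin)
    if (!"id" %in% names(pheno)) stop("pheno must have an `id` column")
    unknown <- setdiff(pheno$id, ids)
    if (length(unknown))
        stop("phenotype ids absent from kinship: ",
             paste(utils::head(unknown, 5L), collapse = ", "))
    if (is.null(traits))
        traits <- setdiff(names(pheno), c("id", covariates))
    loo <- identical(K, "loo") || identical(K, "n")

    rows <- vector("list", length(traits))
    for (ti in seq_along(traits)) {
        tr <- traits[[ti]]
        sub <- pheno[!is.na(pheno[[tr]]), , drop = FALSE]
        # harmonize to kinship order by id join, never by row position
        keep <- which(ids %in% sub$id)
        sub <- sub[match(ids[keep], sub$id), , drop = FALSE]
        y <- as.numeric(sub[[tr]])
        n <- length(y)
        X <- cbind(intercept = rep(1, n))
        for (cv in covariates)
            X <- cbind(X, as.numeric(sub[[cv]]))
        colnames(X) <- c("intercept", covariates)
        if (n == length(ids)) {
            eigTr <- kin
        } else {
            eigTr <- eigenKinship(kin@A[keep, keep, drop = FALSE])
            eigenCount <- eigenCount + 1L
        }
        fit <- remlFit(y, X, eigTr)
        lam <- varianceRatio(fit)
        xiObs <- centeredPhenotypes(fit)
        ehat <- xiObs - blup(fit)
        kEff <- if (loo) n else as.integer(K)

        r2Hat <- seHat <- r2Gcv <- r2Cv <- seCv <- NA_real_
        lamMPE <- r2MPE <- NA_real_
        if ("hat" %in% method) {
            hr <- hatRandom(eigTr, lam)
            if (loo) {
                r2Hat <- predictability(
                    pressLoo(ehat, hatDiag(hr), xiObs = xiObs, lambda = lam))
            } else {
                rc <- replicateCV(y, X, eigTr, K = kEff, reps = reps,
                                  seed = seed, method = "HAT", fit = fit)
                r2Hat <- rc$mean; seHat <- rc$se
            }
        }
        if ("gcv" %in% method)
            r2Gcv <- predictability(
                gcvGress(ehat, hatRandom(eigTr, lam), xiObs = xiObs,
                         lambda = lam))
        if ("cv" %in% method) {
            if (loo) {
                r2Cv <- predictability(
                    kfoldCV(y, X, eigTr, makeFolds(n, n, seed = seed)))
            } else {
                rc <- replicateCV(y, X, eigTr, K = kEff, reps = reps,
                                  seed = seed, method = "CV")
                r2Cv <- rc$mean; seCv <- rc$se
            }
        }
        if (tune) {
            tn <- tuneLambda(y, X, eigTr, fit = fit)
            lamMPE <- tn$lambdaMPE; r2MPE <- tn$r2Max
        }
        fits <- modelFit(fit)
        rows[[ti]] <- data.frame(
            trait = tr, n = n, K = kEff, lambda = lam,
            h2 = heritability(fit),
            fitCorr = fits[["corr"]], fitEress = fits[["eress"]],
            r2Hat = r2Hat, seHat = seHat, r2Gcv = r2Gcv,
            r2Cv = r2Cv, seCv = seCv,
            lambdaMPE = lamMPE, r2MPE = r2MPE,
            stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    attr(out, "eigenCount") <- eigenCount
    out
}
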