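#' @rdname hatpress-accessors
#' @export
setMethod("individualIds", "GenotypeMatrix", function(x) rownames(x@.Data))

#' @rdname hatpress-accessors
#' @export
setMethod("markerIds", "GenotypeMatrix", function(x) colnames(x@.Data))

#' @rdname hatpress-accessors
#' @export
setMethod("individualIds", "KinshipEigen", function(x) x@ids)

#' @rdname hatpress-accessors
#' @export
setMethod("kinshipMatrix", "KinshipEigen", function(x) {
    A <- x@A
    dimnames(A) <- list(x@ids, x@ids)
    A
})

#' @rdname hatpress-accessors
#' @export
setMethod("normalizationFactor", "KinshipEigen", function(x) x@a)

#' @rdname hatpress-accessors
#' @export
setMethod("eigenVectors", "KinshipEigen", function(x) {
    if (!length(x@values))
        stop("kinship has not been eigendecomposed; call eigenKinship() first")
    x@U
})

#' @rdname hatpress-accessors
#' @export
setMethod("eigenValues", "KinshipEigen", function(x) {
    if (!length(x@values))
        stop("kinship has not been eigendecomposed; call eigenKinship() first")
    x@values
})

#' @rdname hatpress-accessors
#' @export
setMethod("fixedEffects", "MixedModelFit", function(x) x@beta)

#' @rdname hatpress-accessors
#' @export
setMethod("varianceComponents", "MixedModelFit", function(x)
    c(sigmaXi2 = x@sigmaXi2, sigma2 = x@sigma2))

#' @rdname hatpress-accessors
#' @export
setMethod("varianceRatio", "MixedModelFit", function(x) x@lambda)

#' @rdname hatpress-accessors
#' @export
setMethod("heritability", "MixedModelFit", function(x) x@h2)

#' @rdname hatpress-accessors
#' @export
setMethod("blup", "MixedModelFit", function(x) x@xiHat)

#' @rdname hatpress-accessors
#' @export
setMethod("centeredPhenotypes", "MixedModelFit", function(x) x@xiObs)

#' @rdname hatpress-accessors
#' @export
setMethod("modelFit", "MixedModelFit", function(x)
    c(corr = x@fitR2Corr, eress = x@fitR2Eress))

#' @rdname hatpress-accessors
#' @export
setMethod("foldIndices", "FoldAssignment", function(x)
    split(seq_len(x@n), x@assignment))

#' @rdname hatpress-accessors
#' @export
setMethod("press", "PredictabilityResult", function(x) x@press)

#' @rdname hatpress-accessors
#' @export
setMethod("totalSS", "PredictabilityResult", function(x) x@ss)

#' @rdname hatpress-accessors
#' @export
setMethod("predictability", "PredictabilityResult", function(x) x@r2)

#' @rdname hatpress-accessors
#' @export
setMethod("predictedResiduals", "PredictabilityResult", function(x)
    x@residualsPred)

setMethod("show", "GenotypeMatrix", function(object) {
    cat("GenotypeMatrix:", nrow(object@.Data), "individuals x",
        ncol(object@.Data), "markers\n")
    cat("  code range: [", format(min(object@.Data), digits = 3), ", ",
        format(max(object@.Data), digits = 3), "]\n", sep = "")
})

setMethod("show", "KinshipEigen", function(object) {
    n <- nrow(object@A)
    cat("KinshipEigen:", n, "individuals, trace(A) =",
        format(sum(diag(object@A)), digits = 6), "\n")
    if (length(object@values))
        cat("  eigendecomposed; leading eigenvalues:",
            paste(format(utils::head(object@values, 3), digits = 4),
                  collapse = ", "), "...\n")
    else
        cat("  eigendecomposition pending (eigenKinship)\n")
})

setMethod("show", "MixedModelFit", function(object) {
    cat("MixedModelFit (REML, eigen-rotated), n =", object@n,
        ", p =", object@p, "\n")
    cat(sprintf("  sigmaXi2 = %.6g  sigma2 = %.6g  lambda = %.6g  h2 = %.4f\n",
                object@sigmaXi2, object@sigma2, object@lambda, object@h2))
    cat(sprintf("  FIT: corr^2 = %.4f  1-ERESS/SS = %.4f\n",
                object@fitR2Corr, object@fitR2Eress))
    if (!object@identifiable)
        cat("  WARNING: lambda not identifiable (flat restricted likelihood)\n")
    if (object@boundary)
        cat("  NOTE: optimum at the lambda search boundary\n")
})

setMethod("show", "FoldAssignment", function(object) {
    cat("FoldAssignment: n =", object@n, ", K =", object@K,
        ", seed =", object@seed, "\n")
    cat("  fold sizes:", paste(tabulate(object@assignment, object@K),
                               collapse = " "), "\n")
})

setMethod("show", "PredictabilityResult", function(object) {
    lab <- switch(object@method, HAT = "PRESS", CV = "PRESS",
                  GCV = "GRESS", FIT = "ERESS")
    cat("PredictabilityResult [", object@method, "]", sep = "")
    if (!is.na(object@folds)) cat(", K =", object@folds)
    cat("\n")
    cat(sprintf("  %s = %.6g  SS = %.6g  R2 = %.4f  (lambda = %.6g)\n",
                lab, object@press, object@ss, object@r2, object@lambdaUsed))
    if (!is.na(object@repSE))
        cat(sprintf("  over replicates: mean R2 = %.4f +/- %.4f (SE)\n",
                    object@repMean, object@repSE))
})
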