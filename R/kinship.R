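#' Code biallelic genotype calls as a -1/0/+1 matrix
#'
#' Maps biallelic genotype labels or allele dosages to the numeric codes
#' used throughout the package: homozygote A1A1 -> -1, heterozygote
#' A1A2 -> 0, homozygote A2A2 -> +1. Dosages d in \{0, 1, 2\} map to d - 1.
#' Missing calls are imputed per marker.
#'
#' @param calls an n x m matrix (individuals x markers) of either character
#'   labels ("A1A1"/"A1A2"/"A2A2", or any "XX"/"XY"/"YY" two-letter form
#'   where the alphabetically first allele plays the role of A1) or numeric
#'   dosages in \{0, 1, 2\} (NA = missing). Row and column names are used as
#'   individual and marker ids; defaults are generated when absent.
#' @param missing how to fill missing calls: "mean" (default) substitutes
#'   the per-marker mean of observed codes; "zero" substitutes 0 (the
#'   heterozygote code); "fail" raises an error on any missing call.
#' @return a [GenotypeMatrix-class]
#' @details A marker with all calls missing, or with more than two observed
#'   alleles, is a hard error naming the marker. Monomorphic markers are
#'   retained; under raw (uncentered) coding they still contribute to the
#'   kinship cross-product.
#' @examples
#' calls <- rbind(id1 = c(m1 = 0), id2 = c(m1 = 2), id3 = c(m1 = 1))
#' codeGenotypes(calls)
#' @export
codeGenotypes <- function(calls, missing = c("mean", "zero", "fail")) {
    missing <- match.arg(missing)
    if (!is.matrix(calls))
        calls <- as.matrix(calls)
    if (nrow(calls) < 2L)
        stop("at least two individuals are required")
    if (is.null(rownames(calls)))
        rownames(calls) <- paste0("ind", seq_len(nrow(calls)))
    if (is.null(colnames(calls)))
        colnames(calls) <- paste0("m", seq_len(ncol(calls)))

    if (is.character(calls)) {
        codes <- matrix(NA_real_, nrow(calls), ncol(calls),
                        dimnames = dimnames(calls))
        for (k in seq_len(ncol(calls))) {
            g <- calls[, k]
            g[g %in% c("", ".", "./.", "NA", "--")] <- NA
            obs <- g[!is.na(g)]
            if (!length(obs))
                stop("marker '", colnames(calls)[k], "': all calls missing")
            al <- sort(unique(unlist(strsplit(obs, ""))))
            if (length(al) > 2L)
                stop("marker '", colnames(calls)[k],
                     "' is not biallelic (alleles: ",
                     paste(al, collapse = ","), ")")
            # dosage of the alphabetically second allele; for a monomorphic
            # marker every observed call is the A1 homozygote (code -1)
            a2 <- if (length(al) == 2L) al[2L] else NA_character_
            d <- vapply(g, function(gt) {
                if (is.na(gt)) return(NA_real_)
                if (nchar(gt) != 2L)
                    stop("marker '", colnames(calls)[k],
                         "': malformed genotype '", gt, "'")
                if (is.na(a2)) 0 else
                    sum(strsplit(gt, "")[[1L]] == a2)
            }, numeric(1))
            codes[, k] <- d - 1
        }
    } else {
        storage.mode(calls) <- "double"
        bad <- !is.na(calls) & !(calls %in% c(0, 1, 2) |
                                 (calls >= -1 & calls <= 1))
        if (any(bad))
            stop("numeric calls must be dosages in {0,1,2} or codes in [-1,1]")
        # auto-detect: any value > 1 means dosage scale
        codes <- if (any(calls > 1, na.rm = TRUE) ||
                     all(calls >= 0, na.rm = TRUE)) calls - 1 else calls
    }

    for (k in seq_len(ncol(codes))) {
        miss <- is.na(codes[, k])
        if (all(miss))
            stop("marker '", colnames(codes)[k], "': all calls missing")
        if (any(miss)) {
            if (missing == "fail")
                stop("marker '", colnames(codes)[k], "' has missing calls")
            fill <- if (missing == "mean") mean(codes[!miss, k]) else 0
            codes[miss, k] <- fill
        }
    }
    new("GenotypeMatrix", codes)
}

#' Marker-inferred kinship matrix
#'
#' Builds the genomic relationship matrix A = (1/a) sum_k Z_k Z_k' from the
#' coded marker matrix Z, with normalization a = n^-1 tr(sum_k Z_k Z_k') so
#' that trace(A) = n and the diagonal elements sit near unity. Optional
#' per-marker centering (subtract the marker mean) and standardization
#' (scale to unit variance) are applied to Z before the cross-product;
#' under standardization, zero-variance (monomorphic) markers are dropped
#' with a warning since they cannot be scaled.
#'
#' @param Z a [GenotypeMatrix-class] (or plain coded matrix)
#' @param center subtract the per-marker mean before the cross-product
#' @param standardize also scale each marker to unit variance (implies
#'   centering of the scale computation; combine with `center` to get the
#'   fully standardized Z)
#' @return a [KinshipEigen-class] with the kinship and normalization factor
#'   filled in; call [eigenKinship()] to complete the eigen pair
#' @examples
#' Z <- matrix(c(-1, 1), 2, 1, dimnames = list(c("a", "b"), "m1"))
#' K <- computeKinship(new("GenotypeMatrix", Z))
#' kinshipMatrix(K)   # [[1,-1],[-1,1]]
#' @export
computeKinship <- function(Z, center = FALSE, standardize = FALSE) {
    M <- if (is(Z, "GenotypeMatrix")) Z@.Data else as.matrix(Z)
    if (!nrow(M) || !ncol(M)) stop("empty genotype matrix")
    ids <- rownames(M)
    if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(M)))
    if (standardize) {
        sds <- apply(M, 2L, stats::sd)
        keep <- sds > 0
        if (!all(keep)) {
            warning(sum(!keep),
                    " monomorphic marker(s) dropped under standardization")
            M <- M[, keep, drop = FALSE]
            sds <- sds[keep]
            if (!ncol(M)) stop("degenerate genotype matrix")
        }
        M <- scale(M, center = TRUE, scale = sds)
        if (!center)  # standardization centers by construction
            center <- TRUE
    } else if (center) {
        M <- scale(M, center = TRUE, scale = FALSE)
    }
    G <- tcrossprod(M)                  # sum_k Z_k Z_k'
    a <- sum(diag(G)) / nrow(M)
    if (a <= .Machine$double.eps)
        stop("degenerate genotype matrix (all codes constant)")
    A <- G / a
    new("KinshipEigen", A = A, a = a, U = matrix(numeric(), 0, 0),
        values = numeric(), ids = ids)
}

#' Eigendecompose a kinship matrix
#'
#' Fills the (U, D) pair of a [KinshipEigen-class] so that A = U D U' with
#' eigenvalues in descending order. Small negative eigenvalues (numerical
#' noise below `tol` relative to the largest eigenvalue) are clipped to
#' zero; the downstream shrinkage factors delta/(delta+lambda) tolerate
#' exact zeros but not negatives. Mild asymmetry below `tol` is symmetrized
#' as (A + A')/2; anything larger is an error.
#'
#' @param x a [KinshipEigen-class], or a plain symmetric PSD matrix (ids
#'   taken from its rownames)
#' @param tol relative tolerance for asymmetry and eigenvalue clipping
#' @return the [KinshipEigen-class] with U and eigenvalues filled
#' @export
eigenKinship <- function(x, tol = 1e-8) {
    if (!is(x, "KinshipEigen")) {
        A <- as.matrix(x)
        if (any(!is.finite(A))) stop("kinship matrix has non-finite entries")
        asym <- max(abs(A - t(A)))
        if (asym > tol * max(1, max(abs(A))))
            stop("kinship matrix asymmetric beyond tolerance ",
                 "(max |A - t(A)| = ", format(asym), ")")
        ids <- rownames(A)
        if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(A)))
        x <- new("KinshipEigen", A = (A + t(A)) / 2, a = NA_real_,
                 U = matrix(numeric(), 0, 0), values = numeric(), ids = ids)
    }
    A <- x@A
    if (any(!is.finite(A))) stop("kinship matrix has non-finite entries")
    scale <- max(1, max(abs(A)))
    asym <- max(abs(A - t(A)))
    if (asym > tol * scale)
        stop("kinship matrix asymmetric beyond tolerance (max |A - t(A)| = ",
             format(asym), ")")
    A <- (A + t(A)) / 2
    eg <- eigen(A, symmetric = TRUE)
    d <- eg$values
    clip <- tol * max(abs(d[1L]), 1)
    if (any(d < -clip))
        stop("kinship matrix is not positive semidefinite (min eigenvalue ",
             format(min(d)), ")")
    d[d < 0] <- 0
    x@A <- A
    x@U <- eg$vectors
    x@values <- d
    validObject(x)
    x
}
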