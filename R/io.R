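#' Read a genotype table
#'
#' Reads a TSV/CSV genotype file with individual ids in the first column
#' and a header row of marker ids. Cell values may be codes in
#' \{-1, 0, 1\} or dosages in \{0, 1, 2\}; the scale is auto-detected from
#' the value range (any negative value means codes; otherwise dosages)
#' and can be forced with `scale`.
#'
#' @param path file path
#' @param sep field separator ("\t" default; "," for CSV)
#' @param scale "auto", "code" (-1/0/1), or "dosage" (0/1/2)
#' @param missing passed to [codeGenotypes()]
#' @return a [GenotypeMatrix-class]
#' @export
readGenotypes <- function(path, sep = "\t", scale = c("auto", "code", "dosage"),
                          missing = "mean") {
    scale <- match.arg(scale)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1L]])
    M <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(M) <- "double"
    rownames(M) <- ids
    if (scale == "auto")
        scale <- if (any(M < 0, na.rm = TRUE)) "code" else "dosage"
    if (scale == "dosage") {
        if (any(!is.na(M) & !(M %in% c(0, 1, 2))))
            stop("dosage file must contain only {0, 1, 2} (or NA)")
        codeGenotypes(M, missing = missing)
    } else {
        if (any(!is.na(M) & (M < -1 | M > 1)))
            stop("code file must contain values in [-1, 1] (or NA)")
        for (k in seq_len(ncol(M))) {
            miss <- is.na(M[, k])
            if (all(miss))
                stop("marker '", colnames(M)[k], "': all calls missing")
            if (any(miss))
                M[miss, k] <- if (missing == "mean") mean(M[!miss, k])
                              else if (missing == "zero") 0
                              else stop("marker '", colnames(M)[k],
                                        "' has missing calls")
        }
        new("GenotypeMatrix", M)
    }
}

#' Read genotypes from a VCF file
#'
#' Converts GT fields of a biallelic VCF to allele dosages (0/1/2,
#' phased and unphased treated alike) and codes them -1/0/+1.
#' Multi-allelic sites are a hard error.
#'
#' @param path path to a (plain or bgzipped) VCF
#' @param missing passed to [codeGenotypes()]
#' @return a [GenotypeMatrix-class]
#' @export
readVCFGenotypes <- function(path, missing = "mean") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    alt <- vcfR::getALT(v)
    multi <- grepl(",", alt)
    if (any(multi))
        stop("multi-allelic site(s) in VCF: ",
             paste(utils::head(which(multi), 5L), collapse = ", "),
             if (sum(multi) > 5L) " ..." else "")
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- apply(gt, c(1L, 2L), function(g) {
        if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
        sum(as.integer(strsplit(g, "[/|]")[[1L]]))
    })
    ids <- vcfR::getID(v)
    if (is.null(ids) || anyNA(ids) || anyDuplicated(ids))
        ids <- paste0(vcfR::getCHROM(v), ":", vcfR::getPOS(v))
    rownames(dos) <- ids
    codeGenotypes(t(dos), missing = missing)
}

#' Read and write kinship matrices as TSV
#'
#' The kinship TSV is a square matrix with an id header row and an id
#' first column; the writer emits 17 significant digits so a round trip
#' reproduces the values to full double precision.
#'
#' @param path file path
#' @return `readKinship` returns a [KinshipEigen-class] (eigen part not
#'   yet filled; `a` recorded as NA since the writer stores only A)
#' @export
readKinship <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1L]])
    A <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(A) <- "double"
    if (!identical(ids, colnames(A)))
        stop("kinship file row and column ids disagree")
    dimnames(A) <- NULL
    new("KinshipEigen", A = (A + t(A)) / 2, a = NA_real_,
        U = matrix(numeric(), 0, 0), values = numeric(), ids = ids)
}

#' @rdname readKinship
#' @param x a [KinshipEigen-class]
#' @export
writeKinship <- function(x, path) {
    A <- kinshipMatrix(x)
    df <- data.frame(id = rownames(A),
                     signif(A, 17), check.names = FALSE)
    colnames(df) <- c("id", rownames(A))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a phenotype table
#'
#' TSV with an `id` column followed by one column per trait (and
#' optionally covariates). Values are returned as a data frame keyed by
#' id; individuals are matched to genotypes/kinship by id join, never by
#' row position.
#'
#' @param path file path
#' @param sep field separator
#' @return data frame with character `id` first column
#' @export
readPhenotypes <- function(path, sep = "\t") {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    names(df)[1L] <- "id"
    df$id <- as.character(df$id)
    if (anyDuplicated(df$id)) stop("duplicate ids in phenotype file")
    df
}

#' Read and write fold assignments as TSV (id, fold)
#'
#' Lets an external partition be replayed bit-exactly.
#'
#' @param path file path
#' @param ids individual ids in analysis order
#' @return `readFolds` returns a [FoldAssignment-class] ordered by `ids`
#' @export
readFolds <- function(path, ids) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (!all(c("id", "fold") %in% names(df)))
        stop("fold file must have columns id, fold")
    miss <- setdiff(ids, as.character(df$id))
    if (length(miss))
        stop("fold file is missing ids: ", paste(miss, collapse = ", "))
    assignment <- as.integer(df$fold[match(ids, as.character(df$id))])
    new("FoldAssignment", n = length(ids), K = max(assignment),
        assignment = assignment, seed = NA_integer_)
}

#' @rdname readFolds
#' @param folds a [FoldAssignment-class]
#' @export
writeFolds <- function(folds, ids, path) {
    utils::write.table(data.frame(id = ids, fold = folds@assignment),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a genotype matrix as TSV (codes -1/0/1 scale)
#'
#' @param x a [GenotypeMatrix-class]
#' @param path file path
#' @export
writeGenotypes <- function(x, path) {
    df <- data.frame(id = individualIds(x), x@.Data, check.names = FALSE)
    colnames(df) <- c("id", markerIds(x))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
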