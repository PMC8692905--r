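# internal helpers shared across modules

#' @importFrom SummarizedExperiment rowData colData assay assayNames
#' @importFrom S4Vectors metadata metadata<- DataFrame
#' @importFrom SingleCellExperiment SingleCellExperiment counts logcounts
NULL

# extract the genes x cells matrix to operate on: SCE logcounts (preferred)
# or counts, or a plain matrix
.exprMatrix <- function(x, assay = NULL) {
    if (is(x, "SummarizedExperiment")) {
        if (is.null(assay))
            assay <- if ("logcounts" %in% assayNames(x)) "logcounts" else "counts"
        m <- as.matrix(SummarizedExperiment::assay(x, assay))
    } else {
        m <- as.matrix(x)
    }
    if (is.null(rownames(m)) || is.null(colnames(m)))
        stop("expression matrix must have gene and cell names")
    m
}

# per-group row means; groups is a vector parallel to columns, NAs dropped
.groupMeans <- function(m, groups) {
    groups <- as.character(groups)
    keep <- !is.na(groups)
    lv <- sort(unique(groups[keep]))
    out <- vapply(lv, function(g) {
        rowMeans(m[, keep & groups == g, drop = FALSE])
    }, numeric(nrow(m)))
    out <- matrix(out, nrow = nrow(m), dimnames = list(rownames(m), lv))
    out
}

# sample row variances (n - 1 denominator)
.rowVars <- function(m) {
    n <- ncol(m)
    if (n < 2L) return(rep(NA_real_, nrow(m)))
    mu <- rowMeans(m)
    rowSums((m - mu)^2) / (n - 1L)
}

.stopifnotScalar <- function(x, name, lower = -Inf) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower)
        stop("'", name, "' must be a single number >= ", lower)
    invisible(x)
}

# condition labels are fixed throughout the package
.CONDITIONS <- c("nonAD", "AD")

.checkCondition <- function(condition) {
    condition <- as.character(condition)
    bad <- setdiff(unique(condition), .CONDITIONS)
    if (length(bad))
        stop("unknown condition label(s): ", paste(bad, collapse = ", "),
             " (expected nonAD/AD)")
    condition
}
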