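# Input coercion and validation shared by every user-facing entry point.

#' Coerce input to a gene x sample count matrix
#'
#' Accepts a plain matrix/data.frame (genes in rows) or a
#' `SummarizedExperiment` (the `"counts"` assay, else the first assay).
#' @noRd
.asCountMatrix <- function(x) {
    if (methods::is(x, "SummarizedExperiment")) {
        nms <- SummarizedExperiment::assayNames(x)
        x <- if (!is.null(nms) && "counts" %in% nms)
            SummarizedExperiment::assay(x, "counts")
        else SummarizedExperiment::assay(x, 1)
    }
    if (is.data.frame(x)) x <- as.matrix(x)
    if (!is.matrix(x) || !is.numeric(x))
        stop("counts must be a numeric matrix (genes x samples)")
    if (is.null(rownames(x))) rownames(x) <- paste0("g", seq_len(nrow(x)))
    if (is.null(colnames(x))) colnames(x) <- paste0("s", seq_len(ncol(x)))
    x
}

#' Map labels of any type to 1..K integer codes
#'
#' Character/factor labels are coded in first-appearance order; integer
#' labels are kept as given (they must then cover 1..K).
#' @noRd
.normalizeLabels <- function(labels, K = NULL) {
    if (is.factor(labels)) labels <- as.character(labels)
    if (any(is.na(labels))) stop("missing class labels")
    if (is.character(labels)) {
        levels <- unique(labels)
        idx <- match(labels, levels)
    } else {
        if (any(labels != round(labels)))
            stop("numeric labels must be integers")
        idx <- as.integer(labels)
        if (any(idx < 1)) stop("integer labels must be >= 1")
        levels <- as.character(seq_len(max(idx)))
    }
    K <- max(if (is.null(K)) 0L else as.integer(K), length(levels))
    if (K > length(levels))
        levels <- c(levels, paste0("class", seq(length(levels) + 1L, K)))
    list(idx = idx, levels = levels, K = K)
}

#' Validate a count matrix and class labels
#'
#' Checks the invariants every estimator relies on: entries are
#' non-negative integers, identifiers are unique, dimensions agree, and
#' every declared class has at least one training sample.  Genes whose
#' total count is zero across all samples are flagged (not dropped): the
#' Gamma prior on the class-difference factors keeps their parameters
#' finite downstream.
#'
#' @param counts gene x sample matrix, data.frame, or
#'   `SummarizedExperiment` of read counts.
#' @param labels class labels of length `ncol(counts)`; character/factor
#'   labels are coded 1..K in first-appearance order.
#' @param K optional declared class count (to catch empty classes).
#' @return a list with elements `counts` (integer-mode matrix), `labels`
#'   (1..K integer codes), `levels`, `K`, `classSizes`, and
#'   `allZeroGenes` (integer indices of flagged genes).
#' @examples
#' x <- matrix(rpois(12, 5), 3, 4,
#'     dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' v <- validateCounts(x, c("A", "A", "B", "B"))
#' v$classSizes
#' @export
validateCounts <- function(counts, labels, K = NULL) {
    counts <- .asCountMatrix(counts)
    if (any(is.na(counts))) stop("missing values in count matrix")
    if (any(counts < 0)) stop("negative count")
    if (any(counts != round(counts))) stop("non-integer count")
    if (anyDuplicated(rownames(counts))) stop("duplicate gene identifiers")
    if (anyDuplicated(colnames(counts))) stop("duplicate sample identifiers")
    if (length(labels) != ncol(counts))
        stop("labels length (", length(labels),
            ") does not match sample count (", ncol(counts), ")")
    lab <- .normalizeLabels(labels, K)
    sizes <- tabulate(lab$idx, nbins = lab$K)
    if (any(sizes == 0))
        stop("empty class ", paste(which(sizes == 0), collapse = ", "))
    storage.mode(counts) <- "integer"
    list(counts = counts, labels = lab$idx, levels = lab$levels,
        K = lab$K, classSizes = sizes,
        allZeroGenes = which(rowSums(counts) == 0L))
}
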