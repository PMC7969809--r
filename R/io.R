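# Plain-text readers/writers, model serialization, and the train/test
# split used by the evaluation protocol.

.sepFor <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a count matrix from TSV/CSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers (genes in rows, the standard expression-matrix
#' orientation); `samplesInRows = TRUE` transposes files exported the
#' other way.  Float values that are integral are cast; anything else is
#' rejected.
#'
#' @param path file path (`.csv` uses a comma separator, anything else
#'   tab).
#' @param samplesInRows the file stores samples in rows.
#' @return validated integer gene x sample matrix.
#' @export
readCounts <- function(path, samplesInRows = FALSE) {
    df <- utils::read.table(path, header = TRUE, sep = .sepFor(path),
        check.names = FALSE, stringsAsFactors = FALSE, row.names = NULL)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric cells in ", path)
    rownames(m) <- ids
    if (samplesInRows) m <- t(m)
    if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers")
    if (anyDuplicated(colnames(m))) stop("duplicate sample identifiers")
    if (any(is.na(m))) stop("missing values in ", path)
    if (any(m != round(m))) stop("non-integer count in ", path)
    if (any(m < 0)) stop("negative count in ", path)
    storage.mode(m) <- "integer"
    m
}

#' Write a count matrix to TSV/CSV
#'
#' Inverse of [readCounts()]: header row of sample ids, first column of
#' gene ids.
#'
#' @param counts gene x sample matrix.
#' @param path output path (`.csv` comma, else tab).
#' @export
writeCounts <- function(counts, path) {
    counts <- .asCountMatrix(counts)
    df <- data.frame(gene_id = rownames(counts), counts,
        check.names = FALSE)
    utils::write.table(df, path, sep = .sepFor(path), quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' Read class labels
#'
#' One label per line, or two-column `sample_id<TAB/;,>label`.  Labels
#' are coded 1..K in first-appearance order; the original names are kept
#' as `levels`.
#'
#' @param path file path.
#' @return list with `labels` (1..K integers), `levels`, and
#'   `sampleIds` (`NULL` for the one-column form).
#' @export
readLabels <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty label file: ", path)
    parts <- strsplit(lines, "[\t,]")
    ncols <- lengths(parts)
    if (any(ncols > 2)) stop("label file must have 1 or 2 columns")
    if (all(ncols == 2)) {
        sampleIds <- vapply(parts, `[`, "", 1)
        raw <- vapply(parts, `[`, "", 2)
    } else {
        sampleIds <- NULL
        raw <- trimws(lines)
    }
    lab <- .normalizeLabels(raw)
    list(labels = lab$idx, levels = lab$levels, sampleIds = sampleIds)
}

#' Serialize a fitted classifier to JSON
#'
#' Writes every [CountClassifier-class] field (and its zero model) as a
#' JSON object, readable back with [readModel()].
#'
#' @param model a `CountClassifier`.
#' @param path output path.
#' @export
writeModel <- function(model, path) {
    zm <- model@zeroModel
    obj <- list(method = model@method, d = model@d,
        sizeFactors = model@sizeFactors, lambda = model@lambda,
        phi = model@phi, priors = model@priors,
        trainGrandTotal = model@trainGrandTotal,
        geneIds = model@geneIds, classLevels = model@classLevels,
        flaggedGenes = model@flaggedGenes,
        zeroModel = list(kind = zm@kind, alpha = zm@alpha,
            beta1 = zm@beta1, beta2 = zm@beta2, refDepth = zm@refDepth,
            p0 = zm@p0))
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
        na = "null")
    invisible(path)
}

#' Read a fitted classifier from JSON
#'
#' @param path a file written by [writeModel()].
#' @return a [CountClassifier-class].
#' @export
readModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    z <- obj$zeroModel
    num1 <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
    zm <- new("ZeroInflationModel", kind = z$kind, alpha = num1(z$alpha),
        beta1 = num1(z$beta1), beta2 = num1(z$beta2),
        refDepth = num1(z$refDepth), p0 = num1(z$p0))
    new("CountClassifier", method = obj$method,
        d = matrix(unlist(obj$d), nrow = length(obj$priors)),
        sizeFactors = as.numeric(obj$sizeFactors),
        lambda = as.numeric(obj$lambda),
        phi = as.numeric(obj$phi %||% numeric(0)),
        zeroModel = zm, priors = as.numeric(obj$priors),
        trainGrandTotal = as.numeric(obj$trainGrandTotal),
        geneIds = as.character(obj$geneIds),
        classLevels = as.character(obj$classLevels),
        flaggedGenes = as.integer(obj$flaggedGenes %||% integer(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified train/test split
#'
#' Randomly partitions samples so that every class appears in both
#' partitions.  Within each class, `round(n_k * trainFraction)` samples
#' (at least 1, at most n_k - 1) go to training; `trainN` instead fixes
#' the total training size, allocated proportionally.
#'
#' @param counts gene x sample matrix.
#' @param labels class labels.
#' @param trainFraction fraction of each class used for training.
#' @param trainN optional total training-set size (overrides
#'   `trainFraction`).
#' @param seed optional integer seed.
#' @return list of two lists `train` and `test`, each with `counts`,
#'   `labels` and `index` (column indices into the input).
#' @export
splitTrainTest <- function(counts, labels, trainFraction = 0.5,
        trainN = NULL, seed = NULL) {
    v <- validateCounts(counts, labels)
    if (any(v$classSizes < 2))
        stop("every class needs >= 2 samples to stratify")
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(seed)
    }
    if (!is.null(trainN)) trainFraction <- trainN / ncol(v$counts)
    idx <- integer(0)
    for (k in seq_len(v$K)) {
        kIdx <- which(v$labels == k)
        nk <- length(kIdx)
        take <- min(max(round(nk * trainFraction), 1), nk - 1)
        idx <- c(idx, sample(kIdx, take))
    }
    idx <- sort(idx)
    rest <- setdiff(seq_len(ncol(v$counts)), idx)
    list(train = list(counts = v$counts[, idx, drop = FALSE],
            labels = v$labels[idx], index = idx),
        test = list(counts = v$counts[, rest, drop = FALSE],
            labels = v$labels[rest], index = rest))
}
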