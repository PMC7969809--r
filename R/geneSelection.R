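# Univariate gene screening by the ratio of between-group to within-group
# sums of squares, computed on the training data only; the test set
# inherits the selected index list.

#' Rank genes by the BSS/WSS ratio
#'
#' For each gene computes
#' \eqn{\sum_k n_k(\bar x_{kg} - \bar x_g)^2 \big/
#' \sum_k \sum_{i \in k} (x_{ig} - \bar x_{kg})^2} and sorts genes from
#' greatest to least ratio.  A gene that is constant within every class
#' but differs between classes has a zero denominator and is given the
#' `Inf` sentinel (a perfect separator, ranked first); a gene constant
#' everywhere gets ratio 0.  Ties are broken by original gene index.
#' Raw counts are used (no size-factor adjustment), matching the
#' classical screening protocol; set `normalize = TRUE` to rank
#' depth-normalised values instead.
#'
#' @param counts gene x sample count matrix.
#' @param labels class labels.
#' @param normalize divide each sample by its total-count size factor
#'   before computing the sums of squares.
#' @return list of class `"GeneRanking"` with `ratios` (length-G) and
#'   `order` (gene indices, decreasing ratio).
#' @examples
#' x <- rbind(g1 = c(0, 2, 4, 6), g2 = c(5, 5, 5, 5))
#' colnames(x) <- paste0("s", 1:4)
#' bssWssRank(x, c(1, 1, 2, 2))$ratios
#' @export
bssWssRank <- function(counts, labels, normalize = FALSE) {
    v <- validateCounts(counts, labels)
    x <- v$counts
    storage.mode(x) <- "double"
    if (normalize)
        x <- sweep(x, 2, totalCountSizeFactors(x), "/")
    labels <- v$labels
    G <- nrow(x)
    overall <- rowMeans(x)
    bss <- numeric(G); wss <- numeric(G)
    for (k in seq_len(v$K)) {
        xk <- x[, labels == k, drop = FALSE]
        mk <- rowMeans(xk)
        bss <- bss + ncol(xk) * (mk - overall)^2
        wss <- wss + rowSums((xk - mk)^2)
    }
    ratios <- ifelse(wss > 0, bss / wss, ifelse(bss > 0, Inf, 0))
    structure(list(ratios = ratios,
        order = order(-ratios, seq_len(G)),
        geneIds = rownames(x)), class = "GeneRanking")
}

#' @export
print.GeneRanking <- function(x, ...) {
    cat("GeneRanking over", length(x$ratios), "genes; top 5:",
        paste(x$geneIds[utils::head(x$order, 5)], collapse = ", "), "\n")
    invisible(x)
}

#' Select the top-ranked genes
#'
#' @param ranking a `"GeneRanking"` from [bssWssRank()].
#' @param p number of genes to keep, `1 <= p <= G`.
#' @return integer vector of the `p` best gene indices (decreasing
#'   ratio, index tie-break).
#' @export
selectTopGenes <- function(ranking, p) {
    G <- length(ranking$ratios)
    if (p < 1 || p > G) stop("p must be in 1..", G)
    ranking$order[seq_len(p)]
}
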