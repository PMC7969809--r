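#' @import methods
NULL

#' Zero-inflation model for excess-zero probabilities
#'
#' Describes how the probability of an excess (structural) zero in a count
#' cell is obtained.  The `"logistic"` kind carries the coefficients of a
#' binomial-logit regression of the zero indicator on the sample's relative
#' sequencing depth and the fitted cell mean; `"constant"` fixes a single
#' excess-zero probability for every cell (the degenerate fit used when the
#' training matrix contains no zeros); `"none"` marks classifiers without a
#' zero-inflation component.
#'
#' @slot kind one of `"logistic"`, `"constant"`, `"none"`.
#' @slot alpha,beta1,beta2 logistic coefficients: intercept, coefficient on
#'   relative depth \eqn{N/N_{ref}}, coefficient on the cell mean \eqn{\mu}.
#' @slot refDepth library size of the reference training sample (first
#'   sample of class 1 in input order).
#' @slot p0 fixed excess-zero probability for the `"constant"` kind.
#'
#' @exportClass ZeroInflationModel
setClass("ZeroInflationModel",
    representation(kind = "character", alpha = "numeric", beta1 = "numeric",
        beta2 = "numeric", refDepth = "numeric", p0 = "numeric"),
    prototype(kind = "none", alpha = NA_real_, beta1 = NA_real_,
        beta2 = NA_real_, refDepth = NA_real_, p0 = 0))

setValidity("ZeroInflationModel", function(object) {
    msg <- NULL
    if (!object@kind %in% c("logistic", "constant", "none"))
        msg <- c(msg, "kind must be 'logistic', 'constant' or 'none'")
    if (object@kind == "logistic") {
        if (!all(is.finite(c(object@alpha, object@beta1, object@beta2))))
            msg <- c(msg, "logistic coefficients must be finite")
        if (!isTRUE(object@refDepth > 0))
            msg <- c(msg, "refDepth must be positive")
    }
    if (object@kind == "constant" &&
        !(object@p0 >= 0 && object@p0 < 1))
        msg <- c(msg, "constant p0 must lie in [0, 1)")
    if (is.null(msg)) TRUE else msg
})

#' Fitted count-model discriminant classifier
#'
#' Parameter bundle for one of the four count-model linear discriminant
#' classifiers.  All four share the mean decomposition
#' \eqn{\mu_{kig} = d_{kg} s_i \lambda_g}: `d` holds the class-difference
#' factors (1 for a gene with no class effect), `sizeFactors` the
#' total-count size factors of the training samples (they sum to 1),
#' `lambda` the per-gene abundances.  `phi` carries the per-gene NB
#' dispersions for NBLDA/ZINBLDA (length 0 otherwise) and `zeroModel` the
#' excess-zero model for ZIPLDA/ZINBLDA (`kind == "none"` otherwise).
#' The Gamma(beta, beta) prior on `d` (beta = 1 throughout) keeps every
#' entry strictly positive; the class-independent constant of the
#' discriminant scores is dropped identically across classes.
#'
#' @slot method one of `"PLDA"`, `"NBLDA"`, `"ZIPLDA"`, `"ZINBLDA"`.
#' @slot d K x G positive matrix of class-difference factors.
#' @slot sizeFactors length-n positive vector summing to 1.
#' @slot lambda length-G non-negative gene abundances.
#' @slot phi length-G non-negative dispersions, or `numeric(0)`.
#' @slot zeroModel a [ZeroInflationModel-class] object.
#' @slot priors class priors \eqn{\pi_k = n_k/n}, summing to 1.
#' @slot trainGrandTotal grand total count of the training matrix (the
#'   denominator of every size factor, including the test one).
#' @slot geneIds,classLevels identifiers carried through from training.
#' @slot flaggedGenes indices of genes whose training total count is zero
#'   (retained, not dropped; the prior keeps their `d` finite).
#'
#' @seealso [fitCountClassifier()], [predict,CountClassifier-method]
#' @exportClass CountClassifier
setClass("CountClassifier",
    representation(method = "character", d = "matrix",
        sizeFactors = "numeric", lambda = "numeric", phi = "numeric",
        zeroModel = "ZeroInflationModel", priors = "numeric",
        trainGrandTotal = "numeric", geneIds = "character",
        classLevels = "character", flaggedGenes = "integer"))

setValidity("CountClassifier", function(object) {
    msg <- NULL
    if (!object@method %in% c("PLDA", "NBLDA", "ZIPLDA", "ZINBLDA"))
        msg <- c(msg, "unknown method")
    K <- nrow(object@d); G <- ncol(object@d)
    if (length(object@priors) != K)
        msg <- c(msg, "priors length must equal nrow(d)")
    if (abs(sum(object@priors) - 1) > 1e-8 ||
        any(object@priors <= 0) || any(object@priors > 1))
        msg <- c(msg, "priors must lie in (0, 1] and sum to 1")
    if (any(!is.finite(object@d)) || any(object@d <= 0))
        msg <- c(msg, "all class-difference entries d_kg must be positive and finite")
    if (length(object@lambda) != G)
        msg <- c(msg, "lambda length must equal ncol(d)")
    if (any(object@lambda < 0)) msg <- c(msg, "lambda must be non-negative")
    if (length(object@phi) && length(object@phi) != G)
        msg <- c(msg, "phi must be empty or length G")
    if (length(object@phi) && any(object@phi < 0))
        msg <- c(msg, "phi entries must be >= 0")
    if (!isTRUE(object@trainGrandTotal > 0))
        msg <- c(msg, "trainGrandTotal must be positive")
    if (object@method %in% c("ZIPLDA", "ZINBLDA") &&
        object@zeroModel@kind == "none")
        msg <- c(msg, "zero-inflated methods need a zero model")
    if (is.null(msg)) TRUE else msg
})

#' Meta-model recommending a classifier from dataset attributes
#'
#' A decision tree or random forest trained on a benchmark meta-table that
#' labels each (n, phi, p0) grid cell with the classifier attaining the
#' smallest mean misclassification rate there.  `resubError` is the
#' resubstitution (training-set) misclassification rate; for forests
#' `oobError` additionally stores the out-of-bag estimate, the error a
#' forest conventionally reports since its resubstitution error is
#' trivially near zero.
#'
#' @slot kind `"tree"` or `"forest"`.
#' @slot fit the underlying [rpart::rpart] or
#'   [randomForest::randomForest] object.
#' @slot metaTable the training meta-table (one row per grid cell).
#' @slot resubError,oobError training-error summaries in `[0, 1]`
#'   (`oobError` is `NA` for trees).
#'
#' @seealso [buildMetaTable()], [fitSelector()], [recommendClassifier()]
#' @exportClass ClassifierSelector
setClass("ClassifierSelector",
    representation(kind = "character", fit = "ANY",
        metaTable = "data.frame", resubError = "numeric",
        oobError = "numeric"))

setValidity("ClassifierSelector", function(object) {
    msg <- NULL
    if (!object@kind %in% c("tree", "forest"))
        msg <- c(msg, "kind must be 'tree' or 'forest'")
    if (nrow(object@metaTable) < 1) msg <- c(msg, "empty meta-table")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn CountClassifier-class compact display of a fitted classifier.
#' @param object a `CountClassifier`.
#' @export
setMethod("show", "CountClassifier", function(object) {
    cat("CountClassifier (", object@method, ")\n", sep = "")
    cat("  classes: ", length(object@priors),
        " [", paste(object@classLevels, collapse = ", "), "]\n", sep = "")
    cat("  genes:   ", ncol(object@d),
        if (length(object@flaggedGenes))
            paste0(" (", length(object@flaggedGenes), " all-zero, flagged)"),
        "\n", sep = "")
    cat("  samples: ", length(object@sizeFactors), "\n", sep = "")
    if (length(object@phi))
        cat("  dispersion: median phi = ",
            signif(stats::median(object@phi), 3), "\n", sep = "")
    if (object@zeroModel@kind == "logistic")
        cat("  zero model: logistic (alpha=", signif(object@zeroModel@alpha, 3),
            ", beta1=", signif(object@zeroModel@beta1, 3),
            ", beta2=", signif(object@zeroModel@beta2, 3), ")\n", sep = "")
    if (object@zeroModel@kind == "constant")
        cat("  zero model: constant p0 = ", object@zeroModel@p0, "\n", sep = "")
    invisible(NULL)
})

#' @describeIn ClassifierSelector-class compact display of a selector.
#' @param object a `ClassifierSelector`.
#' @export
setMethod("show", "ClassifierSelector", function(object) {
    cat("ClassifierSelector (", object@kind, ") trained on ",
        nrow(object@metaTable), " grid cells\n", sep = "")
    cat("  resubstitution error: ",
        sprintf("%.1f%%", 100 * object@resubError), "\n", sep = "")
    if (!is.na(object@oobError))
        cat("  out-of-bag error:     ",
            sprintf("%.1f%%", 100 * object@oobError), "\n", sep = "")
    invisible(NULL)
})

#' Construct a constant zero-inflation model
#'
#' Convenience constructor for a [ZeroInflationModel-class] that assigns the
#' same excess-zero probability `p0` to every cell, bypassing the logistic
#' depth/mean relation.  Used for the degenerate fit on zero-free training
#' data (`p0 = 0`) and in reduction checks between the zero-inflated and
#' plain classifiers.
#'
#' @param p0 excess-zero probability in `[0, 1)`.
#' @return a `ZeroInflationModel` of kind `"constant"`.
#' @export
constantZeroModel <- function(p0 = 0) {
    new("ZeroInflationModel", kind = "constant", p0 = p0)
}
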