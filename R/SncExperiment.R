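#' Construct an SncExperiment
#'
#' Bundles a raw count matrix, feature kinds and a sample table into the
#' package's central container, assigning the cohort its analysis role.
#'
#' @param counts integer matrix, features x samples, with row and column
#'   names (feature and sample IDs).
#' @param samples `data.frame` or `DataFrame` of per-sample covariates, one
#'   row per column of `counts` (matched by rownames when present, otherwise
#'   by order). Typically contains `diagnosis`, `batch`, `age`, `sex` and the
#'   CSF protein markers `pTau`, `Abeta42`, `Abeta40`.
#' @param kind character vector, `"miRNA"`/`"piRNA"` per feature. Defaults to
#'   tagging IDs starting with `"piR"` as piRNA and everything else as miRNA.
#' @param role cohort role; one of `"unassigned"`, `"signature_train"`,
#'   `"replication_test"`, `"mci_test"`, `"external_test"`. Roles ending in
#'   `_test` are structurally barred from all fitting operations.
#'
#' @return An [SncExperiment-class] object.
#' @examples
#' cts <- matrix(rpois(20, 50), 4, 5,
#'               dimnames = list(paste0("miR-", 1:4), paste0("S", 1:5)))
#' smp <- data.frame(diagnosis = c("control", "control", "AD", "AD", "AD"),
#'                   row.names = colnames(cts))
#' se <- SncExperiment(cts, smp, role = "signature_train")
#' @export
SncExperiment <- function(counts, samples, kind = NULL, role = "unassigned") {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must have feature (row) and sample (column) names")
    if (is.null(kind))
        kind <- ifelse(grepl("^piR", rownames(counts)), "piRNA", "miRNA")
    samples <- as.data.frame(samples)
    if (!is.null(rownames(samples)) &&
        !identical(rownames(samples), as.character(seq_len(nrow(samples))))) {
        miss <- setdiff(colnames(counts), rownames(samples))
        if (length(miss))
            stop("samples table lacks rows for: ",
                 paste(miss, collapse = ", "))
        samples <- samples[colnames(counts), , drop = FALSE]
    } else if (nrow(samples) != ncol(counts)) {
        stop("samples table must have one row per sample")
    }
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(kind = kind, row.names = rownames(counts)),
        colData = DataFrame(samples, row.names = colnames(counts)))
    new("SncExperiment", se, role = role,
        provenance = paste0("created: ", nrow(counts), " features x ",
                            ncol(counts), " samples, role=", role))
}

#' @describeIn SncExperiment cohort role accessor.
#' @param x an `SncExperiment`.
#' @export
cohortRole <- function(x) {
    stopifnot(is(x, "SncExperiment"))
    x@role
}

#' @describeIn SncExperiment per-feature kind (miRNA/piRNA) accessor.
#' @export
featureKind <- function(x) {
    stopifnot(is(x, "SncExperiment"))
    stats::setNames(as.character(rowData(x)$kind), rownames(x))
}

#' @describeIn SncExperiment log of transformations applied so far.
#' @export
provenance <- function(x) {
    stopifnot(is(x, "SncExperiment"))
    x@provenance
}

#' @describeIn SncExperiment the normalized (glog2) assay; errors if
#'   [vsnTransform()] has not been run.
#' @export
normalizedValues <- function(x) {
    stopifnot(is(x, "SncExperiment"))
    if (!"normalized" %in% assayNames(x))
        stop("no 'normalized' assay: run vsnTransform() first")
    assay(x, "normalized")
}

## internal: append a provenance line (never changes the role)
.addProvenance <- function(x, line) {
    x@provenance <- c(x@provenance, line)
    x
}

## internal: refuse held-out cohorts in fitting code paths
.assertTrainable <- function(x, what) {
    if (grepl("_test$", cohortRole(x)))
        stop("leakage guard: cohort with role '", cohortRole(x),
             "' must not be used for ", what)
    invisible(TRUE)
}

#' @export
setMethod("show", "SncExperiment", function(object) {
    callNextMethod()
    cat("role:", object@role, "\n")
    cat("kinds:", paste(names(table(rowData(object)$kind)),
                        table(rowData(object)$kind),
                        sep = ":", collapse = " "), "\n")
    cat("provenance:", length(object@provenance), "step(s)\n")
})

setMethod("show", "RelevanceRanking", function(object) {
    cat("RelevanceRanking:", nrow(object@table), "features;",
        sum(object@table$passes), "pass critical value",
        format(object@criticalValue, digits = 4), "\n")
    cat("  null:", object@nPermutations,
        if (object@exhaustive) "arrangements (exhaustive);"
        else "permutations;",
        "alpha =", object@alpha, "\n")
})

setMethod("show", "StabilityReport", function(object) {
    cat("StabilityReport:", nrow(object@table), "features;",
        sum(object@table$stable), "stable at threshold",
        object@stabilityThreshold, "over", object@nResamples,
        "resamples\n")
})

setMethod("show", "InfoRanking", function(object) {
    cat("InfoRanking:", nrow(object@table), "features;",
        sum(object@table$kept), "above permutation null (",
        object@nBins, "bins )\n")
})

setMethod("show", "ConfoundReport", function(object) {
    cat("ConfoundReport:", sum(object@table$retained), "of",
        nrow(object@table), "features retained at alpha =", object@alpha,
        "(Bonferroni)\n")
    if (!is.na(object@pillai["statistic"]))
        cat("  Pillai's trace:", format(object@pillai["statistic"],
                                        digits = 4),
            " p =", format(object@pillai["p.value"], digits = 3), "\n")
})

setMethod("show", "Signature", function(object) {
    cat("Signature of", length(object@featureIds), "sncRNAs:\n")
    print(data.frame(feature = object@featureIds, kind = object@kind,
                     direction = object@direction))
})

setMethod("show", "ForestModel", function(object) {
    cat("ForestModel:", object@nTrees, "trees (CV weighted error",
        format(object@cvError, digits = 3), ") on",
        length(object@featureNames), "features\n")
})

setMethod("show", "RocResult", function(object) {
    cat("RocResult: AUC =", format(object@auc, digits = 3))
    if (!is.na(object@ciLow))
        cat(" [", format(object@ciLow, digits = 3), ",",
            format(object@ciHigh, digits = 3), "] (",
            object@nBootstrap, "stratified bootstraps )")
    cat("\n")
})

#' @describeIn Signature-class feature IDs in rank order.
#' @param x a `Signature`.
#' @export
signatureFeatures <- function(x) {
    stopifnot(is(x, "Signature"))
    x@featureIds
}

#' @describeIn Signature-class signature as a data.frame.
#' @export
signatureTable <- function(x) {
    stopifnot(is(x, "Signature"))
    data.frame(feature_id = x@featureIds, kind = x@kind,
               direction = x@direction)
}

#' @describeIn RocResult-class the area under the ROC curve.
#' @param x a `RocResult`.
#' @export
aucValue <- function(x) {
    stopifnot(is(x, "RocResult"))
    x@auc
}

#' @describeIn RocResult-class 95% percentile-bootstrap interval
#'   (`c(low, high)`).
#' @export
aucInterval <- function(x) {
    stopifnot(is(x, "RocResult"))
    c(low = x@ciLow, high = x@ciHigh)
}

#' @describeIn RocResult-class ROC curve points as a data.frame.
#' @export
rocPoints <- function(x) {
    stopifnot(is(x, "RocResult"))
    data.frame(fpr = x@fpr, tpr = x@tpr)
}

#' @describeIn RelevanceRanking-class ranking table as a data.frame.
#' @param x a `RelevanceRanking`.
#' @export
rankingTable <- function(x) {
    stopifnot(is(x, "RelevanceRanking"))
    as.data.frame(x@table)
}

#' @describeIn RelevanceRanking-class the permutation critical value (the
#'   "dotted red line" cutoff).
#' @export
criticalValue <- function(x) {
    stopifnot(is(x, "RelevanceRanking"))
    x@criticalValue
}
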