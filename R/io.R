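#' Read and write count matrices and sample tables (TSV)
#'
#' Counts are stored as TSV with a `feature_id` first column, an optional
#' `kind` column (miRNA/piRNA; inferred from the `piR` ID prefix when
#' absent), and one column per sample. Sample tables carry a `sample_id`
#' first column. Readers validate types and reject duplicated IDs, naming
#' the offending rows or columns; values must be nonnegative integers.
#'
#' @param path TSV file path.
#' @return `readCounts`: list(counts = integer matrix, kind = character
#'   vector). `readSamples`: a `data.frame` with `sample_id` rownames.
#' @export
readCounts <- function(path) {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (!ncol(tab) || colnames(tab)[1] != "feature_id")
        stop("first column must be 'feature_id'")
    ids <- as.character(tab$feature_id)
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop("duplicate feature ID(s): ", paste(unique(dup), collapse = ", "))
    kindCol <- which(colnames(tab) == "kind")
    kind <- if (length(kindCol)) as.character(tab[[kindCol]]) else
        ifelse(grepl("^piR", ids), "piRNA", "miRNA")
    valCols <- setdiff(seq_len(ncol(tab))[-1], kindCol)
    sampleIds <- colnames(tab)[valCols]
    dup <- sampleIds[duplicated(sampleIds)]
    if (length(dup))
        stop("duplicate sample column(s): ",
             paste(unique(dup), collapse = ", "))
    m <- as.matrix(tab[, valCols, drop = FALSE])
    if (!is.numeric(m)) {
        badCol <- sampleIds[vapply(valCols, function(j)
            !is.numeric(tab[[j]]), logical(1))]
        stop("non-numeric counts in column(s): ",
             paste(badCol, collapse = ", "))
    }
    bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad))
        stop("counts must be nonnegative integers; first offender: ",
             "feature ", ids[bad[1, 1]], ", sample ", sampleIds[bad[1, 2]])
    storage.mode(m) <- "integer"
    dimnames(m) <- list(ids, sampleIds)
    list(counts = m, kind = kind)
}

#' @rdname readCounts
#' @param x an [SncExperiment-class] (or matrix for `writeCounts`).
#' @param kind per-feature kind when `x` is a matrix.
#' @export
writeCounts <- function(x, path, kind = NULL) {
    if (is(x, "SncExperiment")) {
        kind <- unname(featureKind(x))
        x <- assay(x, "counts")
    }
    df <- data.frame(feature_id = rownames(x),
                     kind = if (is.null(kind))
                         ifelse(grepl("^piR", rownames(x)), "piRNA",
                                "miRNA") else kind,
                     x, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname readCounts
#' @export
readSamples <- function(path) {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (!ncol(tab) || colnames(tab)[1] != "sample_id")
        stop("first column must be 'sample_id'")
    dup <- tab$sample_id[duplicated(tab$sample_id)]
    if (length(dup))
        stop("duplicate sample ID(s): ", paste(unique(dup), collapse = ", "))
    if ("age" %in% colnames(tab) && any(!is.na(tab$age) & tab$age <= 0))
        stop("age must be positive where present")
    rownames(tab) <- tab$sample_id
    tab[, -1, drop = FALSE]
}

#' @rdname readCounts
#' @param samples data.frame of per-sample covariates (rownames = IDs), or
#'   an `SncExperiment`.
#' @export
writeSamples <- function(samples, path) {
    if (is(samples, "SncExperiment"))
        samples <- as.data.frame(colData(samples))
    df <- data.frame(sample_id = rownames(samples), samples,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Load a cohort bundle from TSV files
#'
#' @param countsPath,samplesPath TSV paths as written by [writeCounts()] /
#'   [writeSamples()].
#' @param role cohort role, see [SncExperiment()].
#' @return An [SncExperiment-class].
#' @export
readCohort <- function(countsPath, samplesPath, role = "unassigned") {
    cts <- readCounts(countsPath)
    smp <- readSamples(samplesPath)
    SncExperiment(cts$counts, smp, kind = cts$kind, role = role)
}
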