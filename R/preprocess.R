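#' Filter out low-depth samples
#'
#' Removes every sample whose library size (column sum of the raw count
#' matrix) is strictly below `minLibrarySize`. The default of 50,000 reads is
#' the conventional floor for CSF-exosome small RNA libraries, below which
#' quantification is unreliable.
#'
#' @param x an [SncExperiment-class].
#' @param minLibrarySize minimum total counts per retained sample.
#' @return The filtered `SncExperiment`; `metadata(x)$sample_filter` holds a
#'   data.frame of removed sample IDs and their library sizes.
#' @export
filterSamples <- function(x, minLibrarySize = 50000) {
    stopifnot(is(x, "SncExperiment"))
    libsize <- colSums(assay(x, "counts"))
    keep <- libsize >= minLibrarySize
    if (!any(keep))
        stop("empty cohort: all ", length(keep),
             " samples fall below the minimum library size of ",
             minLibrarySize)
    report <- data.frame(sample_id = colnames(x)[!keep],
                         library_size = unname(libsize[!keep]))
    out <- x[, keep]
    metadata(out)$sample_filter <- report
    .addProvenance(out, paste0("filterSamples: removed ", sum(!keep), "/",
                               length(keep), " samples (< ", minLibrarySize,
                               " reads)"))
}

#' Variance-stabilizing normalization (affine calibration + glog2)
#'
#' Normalizes a count matrix with a VSN-style model: each sample receives an
#' affine calibration (offset `a_s`, positive scale `b_s`) followed by a
#' generalized log2, `h_s(x) = glog2((x - a_s) / b_s)` with
#' `glog2(z) = log2((z + sqrt(z^2 + c^2)) / 2)`. For large counts this
#' behaves as `log2((x - a_s) / b_s)`; near zero the glog damps the variance
#' inflation of the plain log, so per-feature variances become approximately
#' independent of the mean.
#'
#' Calibration is estimated iteratively: samples are regressed against the
#' across-sample trimmed-mean reference profile (ordinary least squares over
#' the central `1 - 2 * trim` quantile band of the reference), the reference
#' is recomputed from the calibrated matrix, and the loop stops when no
#' parameter moves by more than `tol` or after `maxIter` rounds. The glog
#' offset `c` is set to the median calibrated count level (per-feature mean
#' of the calibrated matrix) among low-abundance features (calibrated mean
#' < 10); when no such feature exists it falls back to 1.
#'
#' @param x an [SncExperiment-class] (adds a `"normalized"` assay) or a
#'   numeric count matrix (returns a list).
#' @param trim trimming fraction in [0, 0.5) for the reference profile and
#'   the calibration band.
#' @param tol,maxIter convergence control for the calibration loop.
#' @return For an `SncExperiment`: the object with assay `"normalized"` and
#'   `metadata(x)$vsn = list(a, b, c, iterations, converged)`. For a matrix:
#'   `list(h, a, b, c, iterations, converged)` where `h` is the transformed
#'   matrix.
#' @examples
#' m <- matrix(rpois(600, 40), 30, 20,
#'             dimnames = list(paste0("f", 1:30), paste0("s", 1:20)))
#' v <- vsnTransform(m)
#' range(v$h)
#' @export
setGeneric("vsnTransform", function(x, trim = 0.1, tol = 1e-6, maxIter = 50)
    standardGeneric("vsnTransform"))

#' @rdname vsnTransform
#' @export
setMethod("vsnTransform", "matrix", function(x, trim = 0.1, tol = 1e-6,
                                             maxIter = 50) {
    if (ncol(x) < 2) stop("at least 2 samples required")
    if (nrow(x) < 10) stop("at least 10 features required")
    if (trim < 0 || trim >= 0.5) stop("trim must lie in [0, 0.5)")
    .vsnCore(x, trim, tol, maxIter)
})

#' @rdname vsnTransform
#' @export
setMethod("vsnTransform", "SncExperiment", function(x, trim = 0.1,
                                                    tol = 1e-6,
                                                    maxIter = 50) {
    fit <- vsnTransform(assay(x, "counts"), trim = trim, tol = tol,
                        maxIter = maxIter)
    assay(x, "normalized") <- fit$h
    metadata(x)$vsn <- fit[c("a", "b", "c", "iterations", "converged")]
    .addProvenance(x, sprintf("vsnTransform: c=%.4g, %d iteration(s)",
                              fit$c, fit$iterations))
})

## Robust affine calibration: per-sample scale b_s is the median of
## count/reference ratios over the central expression band (insensitive to
## extreme features), and the offset a_s is the median residual of the
## low-expression features (a background estimate, near zero for clean
## count data). The reference profile is the trimmed mean of the calibrated
## matrix, recomputed each round.
.vsnCore <- function(X, trim, tol, maxIter) {
    S <- ncol(X)
    b <- colSums(X)
    b <- b / exp(mean(log(pmax(b, 1))))
    b[b <= 0] <- 1
    a <- numeric(S)
    converged <- FALSE
    iter <- 0L
    for (iter in seq_len(maxIter)) {
        Xc <- sweep(sweep(X, 2, a, "-"), 2, b, "/")
        ref <- apply(Xc, 1, mean, trim = trim)
        qs <- stats::quantile(ref[ref > 0], c(max(trim, 0.25), 1 - trim),
                              na.rm = TRUE)
        band <- ref >= qs[1] & ref <= qs[2] & ref > 0
        if (sum(band) < 3) band <- ref > 0
        lowf <- ref <= stats::quantile(ref, 0.25) & ref >= 0
        if (!any(lowf)) lowf <- band
        aNew <- numeric(S); bNew <- numeric(S)
        for (s in seq_len(S)) {
            bNew[s] <- stats::median(X[band, s] / ref[band])
            if (!is.finite(bNew[s]) || bNew[s] <= 0) bNew[s] <- b[s]
            aNew[s] <- stats::median(X[lowf, s] - bNew[s] * ref[lowf])
            if (!is.finite(aNew[s])) aNew[s] <- a[s]
        }
        delta <- max(abs(aNew - a), abs(bNew - b))
        a <- aNew; b <- bNew
        if (!all(is.finite(c(a, b))))
            stop("VSN calibration produced non-finite parameters ",
                 "(iteration ", iter, ")")
        if (delta < tol) { converged <- TRUE; break }
    }
    Xc <- sweep(sweep(X, 2, a, "-"), 2, b, "/")
    rm <- rowMeans(Xc)
    low <- rm < 10
    cOff <- if (any(low)) stats::median(rm[low]) else 1
    cOff <- max(cOff, 1e-3)
    h <- .glog2(Xc, cOff)
    dimnames(h) <- dimnames(X)
    list(h = h, a = a, b = b, c = cOff, iterations = iter,
         converged = converged)
}

.glog2 <- function(z, c) log2((z + sqrt(z * z + c * c)) / 2)

#' Remove unwanted variation using empirical control features
#'
#' Estimates `k` nuisance factors from designated control features (by
#' default the least-variable quartile of the normalized matrix, on the
#' premise that features untouched by the biology mainly carry technical
#' variation) via the singular value decomposition of the row-centered
#' control submatrix, then regresses the factors out of every feature.
#' `k = 0` returns the input unchanged. Batch labels, when supplied, are not
#' used in estimation (the factors are unsupervised) but a post-correction
#' between-batch separation diagnostic is stored.
#'
#' @param x an [SncExperiment-class] with a `"normalized"` assay.
#' @param k number of nuisance factors to remove.
#' @param controlFeatures optional character vector of feature IDs to use as
#'   negative controls; defaults to the least-variable quartile.
#' @param batch optional per-sample batch labels, diagnostics only.
#' @return The corrected `SncExperiment`; `metadata(x)$ruv` stores `W`
#'   (samples x k factors), `alpha` (k x features loadings), the control set
#'   and the diagnostic.
#' @export
removeUnwantedVariance <- function(x, k = 1, controlFeatures = NULL,
                                   batch = NULL) {
    stopifnot(is(x, "SncExperiment"))
    Y <- normalizedValues(x)
    if (k >= ncol(Y) - 1) stop("k must be < number of samples - 2")
    if (k == 0) return(x)
    if (is.null(controlFeatures)) {
        rv <- apply(Y, 1, stats::var)
        controlFeatures <- rownames(Y)[rv <= stats::quantile(rv, 0.25)]
    }
    controlFeatures <- intersect(controlFeatures, rownames(Y))
    if (length(controlFeatures) < k + 1)
        stop("need at least k + 1 = ", k + 1, " control features, have ",
             length(controlFeatures))
    Yc <- Y[controlFeatures, , drop = FALSE]
    Yc <- Yc - rowMeans(Yc)
    sv <- svd(Yc, nu = 0, nv = k)
    W <- sv$v[, seq_len(k), drop = FALSE]           # samples x k
    Ycent <- Y - rowMeans(Y)
    alpha <- t(solve(crossprod(W), crossprod(W, t(Ycent))))  # features x k
    corrected <- Y - alpha %*% t(W)
    assay(x, "normalized") <- corrected
    diag <- NA_real_
    if (!is.null(batch) && length(unique(batch)) > 1) {
        bm <- vapply(split(seq_len(ncol(corrected)), batch),
                     function(i) mean(corrected[, i]), numeric(1))
        diag <- max(bm) - min(bm)
    }
    metadata(x)$ruv <- list(W = W, alpha = alpha,
                            control_features = controlFeatures,
                            batch_mean_range = diag)
    .addProvenance(x, paste0("removeUnwantedVariance: k=", k, ", ",
                             length(controlFeatures), " control features"))
}

#' Expression filter on the normalized scale
#'
#' Drops features that are essentially unexpressed in both diagnostic
#' groups: a feature is removed iff, in each of the two groups, at least
#' `exprFraction` of the samples lie below `exprThreshold` on the normalized
#' scale. Equivalently a feature is kept when it is expressed (value >=
#' threshold) in more than `1 - exprFraction` of at least one group, so
#' group-specific markers survive.
#'
#' @param x an [SncExperiment-class] with a `"normalized"` assay.
#' @param groups optional two-level labels; defaults to the diagnosis column
#'   (AD/MCI_converter vs control/MCI_stable).
#' @param exprThreshold normalized-scale expression floor (default 0.5).
#' @param exprFraction fraction of below-floor samples required for removal
#'   (default 0.95).
#' @return The filtered `SncExperiment`; `metadata(x)$feature_filter`
#'   reports removed/retained counts per feature kind.
#' @export
filterFeatures <- function(x, groups = NULL, exprThreshold = 0.5,
                           exprFraction = 0.95) {
    stopifnot(is(x, "SncExperiment"))
    Y <- normalizedValues(x)
    groups <- if (is.null(groups)) .seGroups(x) else .asGroups(groups)
    if (length(groups) != ncol(Y))
        stop("groups must have one label per sample")
    if (any(table(groups) < 2))
        stop("each group needs at least 2 samples")
    lowFrac <- vapply(levels(groups), function(g) {
        rowMeans(Y[, groups == g, drop = FALSE] < exprThreshold)
    }, numeric(nrow(Y)))
    removed <- rowSums(lowFrac >= exprFraction) == 2L
    if (all(removed))
        stop("expression filter removed every feature")
    kind <- featureKind(x)
    report <- as.data.frame(table(kind = kind, retained = !removed))
    out <- x[!removed, ]
    metadata(out)$feature_filter <- report
    .addProvenance(out, paste0("filterFeatures: removed ", sum(removed), "/",
                               length(removed), " features (< ",
                               exprThreshold, " in >= ", exprFraction * 100,
                               "% of both groups)"))
}

#' Run the full preprocessing chain
#'
#' Applies, in the fixed order the pipeline requires: sample filter ->
#' variance-stabilizing normalization -> removal of unwanted variation ->
#' expression filter. The order is enforced here; calling the stages
#' individually out of order fails on missing prerequisites.
#'
#' @param x an [SncExperiment-class] with raw counts.
#' @param minLibrarySize,exprThreshold,exprFraction,ruvK,trim stage
#'   parameters, see the individual stage functions.
#' @param groups optional two-level labels for the expression filter.
#' @param featureFilter set `FALSE` to skip the expression filter (used for
#'   held-out cohorts that are later restricted to a signature).
#' @return The preprocessed `SncExperiment`.
#' @export
preprocess <- function(x, minLibrarySize = 50000, exprThreshold = 0.5,
                       exprFraction = 0.95, ruvK = 1, trim = 0.1,
                       groups = NULL, featureFilter = TRUE) {
    x <- filterSamples(x, minLibrarySize = minLibrarySize)
    x <- vsnTransform(x, trim = trim)
    x <- removeUnwantedVariance(x, k = ruvK)
    if (featureFilter)
        x <- filterFeatures(x, groups = groups,
                            exprThreshold = exprThreshold,
                            exprFraction = exprFraction)
    x
}
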