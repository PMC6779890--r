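#' Tune and train the random-forest classifier
#'
#' Chooses the ensemble size by stratified tenfold cross-validation of the
#' class-weighted misclassification error over a tree grid (ties resolved
#' toward fewer trees), then refits on the full training data with
#' stratified per-tree sampling and the configured class weights. The
#' asymmetric default weights (control 0.5, case 1.0) penalize false
#' negatives, reflecting the screening use-case. Permutation variable
#' importance (mean decrease in accuracy) is stored.
#'
#' @param features numeric matrix, samples x features (complete, no missing
#'   values), with column names.
#' @param labels two-level labels, second level = case.
#' @param treeGrid candidate tree counts.
#' @param nFolds CV folds (default 10).
#' @param classWeights named weights `c(control = , case = )`.
#' @param seed integer seed; the fit is reproducible.
#' @return A [ForestModel-class].
#' @importFrom randomForest randomForest importance
#' @export
tuneAndTrain <- function(features, labels, treeGrid = seq(100, 1000, 100),
                         nFolds = 10, classWeights = c(control = 0.5,
                                                       case = 1.0),
                         seed = 1L) {
    features <- as.matrix(features)
    if (anyNA(features)) stop("features must be complete (no missing values)")
    y <- .asGroups(labels)
    if (any(table(y) < 2)) stop("both classes need at least 2 samples")
    if (any(classWeights <= 0)) stop("class weights must be positive")
    if (nFolds < 2) stop("nFolds must be >= 2")
    if (all(apply(features, 2, function(v) length(unique(v)) == 1)))
        stop("every feature is constant; the forest cannot be grown")
    w <- stats::setNames(classWeights[c("control", "case")],
                         levels(y))
    nFolds <- min(nFolds, min(table(y)))

    set.seed(.subSeed(seed, 1L))
    fold <- integer(length(y))
    for (lev in levels(y)) {
        idx <- which(y == lev)
        fold[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
    }
    cvErr <- vapply(treeGrid, function(nt) {
        wrong <- 0; tot <- 0
        for (k in seq_len(nFolds)) {
            tr <- fold != k
            if (length(unique(y[tr])) < 2 || sum(!tr) == 0) next
            fit <- randomForest::randomForest(
                x = features[tr, , drop = FALSE], y = y[tr], ntree = nt,
                classwt = w, strata = y[tr],
                sampsize = as.vector(table(y[tr])))
            pred <- stats::predict(fit, features[!tr, , drop = FALSE])
            wt <- unname(w[as.character(y[!tr])])
            wrong <- wrong + sum(wt * (pred != y[!tr]))
            tot <- tot + sum(wt)
        }
        wrong / tot
    }, numeric(1))
    names(cvErr) <- treeGrid
    best <- treeGrid[which.min(cvErr)]   # which.min takes the first minimum

    set.seed(.subSeed(seed, 2L))
    fit <- randomForest::randomForest(
        x = features, y = y, ntree = best, classwt = w, strata = y,
        sampsize = as.vector(table(y)), importance = TRUE)
    imp <- randomForest::importance(fit, type = 1)[, 1]
    new("ForestModel", fit = fit, nTrees = as.integer(best),
        cvError = unname(cvErr[as.character(best)]), cvErrors = cvErr,
        importance = imp, featureNames = colnames(features),
        classWeights = w)
}

#' Score a held-out cohort
#'
#' Applies a fitted [ForestModel-class] to new samples without any
#' refitting, returning the forest's case-class probability (the fraction
#' of trees voting case). The feature schema must match the training schema
#' exactly.
#'
#' @param model a [ForestModel-class].
#' @param features samples x features matrix of the held-out cohort.
#' @return Numeric vector of case probabilities in [0, 1], named by sample.
#' @export
predictScores <- function(model, features) {
    stopifnot(is(model, "ForestModel"))
    features <- as.matrix(features)
    if (nrow(features) == 0)
        return(stats::setNames(numeric(0), character(0)))
    missing <- setdiff(model@featureNames, colnames(features))
    extra <- setdiff(colnames(features), model@featureNames)
    if (length(missing) || length(extra))
        stop("feature schema mismatch; missing: [",
             paste(missing, collapse = ", "), "], extra: [",
             paste(extra, collapse = ", "), "]")
    features <- features[, model@featureNames, drop = FALSE]
    prob <- stats::predict(model@fit, features, type = "prob")
    stats::setNames(prob[, "case"], rownames(features))
}

#' Empirical ROC curve and AUC
#'
#' Computes the AUC as the Mann-Whitney rank statistic `U / (n_case *
#' n_control)` with ties counted 0.5 — the probability that a random case
#' scores above a random control — and the ROC curve from all distinct
#' score thresholds. No smoothing is applied.
#'
#' @param scores numeric case-probability scores.
#' @param labels two-level labels (second level / `TRUE` = case).
#' @return A [RocResult-class] (CI slots are `NA`; see [bootstrapCi()]).
#' @examples
#' rocAuc(c(0.9, 0.8, 0.7, 0.85), c(TRUE, TRUE, FALSE, FALSE))
#' @export
rocAuc <- function(scores, labels) {
    y <- .asGroups(labels)
    if (any(table(y) == 0)) stop("both classes must be present")
    case <- y == levels(y)[2]
    new("RocResult", fpr = .rocCurve(scores, case)$fpr,
        tpr = .rocCurve(scores, case)$tpr,
        auc = .aucRank(scores, case),
        ciLow = NA_real_, ciHigh = NA_real_, nBootstrap = 0L,
        seed = NA_integer_)
}

.aucRank <- function(scores, case) {
    n1 <- sum(case); n0 <- sum(!case)
    r <- rank(scores)
    (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.rocCurve <- function(scores, case) {
    thr <- sort(unique(scores), decreasing = TRUE)
    tpr <- vapply(thr, function(t) mean(scores[case] >= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(scores[!case] >= t), numeric(1))
    list(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Stratified-bootstrap confidence interval for the AUC
#'
#' Resamples cases and controls separately with replacement (class sizes
#' preserved), recomputes the AUC on each resample, and reports the 2.5/97.5
#' percentile interval. Stratification guarantees both classes are present
#' in every resample. Deterministic given `seed`.
#'
#' @inheritParams rocAuc
#' @param nBootstrap number of resamples (default 500).
#' @param seed integer seed.
#' @return A [RocResult-class] with the full-data AUC/curve and the CI.
#' @export
bootstrapCi <- function(scores, labels, nBootstrap = 500, seed = 1L) {
    y <- .asGroups(labels)
    if (any(table(y) < 2)) stop("both classes need at least 2 samples")
    case <- y == levels(y)[2]
    iCase <- which(case); iCtrl <- which(!case)
    set.seed(seed)
    aucs <- vapply(seq_len(nBootstrap), function(b) {
        sc <- c(scores[iCase[sample.int(length(iCase), replace = TRUE)]],
                scores[iCtrl[sample.int(length(iCtrl), replace = TRUE)]])
        cs <- rep(c(TRUE, FALSE), c(length(iCase), length(iCtrl)))
        .aucRank(sc, cs)
    }, numeric(1))
    ci <- stats::quantile(aucs, c(0.025, 0.975), names = FALSE)
    point <- .aucRank(scores, case)
    curve <- .rocCurve(scores, case)
    new("RocResult", fpr = curve$fpr, tpr = curve$tpr, auc = point,
        ciLow = min(ci[1], point), ciHigh = max(ci[2], point),
        nBootstrap = as.integer(nBootstrap), seed = as.integer(seed))
}

#' Train and evaluate a signature / protein-panel / combined classifier
#'
#' Assembles the requested feature set from a training cohort, fits the
#' tuned random forest on it, and scores a held-out cohort:
#' `"snc_only"` uses the normalized expression of the signature features;
#' `"pirna_only"` restricts the signature to its piRNA members (the design
#' used for MCI-conversion prediction); `"protein_only"` uses pTau and the
#' Abeta42/40 ratio; `"combined"` concatenates signature and panel. The
#' training cohort must carry a trainable role and the held-out cohort is
#' only ever scored (leakage guard).
#'
#' @param train,test [SncExperiment-class] cohorts with `"normalized"`
#'   assays; `test`'s features must include the signature.
#' @param signature a [Signature-class] (not needed for `"protein_only"`).
#' @param mode one of `"snc_only"`, `"pirna_only"`, `"protein_only"`,
#'   `"combined"`.
#' @param nBootstrap,seed evaluation settings, see [bootstrapCi()].
#' @param ... passed to [tuneAndTrain()].
#' @return list(model = [ForestModel-class], roc = [RocResult-class],
#'   scores = held-out case probabilities).
#' @export
combinedModel <- function(train, test, signature = NULL,
                          mode = c("snc_only", "pirna_only", "protein_only",
                                   "combined"),
                          nBootstrap = 500, seed = 1L, ...) {
    mode <- match.arg(mode)
    stopifnot(is(train, "SncExperiment"), is(test, "SncExperiment"))
    .assertTrainable(train, "model training")
    Xtr <- .assembleFeatures(train, signature, mode)
    Xte <- .assembleFeatures(test, signature, mode)
    model <- tuneAndTrain(Xtr, .seGroups(train), seed = seed, ...)
    scores <- predictScores(model, Xte)
    roc <- bootstrapCi(scores, .seGroups(test), nBootstrap = nBootstrap,
                       seed = .subSeed(seed, 3L))
    list(model = model, roc = roc, scores = scores)
}

#' @describeIn combinedModel derive the Abeta42/40 ratio from a sample
#'   table; errors unless Abeta40 is positive throughout.
#' @param samples data.frame/DataFrame with `Abeta42` and `Abeta40` columns.
#' @export
abetaRatio <- function(samples) {
    samples <- as.data.frame(samples)
    if (!all(c("Abeta42", "Abeta40") %in% colnames(samples)))
        stop("Abeta42 and Abeta40 columns are required")
    if (any(!is.finite(samples$Abeta40)) || any(samples$Abeta40 <= 0))
        stop("Abeta40 must be positive to form the Abeta42/40 ratio")
    samples$Abeta42 / samples$Abeta40
}

.assembleFeatures <- function(x, signature, mode) {
    parts <- list()
    if (mode %in% c("snc_only", "pirna_only", "combined")) {
        if (is.null(signature)) stop("a signature is required for mode ",
                                     mode)
        ids <- signatureFeatures(signature)
        if (mode == "pirna_only") {
            ids <- ids[signature@kind == "piRNA"]
            if (!length(ids)) stop("signature contains no piRNA features")
        }
        miss <- setdiff(ids, rownames(x))
        if (length(miss))
            stop("cohort lacks signature feature(s): ",
                 paste(miss, collapse = ", "))
        parts$snc <- t(normalizedValues(x)[ids, , drop = FALSE])
    }
    if (mode %in% c("protein_only", "combined")) {
        cd <- as.data.frame(colData(x))
        if (!"pTau" %in% colnames(cd))
            stop("pTau is missing from the sample table")
        bad <- rownames(cd)[!stats::complete.cases(
            cd[, intersect(c("pTau", "Abeta42", "Abeta40"), colnames(cd))])]
        if (length(bad))
            stop("incomplete biomarker panel for sample(s): ",
                 paste(bad, collapse = ", "))
        parts$panel <- cbind(pTau = cd$pTau, ab42_40_ratio = abetaRatio(cd))
        rownames(parts$panel) <- rownames(cd)
    }
    do.call(cbind, parts)
}

#' Correlate signature expression with the protein biomarker panel
#'
#' Pairwise Pearson correlations (with two-sided t-test p-values) between
#' the normalized expression of the signature features, pTau and the
#' Abeta42/40 ratio. Zero-variance variables yield `NA` with a warning.
#'
#' @param x an [SncExperiment-class] with normalized values and a complete
#'   biomarker panel.
#' @param signature a [Signature-class].
#' @return list(r = correlation matrix, p = p-value matrix, n = sample
#'   count).
#' @importFrom stats cor.test
#' @export
correlateSignatureWithPanel <- function(x, signature) {
    stopifnot(is(x, "SncExperiment"), is(signature, "Signature"))
    ids <- signatureFeatures(signature)
    M <- cbind(t(normalizedValues(x)[ids, , drop = FALSE]),
               pTau = colData(x)$pTau,
               ab42_40_ratio = abetaRatio(colData(x)))
    if (nrow(M) < 3) stop("at least 3 samples required")
    p <- ncol(M)
    r <- matrix(NA_real_, p, p, dimnames = list(colnames(M), colnames(M)))
    pv <- r
    zeroVar <- apply(M, 2, stats::sd) == 0
    if (any(zeroVar))
        warning("zero-variance variable(s): ",
                paste(colnames(M)[zeroVar], collapse = ", "))
    for (i in seq_len(p)) for (j in seq_len(p)) {
        if (zeroVar[i] || zeroVar[j]) next
        if (i == j) { r[i, j] <- 1; pv[i, j] <- 0; next }
        ct <- stats::cor.test(M[, i], M[, j])
        r[i, j] <- unname(ct$estimate)
        pv[i, j] <- ct$p.value
    }
    list(r = r, p = pv, n = nrow(M))
}
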