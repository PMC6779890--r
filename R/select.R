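#' Measure-of-relevance (MoR) discrimination scores
#'
#' Scores each feature's case/control discrimination independently of all
#' others as the Welch-standardized absolute mean difference:
#' `|mean_case - mean_ctrl| / max(eps, sqrt(s2_case/n_case + s2_ctrl/n_ctrl))`
#' with `eps = 1e-8`. The score is invariant under common affine rescaling
#' of the matrix and is zero when group means coincide.
#'
#' @param x a numeric matrix (features x samples) or an
#'   [SncExperiment-class] with a `"normalized"` assay.
#' @param groups two-level labels (second level = case); for an
#'   `SncExperiment` defaults to the diagnosis column.
#' @return Named numeric vector of nonnegative scores.
#' @examples
#' m <- rbind(f1 = c(1, 2, 3, 4, 5, 6))
#' colnames(m) <- paste0("s", 1:6)
#' morScores(m, c("a", "a", "a", "b", "b", "b"))
#' @export
setGeneric("morScores", function(x, groups = NULL)
    standardGeneric("morScores"))

#' @rdname morScores
#' @export
setMethod("morScores", "matrix", function(x, groups = NULL) {
    groups <- .asGroups(groups)
    if (length(unique(groups)) < 2) stop("labels are constant")
    G <- matrix(as.numeric(groups == levels(groups)[2]), ncol = 1)
    drop(.morScoreMat(x, G))
})

#' @rdname morScores
#' @export
setMethod("morScores", "SncExperiment", function(x, groups = NULL) {
    groups <- if (is.null(groups)) .seGroups(x) else .asGroups(groups)
    morScores(normalizedValues(x), groups)
})

#' MoR critical value from a label-permutation null
#'
#' Estimates the critical MoR cutoff (the "dotted red line") as the
#' `1 - alpha` empirical quantile of the pooled per-feature score null
#' obtained by recomputing all scores under case/control label permutations.
#' When the number of distinct label arrangements `C(n, n_case)` does not
#' exceed 10,000 the null is enumerated exhaustively; otherwise
#' `nPermutations` random label permutations are drawn. A feature passes iff
#' its observed score lies strictly above the critical value.
#'
#' @inheritParams morScores
#' @param nPermutations number of random permutations when enumeration is
#'   infeasible.
#' @param alpha tail probability of the null retained above the cutoff.
#' @param seed integer seed (random-permutation path only).
#' @return A [RelevanceRanking-class].
#' @export
setGeneric("morCriticalValue",
           function(x, groups = NULL, nPermutations = 1000, alpha = 0.05,
                    seed = 1L)
               standardGeneric("morCriticalValue"))

#' @rdname morCriticalValue
#' @export
setMethod("morCriticalValue", "matrix",
          function(x, groups = NULL, nPermutations = 1000, alpha = 0.05,
                   seed = 1L) {
    groups <- .asGroups(groups)
    kind <- rep(NA_character_, nrow(x))
    .morCriticalCore(x, groups, kind, nPermutations, alpha, seed)
})

#' @rdname morCriticalValue
#' @export
setMethod("morCriticalValue", "SncExperiment",
          function(x, groups = NULL, nPermutations = 1000, alpha = 0.05,
                   seed = 1L) {
    groups <- if (is.null(groups)) .seGroups(x) else .asGroups(groups)
    .morCriticalCore(normalizedValues(x), groups,
                     unname(featureKind(x)), nPermutations, alpha, seed)
})

.morCriticalCore <- function(X, groups, kind, nPermutations, alpha, seed) {
    n <- length(groups)
    n1 <- sum(groups == levels(groups)[2])
    if (choose(n, n1) < 2)
        stop("too few samples to permute: only one distinct arrangement")
    obs <- morScores(X, groups)
    G <- .enumerateArrangements(n, n1)
    exhaustive <- !is.null(G)
    if (!exhaustive) {
        set.seed(seed)
        G <- .randomArrangements(groups, nPermutations)
    }
    null <- as.vector(.morScoreMat(X, G))
    crit <- .nullQuantile(null, alpha)
    ids <- if (!is.null(rownames(X))) rownames(X) else
        sprintf("f%04d", seq_len(nrow(X)))
    tab <- DataFrame(feature_id = ids, kind = kind, mor = unname(obs),
                     passes = unname(obs > crit))
    new("RelevanceRanking", table = tab, criticalValue = crit,
        nPermutations = ncol(G), exhaustive = exhaustive, alpha = alpha)
}

#' Reliability analysis: bootstrap stability of the MoR selection
#'
#' Validates the permutation-calibrated relevance selection by stratified
#' bootstrap: each resample redraws samples within class (class sizes
#' preserved), re-estimates the critical value on the resampled matrix, and
#' records which features pass. A feature's selection frequency is the
#' fraction of resamples in which it passes; the surviving set contains the
#' features that passed on the full data *and* reach the stability
#' threshold.
#'
#' @inheritParams morCriticalValue
#' @param ranking the full-data [RelevanceRanking-class]; computed when
#'   omitted.
#' @param nResamples number of stratified bootstrap resamples (>= 10).
#' @param stabilityThreshold minimum selection frequency (default 0.8).
#' @param nPermutations permutations per resample for the re-estimated
#'   critical value.
#' @return list(report = [StabilityReport-class], survivors = character,
#'   ranking = the full-data ranking).
#' @export
setGeneric("reliabilityAnalysis",
           function(x, groups = NULL, ranking = NULL, nResamples = 100,
                    stabilityThreshold = 0.8, nPermutations = 200,
                    alpha = 0.05, seed = 1L)
               standardGeneric("reliabilityAnalysis"))

#' @rdname reliabilityAnalysis
#' @export
setMethod("reliabilityAnalysis", "matrix",
          function(x, groups = NULL, ranking = NULL, nResamples = 100,
                   stabilityThreshold = 0.8, nPermutations = 200,
                   alpha = 0.05, seed = 1L) {
    groups <- .asGroups(groups)
    .riaCore(x, groups, ranking, nResamples, stabilityThreshold,
             nPermutations, alpha, seed)
})

#' @rdname reliabilityAnalysis
#' @export
setMethod("reliabilityAnalysis", "SncExperiment",
          function(x, groups = NULL, ranking = NULL, nResamples = 100,
                   stabilityThreshold = 0.8, nPermutations = 200,
                   alpha = 0.05, seed = 1L) {
    groups <- if (is.null(groups)) .seGroups(x) else .asGroups(groups)
    .riaCore(normalizedValues(x), groups, ranking, nResamples,
             stabilityThreshold, nPermutations, alpha, seed)
})

.riaCore <- function(X, groups, ranking, nResamples, stabilityThreshold,
                     nPermutations, alpha, seed) {
    if (nResamples < 10) stop("nResamples must be >= 10")
    if (is.null(ranking))
        ranking <- morCriticalValue(X, groups,
                                    nPermutations = nPermutations,
                                    alpha = alpha, seed = seed)
    set.seed(.subSeed(seed, 11L))
    hits <- numeric(nrow(X))
    for (b in seq_len(nResamples)) {
        idx <- .stratifiedResample(groups)
        Xb <- X[, idx, drop = FALSE]
        gb <- groups[idx]
        obs <- morScores(Xb, gb)
        Gb <- .randomArrangements(gb, nPermutations)
        critB <- .nullQuantile(as.vector(.morScoreMat(Xb, Gb)), alpha)
        hits <- hits + (obs > critB)
    }
    freq <- hits / nResamples
    ids <- ranking@table$feature_id
    stable <- freq >= stabilityThreshold
    tab <- DataFrame(feature_id = ids, selection_frequency = freq,
                     stable = stable)
    survivors <- ids[ranking@table$passes & stable]
    list(report = new("StabilityReport", table = tab,
                      nResamples = as.integer(nResamples),
                      stabilityThreshold = stabilityThreshold),
         survivors = survivors, ranking = ranking)
}

#' Mutual-information feature ranking with a permutation null
#'
#' Ranks features by the plug-in mutual information (in bits) between their
#' equal-frequency-binned expression and the class label, keeping a feature
#' iff its MI exceeds the 95th percentile of its own label-permutation null.
#' Equal-frequency bin edges are the `nBins + 1` quantiles of the feature
#' (deduplicated, so heavily tied features may use fewer effective bins).
#' Rank ties are broken by MoR score (when given), then lexicographic ID.
#'
#' @inheritParams morScores
#' @param nBins number of expression bins (>= 2, default 3).
#' @param nullPermutations label permutations per feature for the null.
#' @param morScores optional named score vector for tie-breaking.
#' @param seed integer seed.
#' @return An [InfoRanking-class]; kept features are the surviving subset.
#' @export
setGeneric("infoRank",
           function(x, groups = NULL, nBins = 3, nullPermutations = 200,
                    morScores = NULL, seed = 1L)
               standardGeneric("infoRank"))

#' @rdname infoRank
#' @export
setMethod("infoRank", "matrix",
          function(x, groups = NULL, nBins = 3, nullPermutations = 200,
                   morScores = NULL, seed = 1L) {
    groups <- .asGroups(groups)
    .infoRankCore(x, groups, nBins, nullPermutations, morScores, seed)
})

#' @rdname infoRank
#' @export
setMethod("infoRank", "SncExperiment",
          function(x, groups = NULL, nBins = 3, nullPermutations = 200,
                   morScores = NULL, seed = 1L) {
    groups <- if (is.null(groups)) .seGroups(x) else .asGroups(groups)
    .infoRankCore(normalizedValues(x), groups, nBins, nullPermutations,
                  morScores, seed)
})

## plug-in MI (bits) between an integer bin assignment and the class label
.miBits <- function(bins, y) {
    tab <- table(bins, y)
    n <- sum(tab)
    p <- tab / n
    pr <- rowSums(p); pc <- colSums(p)
    e <- outer(pr, pc)
    nz <- p > 0
    sum(p[nz] * log2(p[nz] / e[nz]))
}

.equalFreqBins <- function(v, nBins) {
    br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = nBins + 1),
                                 names = FALSE))
    if (length(br) < 2) return(rep(1L, length(v)))
    findInterval(v, br[-c(1, length(br))]) + 1L
}

.infoRankCore <- function(X, groups, nBins, nullPermutations, morScores,
                          seed) {
    if (nrow(X) == 0) stop("no features to rank")
    if (nBins < 2) stop("nBins must be >= 2")
    set.seed(.subSeed(seed, 21L))
    n <- ncol(X)
    perms <- replicate(nullPermutations, sample.int(n))
    mi <- numeric(nrow(X))
    cutoff <- numeric(nrow(X))
    for (f in seq_len(nrow(X))) {
        bins <- .equalFreqBins(X[f, ], nBins)
        mi[f] <- .miBits(bins, groups)
        null <- vapply(seq_len(nullPermutations),
                       function(p) .miBits(bins, groups[perms[, p]]),
                       numeric(1))
        cutoff[f] <- .nullQuantile(null, 0.05)
    }
    ids <- if (!is.null(rownames(X))) rownames(X) else
        sprintf("f%04d", seq_len(nrow(X)))
    tie <- if (!is.null(morScores)) unname(morScores[ids]) else
        numeric(length(ids))
    ord <- order(-mi, -tie, ids)
    rank <- integer(length(ids)); rank[ord] <- seq_along(ids)
    tab <- DataFrame(feature_id = ids, mutual_information = mi,
                     null_cutoff = cutoff, rank = rank,
                     kept = mi > cutoff)
    new("InfoRanking", table = tab, nBins = as.integer(nBins),
        nullPermutations = as.integer(nullPermutations))
}

#' Confound filter: covariate-adjusted group effect per feature
#'
#' For each feature fits `value ~ group + age + sex` and tests the group
#' effect by the partial F-test against the covariate-only model, so a
#' feature whose apparent discrimination is explained by age or sex loses
#' its group effect after adjustment. P-values are Bonferroni-corrected
#' across the tested features and a feature is retained iff the corrected
#' p-value is at most `alpha`. Pillai's trace from the joint multivariate
#' fit over the retained set is reported as an omnibus diagnostic. Constant
#' covariates are dropped, in which case the test reduces to the one-way
#' ANOVA on group.
#'
#' @inheritParams morScores
#' @param age numeric years per sample; `SncExperiment` methods default to
#'   `colData(x)$age`.
#' @param sex per-sample factor (e.g. F/M); defaults to `colData(x)$sex`.
#' @param alpha Bonferroni-corrected significance level (default 0.05).
#' @param morScores optional named score vector used to order the signature.
#' @param mTests size of the Bonferroni family (default: the number of
#'   features in `x`). When the tested features were pre-selected from a
#'   larger screen, pass the full screen size so the familywise error rate
#'   refers to the whole experiment.
#' @return list(report = [ConfoundReport-class],
#'   signature = [Signature-class] or NULL when nothing is retained).
#' @importFrom stats lm anova manova
#' @export
setGeneric("mancovaFilter",
           function(x, groups = NULL, age = NULL, sex = NULL, alpha = 0.05,
                    morScores = NULL, kind = NULL, mTests = NULL)
               standardGeneric("mancovaFilter"))

#' @rdname mancovaFilter
#' @param kind optional per-feature kind vector (named by feature ID).
#' @export
setMethod("mancovaFilter", "matrix",
          function(x, groups = NULL, age = NULL, sex = NULL, alpha = 0.05,
                   morScores = NULL, kind = NULL, mTests = NULL) {
    groups <- .asGroups(groups)
    .mancovaCore(x, groups, age, sex, alpha, morScores, kind, mTests)
})

#' @rdname mancovaFilter
#' @export
setMethod("mancovaFilter", "SncExperiment",
          function(x, groups = NULL, age = NULL, sex = NULL, alpha = 0.05,
                   morScores = NULL, kind = NULL, mTests = NULL) {
    groups <- if (is.null(groups)) .seGroups(x) else .asGroups(groups)
    if (is.null(age)) age <- colData(x)$age
    if (is.null(sex)) sex <- colData(x)$sex
    if (is.null(kind)) kind <- featureKind(x)
    .mancovaCore(normalizedValues(x), groups, age, sex, alpha, morScores,
                 kind, mTests)
})

.mancovaCore <- function(X, groups, age, sex, alpha, morScores, kind,
                         mTests = NULL) {
    if (is.null(mTests)) mTests <- nrow(X)
    if (mTests < nrow(X)) stop("mTests must be >= the number of features")
    if (is.null(age) || is.null(sex))
        stop("age and sex are required for every sample")
    if (anyNA(age) || anyNA(sex))
        stop("age and sex must be complete")
    covars <- list(age = as.numeric(age), sex = factor(sex))
    covars <- covars[vapply(covars,
                            function(v) length(unique(v)) > 1, logical(1))]
    dat <- data.frame(group = groups)
    for (nm in names(covars)) dat[[nm]] <- covars[[nm]]
    mmFull <- stats::model.matrix(~ ., data = dat)
    if (qr(mmFull)$rank < ncol(mmFull))
        stop("singular design: group is collinear with the covariates ",
             "(check sex/age balance)")
    fullForm <- stats::as.formula(
        paste("y ~", paste(c("group", names(covars)), collapse = " + ")))
    redForm <- stats::as.formula(
        if (length(covars))
            paste("y ~", paste(names(covars), collapse = " + "))
        else "y ~ 1")
    ids <- if (!is.null(rownames(X))) rownames(X) else
        sprintf("f%04d", seq_len(nrow(X)))
    p <- vapply(seq_len(nrow(X)), function(f) {
        d <- dat
        d$y <- X[f, ]
        full <- stats::lm(fullForm, data = d)
        red <- stats::lm(redForm, data = d)
        stats::anova(red, full)[2, "Pr(>F)"]
    }, numeric(1))
    pAdj <- pmin(1, p * mTests)
    retained <- pAdj <= alpha
    dir <- ifelse(
        rowMeans(X[, groups == levels(groups)[2], drop = FALSE]) >=
        rowMeans(X[, groups == levels(groups)[1], drop = FALSE]),
        "up", "down")
    pillai <- c(statistic = NA_real_, p.value = NA_real_)
    if (sum(retained) >= 1 && ncol(X) > sum(retained) + length(covars) + 2) {
        fit <- try(suppressWarnings({
            mvDat <- dat
            mvDat$y <- t(X[retained, , drop = FALSE])
            mv <- stats::manova(
                stats::as.formula(paste(
                    "y ~", paste(c("group", names(covars)),
                                 collapse = " + "))),
                data = mvDat)
            summary(mv, test = "Pillai")$stats
        }), silent = TRUE)
        if (!inherits(fit, "try-error") && "group" %in% rownames(fit))
            pillai <- c(statistic = fit["group", "Pillai"],
                        p.value = fit["group", "Pr(>F)"])
    }
    tab <- DataFrame(feature_id = ids, p_group = p, p_adjusted = pAdj,
                     retained = retained, direction = unname(dir))
    report <- new("ConfoundReport", table = tab, alpha = alpha,
                  pillai = pillai)
    signature <- NULL
    if (any(retained)) {
        keep <- ids[retained]
        ord <- if (!is.null(morScores))
            order(-morScores[keep], keep) else order(pAdj[retained], keep)
        keep <- keep[ord]
        kv <- if (!is.null(kind)) unname(kind[keep]) else
            ifelse(grepl("^piR", keep), "piRNA", "miRNA")
        signature <- new("Signature", featureIds = keep, kind = kv,
                         direction = unname(dir[keep]))
    }
    list(report = report, signature = signature)
}

#' Run the three-iteration signature selection
#'
#' Chains the full feature-selection procedure on a training cohort:
#' Iteration 1 identifies discriminative features by the permutation-
#' calibrated MoR cutoff and validates them by bootstrap reliability
#' analysis; Iteration 2 retains those whose mutual information with the
#' class exceeds a per-feature permutation null; Iteration 3 removes
#' features whose group effect does not survive age/sex adjustment. Every
#' intermediate set is logged in the audit trail, and the whole procedure is
#' deterministic given `seed`. Cohorts carrying a held-out role are refused
#' (leakage guard).
#'
#' @param x a preprocessed [SncExperiment-class] (`"normalized"` assay
#'   present) with role `"signature_train"` or `"unassigned"`.
#' @param groups optional two-level labels; defaults to diagnosis.
#' @param nPermutations,alpha MoR null settings (Iteration 1).
#' @param nResamples,stabilityThreshold reliability analysis settings.
#' @param nBins,nullPermutations information-ranking settings (Iteration 2).
#' @param seed master seed; each stage draws from a derived stream.
#' @return list with `signature` ([Signature-class]), `ranking`,
#'   `stability`, `info`, `confound` (the per-stage result objects) and
#'   `audit` (data.frame of stage survivor counts).
#' @examples
#' \donttest{
#' se <- simulateStudy(simulationConfig(seed = 3), role = "signature_train")
#' se <- preprocess(se)
#' sel <- runSelection(se, seed = 3)
#' sel$audit
#' }
#' @export
runSelection <- function(x, groups = NULL, nPermutations = 1000,
                         alpha = 0.05, nResamples = 100,
                         stabilityThreshold = 0.8, nBins = 3,
                         nullPermutations = 200, seed = 1L) {
    stopifnot(is(x, "SncExperiment"))
    .assertTrainable(x, "signature selection")
    groups <- if (is.null(groups)) .seGroups(x) else .asGroups(groups)
    Y <- normalizedValues(x)
    kind <- featureKind(x)

    ranking <- morCriticalValue(Y, groups, nPermutations = nPermutations,
                                alpha = alpha, seed = .subSeed(seed, 1L))
    ranking@table$kind <- unname(kind[ranking@table$feature_id])
    if (!any(ranking@table$passes))
        stop("selection failed at Iteration 1 (MoR): no feature exceeds ",
             "the critical value")
    ria <- reliabilityAnalysis(Y, groups, ranking = ranking,
                               nResamples = nResamples,
                               stabilityThreshold = stabilityThreshold,
                               nPermutations = min(nPermutations, 200),
                               alpha = alpha, seed = .subSeed(seed, 2L))
    it1 <- ria$survivors
    if (!length(it1))
        stop("selection failed at Iteration 1 (reliability analysis): ",
             "no stable feature")

    mor <- morScores(Y, groups)
    info <- infoRank(Y[it1, , drop = FALSE], groups, nBins = nBins,
                     nullPermutations = nullPermutations,
                     morScores = mor[it1], seed = .subSeed(seed, 3L))
    it2 <- info@table$feature_id[info@table$kept]
    if (!length(it2))
        stop("selection failed at Iteration 2 (information ranking): ",
             "no feature beats its permutation null")

    ## Bonferroni family = every expressed feature that entered the screen,
    ## not just the survivors of Iterations 1-2: correcting only across the
    ## data-selected extremes would leave the familywise error uncontrolled.
    mc <- mancovaFilter(Y[it2, , drop = FALSE], groups,
                        age = colData(x)$age, sex = colData(x)$sex,
                        alpha = alpha, morScores = mor[it2],
                        kind = kind[it2], mTests = nrow(Y))
    if (is.null(mc$signature))
        stop("selection failed at Iteration 3 (confound filter): ",
             "no feature survives age/sex adjustment")

    audit <- data.frame(
        stage = c("input", "it1_mor", "it1_ria", "it2_info", "it3_mancova"),
        n_features = c(nrow(Y), sum(ranking@table$passes), length(it1),
                       length(it2), length(mc$signature@featureIds)))
    list(signature = mc$signature, ranking = ranking,
         stability = ria$report, info = info, confound = mc$report,
         audit = audit)
}
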