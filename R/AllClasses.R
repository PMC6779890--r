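#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
NULL

.COHORT_ROLES <- c("unassigned", "signature_train", "replication_test",
                   "mci_test", "external_test")

.FEATURE_KINDS <- c("miRNA", "piRNA")

#' SncExperiment: a small-RNA cohort container
#'
#' `SncExperiment` extends [SummarizedExperiment::SummarizedExperiment] to hold
#' a small-noncoding-RNA count matrix (features x samples) together with the
#' per-sample clinical table and two pieces of pipeline bookkeeping: the cohort
#' `role` (which enforces the train/test separation: cohorts with a `*_test`
#' role are refused by every fitting operation) and a `provenance` log of the
#' transformations applied so far.
#'
#' Assays: `"counts"` (raw nonnegative integers) and, after
#' [vsnTransform()], `"normalized"` (glog2 scale). `rowData(x)$kind` tags each
#' feature as `"miRNA"` or `"piRNA"`; `colData(x)` carries `diagnosis`
#' (control / AD / MCI_stable / MCI_converter), `batch`, `age`, `sex` and,
#' optionally, the CSF protein biomarkers `pTau`, `Abeta42`, `Abeta40` (pg/ml).
#'
#' @slot role character(1), one of `"unassigned"`, `"signature_train"`,
#'   `"replication_test"`, `"mci_test"`, `"external_test"`. Immutable after
#'   construction.
#' @slot provenance character vector, one entry per transformation applied.
#'
#' @seealso [SncExperiment()] for construction, [cohortRole()],
#'   [featureKind()], [provenance()].
#' @aliases SncExperiment-class
#' @exportClass SncExperiment
setClass("SncExperiment",
         contains = "SummarizedExperiment",
         representation(role = "character", provenance = "character"),
         prototype(role = "unassigned", provenance = character()))

setValidity("SncExperiment", function(object) {
    msg <- NULL
    if (length(object@role) != 1L || !object@role %in% .COHORT_ROLES)
        msg <- c(msg, paste0("role must be one of: ",
                             paste(.COHORT_ROLES, collapse = ", ")))
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "an assay named 'counts' is required")
    else {
        cts <- assay(object, "counts")
        if (anyNA(cts) || any(cts < 0))
            msg <- c(msg, "counts must be nonnegative and non-missing")
        else if (any(cts != round(cts)))
            msg <- c(msg, "counts must be integers")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate feature IDs")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample IDs")
    if (!"kind" %in% colnames(rowData(object)))
        msg <- c(msg, "rowData must contain a 'kind' column")
    if ("age" %in% colnames(colData(object))) {
        age <- colData(object)$age
        if (any(!is.na(age) & age <= 0))
            msg <- c(msg, "age must be positive where present")
    }
    if (is.null(msg)) TRUE else msg
})

#' Per-feature relevance ranking with a permutation critical value
#'
#' Result of [morCriticalValue()]: each feature's measure-of-relevance (MoR)
#' score (a Welch-standardized absolute group-mean difference) together with
#' the critical cutoff estimated from the pooled label-permutation null.
#' Features whose score lies strictly above the cutoff pass.
#'
#' @slot table `DataFrame` with columns `feature_id`, `kind`, `mor`, `passes`.
#' @slot criticalValue numeric(1), the (1 - alpha) quantile of the pooled null.
#' @slot nPermutations integer(1); number of label arrangements scored (equal
#'   to the full enumeration count when exhaustive).
#' @slot exhaustive logical(1); whether all label arrangements were enumerated.
#' @slot alpha numeric(1).
#' @aliases RelevanceRanking-class
#' @exportClass RelevanceRanking
setClass("RelevanceRanking",
         representation(table = "DataFrame", criticalValue = "numeric",
                        nPermutations = "integer", exhaustive = "logical",
                        alpha = "numeric"))

setValidity("RelevanceRanking", function(object) {
    tab <- object@table
    msg <- NULL
    if (!all(c("feature_id", "mor", "passes") %in% colnames(tab)))
        msg <- c(msg, "table needs feature_id, mor, passes columns")
    else {
        if (any(tab$mor < 0)) msg <- c(msg, "mor scores must be nonnegative")
        if (!identical(as.logical(tab$passes),
                       as.logical(tab$mor > object@criticalValue)))
            msg <- c(msg, "passes must equal mor > criticalValue")
    }
    if (object@criticalValue < 0) msg <- c(msg, "criticalValue must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' Bootstrap stability report for the relevance selection
#'
#' Result of [reliabilityAnalysis()]: per-feature selection frequency across
#' stratified bootstrap resamples, each resample re-running the full
#' permutation-calibrated relevance selection.
#'
#' @slot table `DataFrame` with `feature_id`, `selection_frequency`, `stable`.
#' @slot nResamples integer(1).
#' @slot stabilityThreshold numeric(1) in (0, 1].
#' @aliases StabilityReport-class
#' @exportClass StabilityReport
setClass("StabilityReport",
         representation(table = "DataFrame", nResamples = "integer",
                        stabilityThreshold = "numeric"))

#' Mutual-information feature ranking
#'
#' Result of [infoRank()]: plug-in mutual information (bits) between each
#' feature's equal-frequency-binned expression and the class label, a
#' per-feature permutation-null cutoff, and the resulting ranking.
#'
#' @slot table `DataFrame` with `feature_id`, `mutual_information`,
#'   `null_cutoff`, `rank`, `kept`.
#' @slot nBins integer(1).
#' @slot nullPermutations integer(1).
#' @aliases InfoRanking-class
#' @exportClass InfoRanking
setClass("InfoRanking",
         representation(table = "DataFrame", nBins = "integer",
                        nullPermutations = "integer"))

#' Covariate-confounding report
#'
#' Result of [mancovaFilter()]: per-feature ANCOVA of expression on group
#' adjusted for age and sex; the group partial-F p-value is Bonferroni
#' corrected across the tested features and a feature is retained iff the
#' corrected p-value stays at or below `alpha`. Pillai's trace from the joint
#' multivariate fit over retained features is reported as a diagnostic.
#'
#' @slot table `DataFrame` with `feature_id`, `p_group`, `p_adjusted`,
#'   `retained`, `direction`.
#' @slot alpha numeric(1).
#' @slot pillai named numeric: Pillai's trace statistic and its p-value
#'   (NA when the omnibus fit is not estimable).
#' @aliases ConfoundReport-class
#' @exportClass ConfoundReport
setClass("ConfoundReport",
         representation(table = "DataFrame", alpha = "numeric",
                        pillai = "numeric"))

#' An sncRNA biomarker signature
#'
#' The ordered set of selected features with their kind (miRNA/piRNA) and
#' effect direction (sign of the case-minus-control mean difference).
#'
#' @slot featureIds ordered character vector (most relevant first).
#' @slot kind character vector parallel to `featureIds`.
#' @slot direction character vector, `"up"` or `"down"` in cases.
#' @aliases Signature-class
#' @exportClass Signature
setClass("Signature",
         representation(featureIds = "character", kind = "character",
                        direction = "character"))

setValidity("Signature", function(object) {
    msg <- NULL
    if (length(object@featureIds) == 0L)
        msg <- c(msg, "a Signature must contain at least one feature")
    if (anyDuplicated(object@featureIds))
        msg <- c(msg, "duplicate feature IDs")
    if (length(object@kind) != length(object@featureIds) ||
        length(object@direction) != length(object@featureIds))
        msg <- c(msg, "kind and direction must parallel featureIds")
    if (!all(object@direction %in% c("up", "down")))
        msg <- c(msg, "direction must be 'up' or 'down'")
    if (is.null(msg)) TRUE else msg
})

#' A tuned random-forest classifier
#'
#' Result of [tuneAndTrain()]: the forest refit on the full training data with
#' the tree count chosen by stratified tenfold cross-validation of the
#' class-weighted error, plus the permutation variable importance.
#'
#' @slot fit the underlying `randomForest` object.
#' @slot nTrees integer(1), the selected ensemble size.
#' @slot cvError numeric(1), the weighted CV error at `nTrees`.
#' @slot cvErrors numeric vector named by tree-grid values.
#' @slot importance named numeric, mean decrease in permutation accuracy.
#' @slot featureNames character, the training feature schema.
#' @slot classWeights named numeric, e.g. c(control = 0.5, case = 1).
#' @aliases ForestModel-class
#' @exportClass ForestModel
setClass("ForestModel",
         representation(fit = "ANY", nTrees = "integer", cvError = "numeric",
                        cvErrors = "numeric", importance = "numeric",
                        featureNames = "character", classWeights = "numeric"))

#' ROC curve, AUC and stratified-bootstrap confidence interval
#'
#' @slot fpr,tpr numeric vectors; the empirical ROC curve from all distinct
#'   score thresholds, from (0,0) to (1,1).
#' @slot auc numeric(1), the Mann-Whitney AUC (ties count 0.5).
#' @slot ciLow,ciHigh numeric(1), percentile bootstrap 95% bounds (NA before
#'   [bootstrapCi()]).
#' @slot nBootstrap integer(1).
#' @slot seed integer(1) (NA when no bootstrap was run).
#' @aliases RocResult-class
#' @exportClass RocResult
setClass("RocResult",
         representation(fpr = "numeric", tpr = "numeric", auc = "numeric",
                        ciLow = "numeric", ciHigh = "numeric",
                        nBootstrap = "integer", seed = "integer"))

setValidity("RocResult", function(object) {
    msg <- NULL
    if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must be in [0,1]")
    if (is.unsorted(object@fpr) || is.unsorted(object@tpr))
        msg <- c(msg, "ROC curve must be monotone nondecreasing")
    if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
        (object@ciLow > object@auc || object@ciHigh < object@auc))
        msg <- c(msg, "ciLow <= auc <= ciHigh violated")
    if (is.null(msg)) TRUE else msg
})

#' Simulation settings for a synthetic sncRNA cohort study
#'
#' Defines the generative model used by [simulateStudy()]: negative-binomial
#' counts with lognormal library sizes, a log-normal baseline abundance
#' profile, planted differential features (log2 fold changes applied to the
#' case group), multiplicative per-(batch, feature) center effects, and
#' age-confounded decoy features whose expression follows a log-linear age
#' slope rather than the diagnosis. Defaults reproduce the study design the
#' package targets: a signature-identification cohort of 38 controls vs 23 AD
#' cases, ~200 features (miRNA + piRNA), three miRNA-like features increased
#' in cases and three piRNA-like features (two increased, one decreased).
#'
#' @slot nControl,nCase integer, cohort sizes (>= 2 each).
#' @slot nMirna,nPirna integer, features per kind.
#' @slot plantedEffects data.frame(feature_id, log2fc): differential truth.
#' @slot confoundedFeatures data.frame(feature_id, age_slope): log2 units per
#'   year of age; disjoint from plantedEffects.
#' @slot nbDispersion positive numeric; NB size parameter k in
#'   var = m + m^2/k.
#' @slot libsizeLogMean,libsizeLogSd lognormal library-size parameters
#'   (natural-log scale).
#' @slot baselineLogSd numeric, spread of baseline feature abundances
#'   (natural-log scale).
#' @slot nBatches integer >= 1; batchSd numeric >= 0, SD of the per
#'   (batch, feature) multiplicative effect in log2 units.
#' @slot ageRangeControl,ageRangeCase numeric(2), uniform age ranges (years);
#'   shifting them apart induces group-age confounding.
#' @slot sexRatio numeric in [0,1], fraction female.
#' @slot seed integer; governs subjects, noise and batch effects.
#' @slot baselineSeed integer; governs the population-level baseline
#'   abundance profile. Cohorts sharing `baselineSeed` (the default) are
#'   drawn from the same underlying sncRNA population even when `seed`
#'   differs, emulating independent cohorts of one study population.
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         representation(nControl = "integer", nCase = "integer",
                        nMirna = "integer", nPirna = "integer",
                        plantedEffects = "data.frame",
                        confoundedFeatures = "data.frame",
                        nbDispersion = "numeric",
                        libsizeLogMean = "numeric", libsizeLogSd = "numeric",
                        baselineLogSd = "numeric",
                        nBatches = "integer", batchSd = "numeric",
                        ageRangeControl = "numeric", ageRangeCase = "numeric",
                        sexRatio = "numeric", seed = "integer",
                        baselineSeed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- NULL
    if (object@nControl < 2L || object@nCase < 2L)
        msg <- c(msg, "nControl and nCase must each be >= 2")
    if (object@nMirna < 0L || object@nPirna < 0L ||
        object@nMirna + object@nPirna < 1L)
        msg <- c(msg, "at least one feature is required")
    if (object@nbDispersion <= 0)
        msg <- c(msg, "nbDispersion must be > 0")
    if (object@libsizeLogSd < 0) msg <- c(msg, "libsizeLogSd must be >= 0")
    if (object@nBatches < 1L) msg <- c(msg, "nBatches must be >= 1")
    if (object@batchSd < 0) msg <- c(msg, "batchSd must be >= 0")
    if (object@sexRatio < 0 || object@sexRatio > 1)
        msg <- c(msg, "sexRatio must be in [0,1]")
    pe <- object@plantedEffects; cf <- object@confoundedFeatures
    if (nrow(pe) && !all(c("feature_id", "log2fc") %in% colnames(pe)))
        msg <- c(msg, "plantedEffects needs feature_id and log2fc columns")
    if (nrow(cf) && !all(c("feature_id", "age_slope") %in% colnames(cf)))
        msg <- c(msg, "confoundedFeatures needs feature_id and age_slope")
    if (nrow(pe) && nrow(cf) &&
        length(intersect(pe$feature_id, cf$feature_id)))
        msg <- c(msg, "planted and confounded feature IDs must be disjoint")
    for (rg in list(object@ageRangeControl, object@ageRangeCase))
        if (length(rg) != 2L || rg[1] <= 0 || rg[2] < rg[1])
            msg <- c(msg, "age ranges must be positive (lo, hi) pairs")
    if (is.null(msg)) TRUE else msg
})
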