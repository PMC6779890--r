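#' Default pipeline configuration
#'
#' A nested list mirroring the YAML configuration schema accepted by
#' [runPipeline()]: a master `seed` (all stage randomness derives from it
#' through named substreams), per-stage parameter blocks, and a `cohorts`
#' block that either points at TSV files (`counts`, `samples` per cohort)
#' or requests simulation (`simulate: yes` with optional generator
#' overrides). The `train` cohort receives role `signature_train`, the
#' `test` cohort `replication_test`; the driver structurally refuses to
#' route a test-role cohort into selection or training.
#'
#' @param seed master seed.
#' @return A config list; editable or writable via [yaml::write_yaml].
#' @export
defaultPipelineConfig <- function(seed = 1L) {
    list(
        seed = as.integer(seed),
        cohorts = list(
            train = list(simulate = TRUE),
            test = list(simulate = TRUE)),
        preprocess = list(min_library_size = 50000, expr_threshold = 0.5,
                          expr_fraction = 0.95, ruv_k = 1, trim = 0.1),
        selection = list(alpha = 0.05, n_permutations = 1000,
                         n_resamples = 100, stability_threshold = 0.8,
                         n_bins = 3, null_permutations = 200),
        classify = list(mode = "snc_only", n_bootstrap = 500,
                        tree_grid = seq(100, 1000, 100), n_folds = 10))
}

#' Run the end-to-end discovery/validation pipeline
#'
#' Executes the full workflow under a single configuration: load or
#' simulate the training and held-out cohorts; preprocess both (sample
#' filter, variance-stabilizing normalization, removal of unwanted
#' variation; the expression filter is applied to the training cohort
#' only); run the three-iteration signature selection on the training
#' cohort; train the tuned random forest on the signature features and
#' score the untouched held-out cohort; evaluate by stratified-bootstrap
#' AUROC; and write the report. Reruns with the same configuration produce
#' byte-identical reports (artifacts are stamped with the configuration
#' hash and seed, never with timestamps).
#'
#' Report files: `signature.tsv`, `ranking.tsv`, `audit.tsv`, `roc.tsv`,
#' `auc.json` (auc, ci_low, ci_high, n_bootstrap), `importance.tsv`,
#' `correlation.tsv`, `provenance.txt`.
#'
#' @param config a config list (see [defaultPipelineConfig()]) or a YAML
#'   file path.
#' @param outDir report directory (created if needed).
#' @param train,test optional in-memory [SncExperiment-class] cohorts,
#'   overriding the `cohorts` block. `test` must carry a `*_test` role.
#' @return Invisibly, list(signature, selection, model, roc, report_dir).
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir,
                        train = NULL, test = NULL) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    seed <- as.integer(config$seed)
    cfgHash <- .configHash(config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

    if (is.null(train))
        train <- .loadCohort(config$cohorts$train, "signature_train", seed)
    if (is.null(test))
        test <- .loadCohort(config$cohorts$test, "replication_test",
                            .subSeed(seed, 101L))
    if (!grepl("_test$", cohortRole(test)))
        stop("held-out cohort must carry a *_test role, got: ",
             cohortRole(test))
    .assertTrainable(train, "the pipeline's selection/training stages")

    pp <- config$preprocess
    train <- preprocess(train,
                        minLibrarySize = pp$min_library_size,
                        exprThreshold = pp$expr_threshold,
                        exprFraction = pp$expr_fraction,
                        ruvK = pp$ruv_k, trim = pp$trim)
    test <- preprocess(test,
                       minLibrarySize = pp$min_library_size,
                       ruvK = pp$ruv_k, trim = pp$trim,
                       featureFilter = FALSE)

    sl <- config$selection
    sel <- runSelection(train, nPermutations = sl$n_permutations,
                        alpha = sl$alpha, nResamples = sl$n_resamples,
                        stabilityThreshold = sl$stability_threshold,
                        nBins = sl$n_bins,
                        nullPermutations = sl$null_permutations,
                        seed = .subSeed(seed, 7L))

    cl <- config$classify
    cm <- combinedModel(train, test, signature = sel$signature,
                        mode = cl$mode, nBootstrap = cl$n_bootstrap,
                        treeGrid = cl$tree_grid, nFolds = cl$n_folds,
                        seed = .subSeed(seed, 8L))

    corr <- NULL
    if (all(c("pTau", "Abeta42", "Abeta40") %in%
            colnames(colData(train))))
        corr <- correlateSignatureWithPanel(train, sel$signature)

    .writeReport(outDir, cfgHash, seed, sel, cm, corr, train, test)
    invisible(list(signature = sel$signature, selection = sel,
                   model = cm$model, roc = cm$roc, report_dir = outDir))
}

.loadCohort <- function(block, role, seed) {
    if (is.null(block))
        stop("cohort block missing from configuration")
    if (isTRUE(block$simulate)) {
        args <- block[setdiff(names(block), c("simulate", "role"))]
        args$seed <- if (is.null(args$seed)) seed else args$seed
        cfg <- do.call(simulationConfig, args)
        simulateStudy(cfg, role = role)
    } else {
        readCohort(block$counts, block$samples, role = role)
    }
}

## Stable hash of the configuration: canonical YAML serialization -> md5.
## YAML round-trips numbers stably, so a config read from disk hashes the
## same as its in-memory equivalent.
.configHash <- function(config) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(yaml::as.yaml(config[order(names(config))]), tmp)
    unname(tools::md5sum(tmp))
}

.stamp <- function(path, cfgHash, seed) {
    cat(sprintf("# config_md5=%s seed=%d\n", cfgHash, seed), file = path)
    path
}

.writeTsv <- function(df, path, cfgHash, seed) {
    .stamp(path, cfgHash, seed)
    suppressWarnings(utils::write.table(
        df, path, sep = "\t", quote = FALSE, row.names = FALSE,
        append = TRUE))
    path
}

.writeReport <- function(outDir, cfgHash, seed, sel, cm, corr, train,
                         test) {
    f <- function(x) file.path(outDir, x)
    .writeTsv(signatureTable(sel$signature), f("signature.tsv"), cfgHash,
              seed)
    rk <- rankingTable(sel$ranking)
    rk$critical_value <- criticalValue(sel$ranking)
    st <- as.data.frame(sel$stability@table)
    rk$selection_frequency <-
        st$selection_frequency[match(rk$feature_id, st$feature_id)]
    .writeTsv(rk, f("ranking.tsv"), cfgHash, seed)
    .writeTsv(sel$audit, f("audit.tsv"), cfgHash, seed)
    .writeTsv(rocPoints(cm$roc), f("roc.tsv"), cfgHash, seed)
    .writeTsv(data.frame(feature = names(cm$model@importance),
                         importance = unname(cm$model@importance)),
              f("importance.tsv"), cfgHash, seed)
    if (!is.null(corr)) {
        cd <- data.frame(variable = rownames(corr$r),
                         round(corr$r, 10), check.names = FALSE)
        .writeTsv(cd, f("correlation.tsv"), cfgHash, seed)
    }
    jsonlite::write_json(
        list(auc = cm$roc@auc, ci_low = cm$roc@ciLow,
             ci_high = cm$roc@ciHigh, n_bootstrap = cm$roc@nBootstrap,
             n_trees = cm$model@nTrees, cv_error = cm$model@cvError,
             config_md5 = cfgHash, seed = seed),
        f("auc.json"), auto_unbox = TRUE, digits = NA)
    writeLines(c(paste0("# config_md5=", cfgHash, " seed=", seed),
                 "## train", provenance(train), "## test",
                 provenance(test)),
               f("provenance.txt"))
    invisible(outDir)
}
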