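test_that("forest tuning learns separable data and is reproducible", {
    set.seed(1)
    n <- 60
    g <- rep(c("control", "case"), each = n / 2)
    X <- cbind(a = c(rnorm(n / 2, 0), rnorm(n / 2, 4)),
               b = c(rnorm(n / 2, 0), rnorm(n / 2, -4)))
    rownames(X) <- sprintf("s%02d", 1:n)
    m <- tuneAndTrain(X, g, treeGrid = c(100, 300), seed = 2)
    expect_lte(m@cvError, 0.05)
    expect_identical(sort(names(m@importance)), c("a", "b"))

    m2 <- tuneAndTrain(X, g, treeGrid = c(100, 300), seed = 2)
    expect_identical(m@nTrees, m2@nTrees)
    expect_identical(m@importance, m2@importance)

    expect_error(tuneAndTrain(X, rep("case", n)), "two group labels")
    expect_error(tuneAndTrain(X * NA, g), "complete")
})

test_that("prediction respects the held-out contract and the schema", {
    set.seed(3)
    X <- matrix(rnorm(40), 20, 2,
                dimnames = list(sprintf("s%02d", 1:20), c("a", "b")))
    g <- rep(c("control", "case"), 10)
    m <- tuneAndTrain(X, g, treeGrid = 100, seed = 1)

    sc <- predictScores(m, X)
    expect_true(all(sc >= 0 & sc <= 1))

    empty <- predictScores(m, X[0, , drop = FALSE])
    expect_length(empty, 0)

    bad <- X; colnames(bad) <- c("a", "zz")
    expect_error(predictScores(m, bad), "missing: \\[b\\], extra: \\[zz\\]")
})

test_that("AUC equals pair enumeration, including ties", {
    r <- rocAuc(c(0.9, 0.8, 0.7, 0.85), c(TRUE, TRUE, FALSE, FALSE))
    expect_equal(aucValue(r), 0.75)           # 3 of 4 concordant pairs

    expect_equal(aucValue(rocAuc(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE,
                                                  FALSE))), 1.0)
    expect_equal(aucValue(rocAuc(rep(0.5, 6),
                                 rep(c(TRUE, FALSE), 3))), 0.5)

    set.seed(7)
    for (i in 1:25) {
        n <- sample(6:20, 1)
        sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
        case <- sample(c(TRUE, FALSE), n, replace = TRUE)
        if (!any(case) || all(case)) next
        expect_equal(aucValue(rocAuc(sc, case)), aucPairOracle(sc, case),
                     tolerance = 1e-12)
        ## complementarity for tie-free scores
        sct <- rank(sc, ties.method = "random") / n
        expect_equal(aucValue(rocAuc(sct, case)) +
                     aucValue(rocAuc(-sct, case)), 1.0, tolerance = 1e-12)
    }
    expect_error(rocAuc(1:3, rep(TRUE, 3)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
    skip_if_not_installed("pROC")
    set.seed(11)
    for (i in 1:5) {
        sc <- round(runif(30), 2)
        case <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(.4, .6))
        if (sum(case) < 2 || sum(!case) < 2) next
        ours <- aucValue(rocAuc(sc, case))
        theirs <- as.numeric(suppressMessages(
            pROC::auc(pROC::roc(case, sc, direction = "<", quiet = TRUE))))
        expect_equal(ours, theirs, tolerance = 1e-12)
    }
})

test_that("stratified bootstrap CI behaves at the extremes and is seeded", {
    sc <- c(rep(0.9, 5), rep(0.1, 5))
    case <- rep(c(TRUE, FALSE), each = 5)
    r <- bootstrapCi(sc, case, nBootstrap = 200, seed = 4)
    expect_identical(unname(aucInterval(r)), c(1, 1))
    expect_identical(aucValue(r), 1)

    set.seed(5)
    sc2 <- runif(30); case2 <- rep(c(TRUE, FALSE), 15)
    a <- bootstrapCi(sc2, case2, nBootstrap = 100, seed = 6)
    b <- bootstrapCi(sc2, case2, nBootstrap = 100, seed = 6)
    expect_identical(aucInterval(a), aucInterval(b))
    expect_true(r@ciLow <= r@auc && r@auc <= r@ciHigh)
})

test_that("combined models assemble panels correctly and guard leakage", {
    expect_equal(abetaRatio(data.frame(Abeta42 = 400, Abeta40 = 8000)),
                 0.05)
    expect_error(abetaRatio(data.frame(Abeta42 = 400, Abeta40 = 0)),
                 "positive")

    tr <- preprocess(simulateStudy(simulationConfig(seed = 61),
                                   role = "signature_train"))
    te <- preprocess(simulateStudy(
        simulationConfig(nControl = 20L, nCase = 12L, seed = 62),
        role = "replication_test"), featureFilter = FALSE)
    sig <- new("Signature",
               featureIds = c("miR-27a-3p", "piR_019324"),
               kind = c("miRNA", "piRNA"), direction = c("up", "down"))

    out <- combinedModel(tr, te, sig, mode = "snc_only",
                         treeGrid = c(100, 200), nBootstrap = 100,
                         seed = 3)
    expect_gt(aucValue(out$roc), 0.8)

    outP <- combinedModel(tr, te, sig, mode = "protein_only",
                          treeGrid = c(100, 200), nBootstrap = 100,
                          seed = 3)
    expect_gt(aucValue(outP$roc), 0.9)   # planted panel separates strongly

    outPi <- combinedModel(tr, te, sig, mode = "pirna_only",
                           treeGrid = c(100, 200), nBootstrap = 100,
                           seed = 3)
    expect_identical(outPi$model@featureNames, "piR_019324")

    ## a class-uninformative panel scores at chance (averaged over draws)
    set.seed(99)
    chance <- vapply(1:8, function(i) {
        trC <- tr; teC <- te
        colData(trC)$pTau <- runif(ncol(trC), 20, 80)
        colData(trC)$Abeta42 <- runif(ncol(trC), 300, 900)
        colData(trC)$Abeta40 <- runif(ncol(trC), 6000, 10000)
        colData(teC)$pTau <- runif(ncol(teC), 20, 80)
        colData(teC)$Abeta42 <- runif(ncol(teC), 300, 900)
        colData(teC)$Abeta40 <- runif(ncol(teC), 6000, 10000)
        outC <- combinedModel(trC, teC, sig, mode = "protein_only",
                              treeGrid = 100, nBootstrap = 50,
                              seed = 100 + i)
        aucValue(outC$roc)
    }, numeric(1))
    expect_gte(mean(chance), 0.4)
    expect_lte(mean(chance), 0.6)

    ## leakage guard: a test-role cohort cannot be trained on
    expect_error(combinedModel(te, tr, sig, mode = "snc_only"),
                 "leakage guard")

    ## missing panel values are reported by sample
    trM <- tr
    colData(trM)$pTau[2] <- NA
    expect_error(combinedModel(trM, te, sig, mode = "protein_only"),
                 colnames(trM)[2])
})

test_that("signature-panel correlation matches hand-computed values", {
    cts <- matrix(10L, 4, 4, dimnames = list(
        c("miR-a-5p", "miR-b-5p", "miR-c-5p", "miR-d-5p"),
        sprintf("S%d", 1:4)))
    norm <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(4, 3, 2, 1),
                  c(1, 3, 2, 4))
    dimnames(norm) <- dimnames(cts)
    se <- makeSnc(counts = cts, normalized = norm,
                  diagnosis = rep(c("control", "AD"), 2))
    colData(se)$pTau <- c(1, 2, 3, 4)
    colData(se)$Abeta42 <- c(500, 500, 400, 400)
    colData(se)$Abeta40 <- rep(8000, 4)
    sig <- new("Signature",
               featureIds = c("miR-a-5p", "miR-b-5p", "miR-c-5p",
                              "miR-d-5p"),
               kind = rep("miRNA", 4), direction = rep("up", 4))
    cp <- correlateSignatureWithPanel(se, sig)
    expect_equal(cp$r["miR-a-5p", "miR-b-5p"], 1.0)
    expect_equal(cp$r["miR-a-5p", "miR-c-5p"], -1.0)
    expect_equal(cp$r["miR-a-5p", "miR-d-5p"], 0.8)
    expect_equal(cp$r["miR-a-5p", "pTau"], 1.0)

    ## zero-variance column is NA with a warning
    norm2 <- norm; norm2[2, ] <- 5
    se2 <- makeSnc(counts = cts, normalized = norm2,
                   diagnosis = rep(c("control", "AD"), 2))
    colData(se2)$pTau <- c(1, 2, 3, 4)
    colData(se2)$Abeta42 <- c(500, 500, 400, 400)
    colData(se2)$Abeta40 <- rep(8000, 4)
    expect_warning(cp2 <- correlateSignatureWithPanel(se2, sig),
                   "zero-variance")
    expect_true(is.na(cp2$r["miR-a-5p", "miR-b-5p"]))
})
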