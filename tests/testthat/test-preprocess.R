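test_that("sample filter applies the strict library-size threshold", {
    cts <- cbind(S1 = rep(1, 10), S2 = rep(5000, 10), S3 = rep(1e5, 10))
    cts[1, ] <- c(49999 - 9, 50000 - 5000 * 9, 1e6 - 1e5 * 9)
    rownames(cts) <- sprintf("miR-t-%02d", 1:10)
    se <- makeSnc(counts = cts, diagnosis = c("control", "AD", "AD"))
    expect_identical(unname(colSums(assay(se, "counts"))),
                     c(49999, 50000, 1e6 + 0))

    kept <- filterSamples(se)
    expect_identical(colnames(kept), c("S2", "S3"))
    expect_identical(metadata(kept)$sample_filter$sample_id, "S1")
    expect_identical(metadata(kept)$sample_filter$library_size, 49999)

    ## identity when everything passes, and idempotence
    again <- filterSamples(kept)
    expect_identical(assay(again, "counts"), assay(kept, "counts"))

    expect_error(filterSamples(se, minLibrarySize = 1e9), "empty cohort")
})

test_that("VSN calibration is symmetric, asymptotically log2, monotone", {
    set.seed(1)
    col <- rnbinom(60, mu = 200, size = 5)
    X <- matrix(rep(col, 8), ncol = 8,
                dimnames = list(sprintf("f%02d", 1:60),
                                sprintf("s%d", 1:8)))
    v <- vsnTransform(X)
    expect_true(max(abs(v$a - v$a[1])) < 1e-8)
    expect_true(max(abs(v$b - v$b[1])) < 1e-8)
    expect_true(all(apply(v$h, 1, function(r) max(r) - min(r)) < 1e-8))

    ## glog2 -> log2 asymptote: doubling a high count raises h by ~1
    x <- (100 * v$c + abs(v$a[1])) * v$b[1]
    h1 <- log2(((x - v$a[1]) / v$b[1] +
                sqrt(((x - v$a[1]) / v$b[1])^2 + v$c^2)) / 2)
    h2 <- log2(((2 * x - v$a[1]) / v$b[1] +
                sqrt(((2 * x - v$a[1]) / v$b[1])^2 + v$c^2)) / 2)
    expect_equal(h2 - h1, 1.0, tolerance = 0.01)

    ## monotone within each sample
    set.seed(2)
    Y <- matrix(rnbinom(400, mu = 50, size = 2), 40, 10,
                dimnames = list(sprintf("g%02d", 1:40),
                                sprintf("t%02d", 1:10)))
    vy <- vsnTransform(Y)
    for (s in 1:10) {
        o <- order(Y[, s])
        expect_true(all(diff(vy$h[o, s][!duplicated(Y[o, s])]) > 0))
    }
})

test_that("VSN stabilizes the SD-vs-mean-rank trend of NB counts", {
    set.seed(11)
    F <- 300; S <- 30
    mu <- 10^runif(F, 0, 4)
    X <- matrix(rnbinom(F * S, mu = rep(mu, S), size = 10), F, S,
                dimnames = list(sprintf("f%03d", 1:F),
                                sprintf("s%02d", 1:S)))
    v <- vsnTransform(X)
    rk <- rank(rowMeans(X))
    rawSlope <- unname(coef(lm(apply(X, 1, sd) ~ rk))[2])
    vsnSlope <- unname(coef(lm(apply(v$h, 1, sd) ~ rk))[2])
    expect_gt(rawSlope, 0.2)
    expect_gte(vsnSlope, -0.05)
    expect_lte(vsnSlope, 0.05)
})

test_that("unwanted-variance removal strips batch shifts, spares signal", {
    set.seed(21)
    F <- 100; S <- 40
    X <- matrix(rnbinom(F * S, mu = 300, size = 100), F, S,
                dimnames = list(c(sprintf("miR-s-%02d", 1:4),
                                  sprintf("miR-n-%02d", 5:F)),
                                sprintf("S%02d", 1:S)))
    diagnosis <- rep(c("control", "AD"), each = S / 2)
    ## group signal on 4 features, orthogonal batch on half the samples
    batch <- rep(c("b1", "b2"), S / 2)
    X[1:4, diagnosis == "AD"] <- X[1:4, diagnosis == "AD"] * 3
    X[, batch == "b2"] <- round(X[, batch == "b2"] * 2)   # +1 log2 unit
    se <- makeSnc(counts = X, diagnosis = diagnosis)
    se <- vsnTransform(se)

    before <- normalizedValues(se)
    corrected <- removeUnwantedVariance(se, k = 1, batch = batch)
    after <- normalizedValues(corrected)

    noise <- rownames(X)[5:F]
    batchDiff <- rowMeans(after[noise, batch == "b2"]) -
        rowMeans(after[noise, batch == "b1"])
    expect_lt(mean(abs(batchDiff)), 0.1)

    ## group signal essentially untouched
    gDiff <- function(M, f) mean(M[f, diagnosis == "AD"]) -
        mean(M[f, diagnosis == "control"])
    for (f in rownames(X)[1:4])
        expect_lt(abs(gDiff(after, f) - gDiff(before, f)) /
                  abs(gDiff(before, f)), 0.05)

    ## k = 0 is the identity, bit for bit
    same <- removeUnwantedVariance(se, k = 0)
    expect_identical(normalizedValues(same), normalizedValues(se))

    expect_error(removeUnwantedVariance(se, k = 2,
                                        controlFeatures = noise[1:2]),
                 "control features")
})

test_that("expression filter removes only features silent in both groups", {
    F <- 6; n <- 40
    norm <- matrix(5, F, n, dimnames = list(
        c("miR-allhi-5p", "miR-allzero-5p", "miR-two-ctrl-5p",
          "miR-one-ctrl-5p", "piR_case_only", "piR_borderline"),
        sprintf("S%02d", 1:n)))
    diagnosis <- rep(c("control", "AD"), each = 20)
    norm["miR-allzero-5p", ] <- 0
    norm["miR-two-ctrl-5p", ] <- 0
    norm["miR-two-ctrl-5p", 1:2] <- 1          # 2/20 controls expressed
    norm["miR-one-ctrl-5p", ] <- 0
    norm["miR-one-ctrl-5p", 1] <- 1            # 1/20 controls expressed
    norm["piR_case_only", ] <- 0
    norm["piR_case_only", 21:40] <- 2          # case-specific marker
    norm["piR_borderline", ] <- 0.5            # exactly at threshold

    cts <- matrix(1L, F, n, dimnames = dimnames(norm))
    se <- makeSnc(counts = cts, diagnosis = diagnosis, normalized = norm)
    out <- filterFeatures(se)
    expect_setequal(rownames(out),
                    c("miR-allhi-5p", "miR-two-ctrl-5p", "piR_case_only",
                      "piR_borderline"))

    ## idempotent
    out2 <- filterFeatures(out)
    expect_identical(rownames(out2), rownames(out))

    expect_error(filterFeatures(se, groups = c(rep("control", 39), "AD")),
                 "at least 2 samples")
})

test_that("pipeline order is enforced through missing prerequisites", {
    se <- makeSnc(nFeatures = 12, nSamples = 8)
    expect_error(filterFeatures(se), "normalized")
    expect_error(removeUnwantedVariance(se, k = 1), "normalized")
})
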