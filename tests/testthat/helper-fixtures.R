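## Shared fixture builders; everything is generated in code at test time.

## Minimal SncExperiment around a given (or random) count matrix.
makeSnc <- function(counts = NULL, nFeatures = 20, nSamples = 10,
                    diagnosis = NULL, role = "unassigned",
                    normalized = NULL, seed = 1) {
    if (is.null(counts)) {
        set.seed(seed)
        counts <- matrix(rnbinom(nFeatures * nSamples, mu = 100, size = 10),
                         nFeatures, nSamples)
        rownames(counts) <- c(sprintf("miR-t-%02d",
                                      seq_len(ceiling(nFeatures / 2))),
                              sprintf("piR_t_%02d",
                                      seq_len(floor(nFeatures / 2))))
        colnames(counts) <- sprintf("S%02d", seq_len(nSamples))
    }
    if (is.null(diagnosis))
        diagnosis <- rep(c("control", "AD"), length.out = ncol(counts))
    smp <- data.frame(diagnosis = diagnosis,
                      age = seq(60, 80, length.out = ncol(counts)),
                      sex = rep(c("F", "M"), length.out = ncol(counts)),
                      row.names = colnames(counts))
    se <- SncExperiment(counts, smp, role = role)
    if (!is.null(normalized))
        SummarizedExperiment::assay(se, "normalized") <- normalized
    se
}

## Independent Welch-score oracle: plain-loop arithmetic.
welchOracle <- function(x, case) {
    m1 <- mean(x[case]); m0 <- mean(x[!case])
    se <- sqrt(var(x[case]) / sum(case) + var(x[!case]) / sum(!case))
    abs(m1 - m0) / max(se, 1e-8)
}

## Exhaustive permutation-null oracle for the MoR critical value: enumerate
## every case assignment with combn, score every feature with welchOracle,
## pool, and take the order statistic at ceiling((1 - alpha) * N).
exhaustiveCritOracle <- function(X, nCase, alpha = 0.05) {
    n <- ncol(X)
    combos <- combn(n, nCase)
    null <- c()
    for (j in seq_len(ncol(combos))) {
        case <- seq_len(n) %in% combos[, j]
        null <- c(null, apply(X, 1, welchOracle, case = case))
    }
    unname(sort(null)[ceiling((1 - alpha) * length(null))])
}

## Brute-force AUC oracle: enumerate all case/control pairs, ties = 0.5.
aucPairOracle <- function(scores, case) {
    sc <- scores[case]; sn <- scores[!case]
    tot <- 0
    for (a in sc) for (b in sn)
        tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(sc) * length(sn))
}

## Brute-force interval classifier over an exon table (plain arithmetic,
## 1-based inclusive coordinates, strand-aware first exon by exon_rank).
annotationOracle <- function(lociDf, exonDf, ignoreStrand = FALSE) {
    overlaps <- function(s1, e1, s2, e2) s1 <= e2 && e1 >= s2
    vapply(seq_len(nrow(lociDf)), function(i) {
        ls <- lociDf$start[i]; le <- lociDf$end[i]; lst <- lociDf$strand[i]
        best <- "intergenic"
        rankOf <- c(exon1 = 1, other_exon = 2, intron = 3, intergenic = 4)
        for (tx in unique(exonDf$transcript_id)) {
            ex <- exonDf[exonDf$transcript_id == tx, ]
            if (!ignoreStrand && ex$strand[1] != lst) next
            cat_tx <- NULL
            for (j in seq_len(nrow(ex))) {
                if (overlaps(ls, le, ex$start[j], ex$end[j])) {
                    c_j <- if (ex$exon_rank[j] == 1) "exon1" else
                        "other_exon"
                    if (is.null(cat_tx) ||
                        rankOf[c_j] < rankOf[cat_tx]) cat_tx <- c_j
                }
            }
            if (is.null(cat_tx) &&
                overlaps(ls, le, min(ex$start), max(ex$end)))
                cat_tx <- "intron"
            if (!is.null(cat_tx) && rankOf[cat_tx] < rankOf[best])
                best <- cat_tx
        }
        best
    }, character(1))
}

grToDf <- function(gr) {
    data.frame(start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               transcript_id = if ("transcript_id" %in%
                                   colnames(S4Vectors::mcols(gr)))
                   S4Vectors::mcols(gr)$transcript_id else NA,
               exon_rank = if ("exon_rank" %in%
                               colnames(S4Vectors::mcols(gr)))
                   S4Vectors::mcols(gr)$exon_rank else NA)
}
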