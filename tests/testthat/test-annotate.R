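test_that("composition fractions reduce to per-biotype sums", {
    cts <- rbind(miRNA1 = c(100, 100), miRNA2 = c(50, 50),
                 piRNA1 = c(50, 50))
    colnames(cts) <- c("S1", "S2")
    out <- compositionFractions(cts, biotype = c("miRNA", "miRNA", "piRNA"))
    expect_equal(unname(out$fractions[c("miRNA", "piRNA")]),
                 c(0.75, 0.25))
    expect_equal(sum(out$fractions), 1, tolerance = 1e-12)

    one <- compositionFractions(cts[1, , drop = FALSE], biotype = "miRNA")
    expect_equal(unname(one$fractions), 1.0)

    set.seed(2)
    M <- matrix(rpois(60, 30), 12, 5,
                dimnames = list(sprintf("f%02d", 1:12),
                                sprintf("s%d", 1:5)))
    bt <- sample(c("miRNA", "piRNA", "snoRNA"), 12, replace = TRUE)
    res <- compositionFractions(M, biotype = bt)
    brute <- tapply(rowSums(M), bt, sum) / sum(M)
    expect_equal(unname(res$fractions[names(brute)]), as.vector(brute),
                 tolerance = 1e-12)

    expect_error(compositionFractions(M * 0L, biotype = bt), "zero total")
})

test_that("locus annotation follows the strand-aware precedence rules", {
    ## hand-built model: one + gene, one - gene
    exons <- GenomicRanges::GRanges(
        "chrS",
        IRanges::IRanges(start = c(100, 500, 2000, 2500),
                         end = c(199, 599, 2099, 2599)),
        strand = c("+", "+", "-", "-"),
        gene_id = c("gA", "gA", "gB", "gB"),
        transcript_id = c("gA.t1", "gA.t1", "gB.t1", "gB.t1"),
        exon_rank = c(1L, 2L, 2L, 1L))   # minus strand: rightmost is first
    loci <- GenomicRanges::GRanges(
        "chrS",
        IRanges::IRanges(start = c(110, 510, 2510, 2010, 300, 110),
                         end = c(139, 539, 2539, 2039, 329, 139)),
        strand = c("+", "+", "-", "-", "+", "-"),
        locus_id = sprintf("L%d", 1:6))
    ann <- annotateLoci(loci, exons)
    expect_identical(as.character(ann$category),
                     c("exon1",        # inside + first exon
                       "other_exon",   # inside + second exon
                       "exon1",        # inside - strand first (rightmost)
                       "other_exon",   # inside - strand second exon
                       "intron",       # between gA exons, same strand
                       "intergenic"))  # antisense to gA: no same-strand hit
    expect_identical(ann$host_gene[1], "gA")
    expect_identical(ann$host_gene[3], "gB")
    expect_true(is.na(ann$host_gene[6]))
    expect_identical(sum(attr(ann, "histogram")), 6L)

    ## ignoring strand turns the antisense locus into exon1
    annIS <- annotateLoci(loci, exons, ignoreStrand = TRUE)
    expect_identical(as.character(annIS$category[6]), "exon1")
})

test_that("annotation agrees with a brute-force oracle and the truth", {
    gm <- simulateGeneModel(nGenes = 12, seed = 19, nLoci = 300)
    ann <- annotateLoci(gm$loci, gm$exons)
    expect_identical(as.character(ann$category),
                     S4Vectors::mcols(gm$loci)$truth)
    oracle <- annotationOracle(grToDf(gm$loci), grToDf(gm$exons))
    expect_identical(as.character(ann$category), oracle)

    ## strand symmetry: mirror all coordinates and flip strands
    L <- max(GenomicRanges::end(gm$exons),
             GenomicRanges::end(gm$loci)) + 1000
    mirror <- function(gr) {
        out <- GenomicRanges::GRanges(
            "chrS",
            IRanges::IRanges(start = L - GenomicRanges::end(gr),
                             end = L - GenomicRanges::start(gr)),
            strand = ifelse(as.character(GenomicRanges::strand(gr)) == "+",
                            "-", "+"))
        S4Vectors::mcols(out) <- S4Vectors::mcols(gr)
        out
    }
    annM <- annotateLoci(mirror(gm$loci), mirror(gm$exons))
    expect_identical(as.character(annM$category),
                     as.character(ann$category))
})

test_that("gene model and loci survive GTF/BED round trips", {
    gm <- simulateGeneModel(nGenes = 5, seed = 3, nLoci = 20)
    gtf <- tempfile(fileext = ".gtf")
    writeGeneModelGTF(gm$exons, gtf)
    back <- readGeneModelGTF(gtf)
    o <- order(GenomicRanges::start(back))
    oe <- order(GenomicRanges::start(gm$exons))
    expect_identical(GenomicRanges::start(back)[o],
                     GenomicRanges::start(gm$exons)[oe])
    expect_identical(GenomicRanges::end(back)[o],
                     GenomicRanges::end(gm$exons)[oe])
    expect_identical(S4Vectors::mcols(back)$exon_rank[o],
                     S4Vectors::mcols(gm$exons)$exon_rank[oe])
    ## annotation is invariant under the round trip
    expect_identical(annotateLoci(gm$loci, back)$category,
                     annotateLoci(gm$loci, gm$exons)$category)

    bed <- tempfile(fileext = ".bed")
    writeLociBED(gm$loci, bed)
    lociBack <- readLociBED(bed)
    expect_identical(GenomicRanges::start(lociBack),
                     GenomicRanges::start(gm$loci))
    expect_identical(as.character(GenomicRanges::strand(lociBack)),
                     as.character(GenomicRanges::strand(gm$loci)))

    ## malformed BED record is rejected by name
    bad <- tempfile(fileext = ".bed")
    writeLines("chrS\t500\t400\tbadLocus\t0\t+", bad)
    expect_error(readLociBED(bad), "badLocus")
})

test_that("arm dominance is recovered and concordance counted", {
    expr <- rbind("mir-X-5p" = rep(8, 4), "mir-X-3p" = rep(2, 4),
                  "mir-Y-5p" = rep(3, 4), "mir-Y-3p" = rep(3, 4))
    colnames(expr) <- sprintf("s%d", 1:4)
    ad <- armDominance(expr)
    expect_identical(ad$dominant_arm[ad$precursor == "mir-X"], "5p")
    expect_identical(ad$dominant_arm[ad$precursor == "mir-Y"], "tie")

    ## planted truth over 50 precursors
    set.seed(6)
    stems <- sprintf("mir-%03d", 1:50)
    dom <- sample(c("5p", "3p"), 50, replace = TRUE)
    hi <- matrix(rnorm(50 * 6, 10, 0.1), 50, 6)
    lo <- matrix(rnorm(50 * 6, 2, 0.1), 50, 6)
    M <- rbind(ifelse(dom == "5p", 1, 0) * hi +
               ifelse(dom == "5p", 0, 1) * lo,
               ifelse(dom == "3p", 1, 0) * hi +
               ifelse(dom == "3p", 0, 1) * lo)
    rownames(M) <- c(paste0(stems, "-5p"), paste0(stems, "-3p"))
    colnames(M) <- sprintf("s%d", 1:6)
    adM <- armDominance(M)
    expect_identical(adM$dominant_arm[match(stems, adM$precursor)], dom)

    expect_error(armDominance(rbind("mir-odd" = rep(1, 3))), "suffix")

    tabA <- data.frame(precursor = c("a", "b", "c", "d"),
                       dominant_arm = c("5p", "5p", "3p", "3p"))
    tabB <- data.frame(precursor = c("a", "b", "c", "d"),
                       dominant_arm = c("5p", "5p", "3p", "5p"))
    expect_equal(armConcordance(tabA, tabB)$concordance, 0.75)
    expect_equal(armConcordance(tabA, tabA)$concordance, 1.0)
    swapped <- tabA
    swapped$dominant_arm <- ifelse(tabA$dominant_arm == "5p", "3p", "5p")
    expect_equal(armConcordance(tabA, swapped)$concordance, 0.0)
    expect_error(armConcordance(tabA,
                                data.frame(precursor = "zz",
                                           dominant_arm = "5p")),
                 "shared")
})

test_that("cell/exosome correlation round-trips the generator", {
    exact <- data.frame(cell = c(1, 2, 3, 4), exosome = c(1, 2, 3, 4),
                        kind = "miRNA")
    pc <- pairedCorrelation(exact)
    expect_equal(pc$r, 1.0)

    sim <- simulatePairedCellExosome(500, rho = 0.9, seed = 10)
    pcs <- pairedCorrelation(sim)
    expect_true(all(pcs$r >= 0.85 & pcs$r <= 0.94))
    expect_true(all(pcs$p < 1e-10))

    indep <- simulatePairedCellExosome(10000, rho = 0, seed = 11)
    pci <- pairedCorrelation(cell = indep$cell, exosome = indep$exosome)
    expect_lt(abs(pci$r), 0.05)

    flat <- data.frame(cell = rep(1, 5), exosome = rnorm(5), kind = "m")
    expect_warning(pcf <- pairedCorrelation(flat), "zero variance")
    expect_true(is.na(pcf$r))
})
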