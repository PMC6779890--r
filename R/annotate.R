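#' Read-composition fractions per RNA biotype
#'
#' Sums raw reads per biotype across the whole matrix and reports each
#' biotype's fraction of the grand total (the pie-chart view of a
#' sncRNAome), together with the top expressed features per biotype.
#'
#' @param x an [SncExperiment-class] (biotype from `rowData(x)$kind`) or a
#'   count matrix.
#' @param biotype per-feature biotype (required for a matrix).
#' @param topK number of top features per biotype to report.
#' @return list(fractions = named numeric summing to 1, top = data.frame of
#'   the `topK` features per biotype by total reads).
#' @export
compositionFractions <- function(x, biotype = NULL, topK = 5) {
    if (is(x, "SncExperiment")) {
        biotype <- unname(featureKind(x))
        x <- assay(x, "counts")
    }
    if (is.null(biotype) || length(biotype) != nrow(x))
        stop("a biotype is required for every feature")
    totals <- rowSums(x)
    grand <- sum(totals)
    if (grand == 0) stop("zero total read count")
    frac <- vapply(split(totals, biotype), sum, numeric(1)) / grand
    ord <- order(-totals)
    top <- do.call(rbind, lapply(split(ord, biotype[ord]), function(i) {
        i <- i[seq_len(min(topK, length(i)))]
        data.frame(biotype = biotype[i],
                   feature_id = rownames(x)[i],
                   reads = totals[i])
    }))
    rownames(top) <- NULL
    list(fractions = frac, top = top)
}

.CATEGORY_LEVELS <- c("exon1", "other_exon", "intron", "intergenic")

#' Genomic-context annotation of small-RNA loci
#'
#' Classifies each locus against a gene model with the precedence
#' exon1 > other_exon > intron > intergenic, where "first exon" means first
#' in transcription order (the rightmost exon interval of a minus-strand
#' transcript), an overlap is any >= 1 bp intersection, and — by default —
#' only same-strand transcripts are considered (the sense piRNA-host
#' relationship). The host gene is the gene granting the highest-precedence
#' hit; ties resolve to the lexicographically smallest gene ID.
#'
#' @param loci `GRanges` of small-RNA loci (metadata column `locus_id`
#'   optional).
#' @param exons `GRanges` of exons with metadata columns `gene_id`,
#'   `transcript_id` and `exon_rank` (1 = first in transcription order), as
#'   produced by [simulateGeneModel()] or [readGeneModelGTF()].
#' @param ignoreStrand set `TRUE` to allow antisense overlaps.
#' @return data.frame(locus_id, category, host_gene) plus a `"histogram"`
#'   attribute with the per-category locus counts.
#' @importFrom GenomicRanges findOverlaps GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols
#' @export
annotateLoci <- function(loci, exons, ignoreStrand = FALSE) {
    req <- c("gene_id", "transcript_id", "exon_rank")
    if (!all(req %in% colnames(mcols(exons))))
        stop("exons need metadata columns: ", paste(req, collapse = ", "))
    nL <- length(loci)
    ids <- if ("locus_id" %in% colnames(mcols(loci)))
        mcols(loci)$locus_id else sprintf("locus_%04d", seq_len(nL))

    txRanges <- unlist(range(split(exons, mcols(exons)$transcript_id)))
    txGene <- vapply(split(as.character(mcols(exons)$gene_id),
                           mcols(exons)$transcript_id),
                     function(g) g[1], character(1))
    mcols(txRanges)$gene_id <- txGene[names(txRanges)]

    category <- rep(NA_character_, nL)
    host <- rep(NA_character_, nL)
    assign <- function(subject, geneIds, label) {
        hits <- findOverlaps(loci, subject, ignore.strand = ignoreStrand)
        q <- queryHits(hits)
        open <- is.na(category[q])
        if (!any(open)) return(invisible())
        for (i in unique(q[open])) {
            g <- geneIds[subjectHits(hits)[q == i]]
            category[i] <<- label
            host[i] <<- min(g)
        }
    }
    first <- exons[mcols(exons)$exon_rank == 1L]
    assign(first, as.character(mcols(first)$gene_id), "exon1")
    other <- exons[mcols(exons)$exon_rank != 1L]
    assign(other, as.character(mcols(other)$gene_id), "other_exon")
    assign(txRanges, as.character(mcols(txRanges)$gene_id), "intron")
    category[is.na(category)] <- "intergenic"

    out <- data.frame(locus_id = ids,
                      category = factor(category,
                                        levels = .CATEGORY_LEVELS),
                      host_gene = host)
    attr(out, "histogram") <- table(out$category)
    out
}

#' miRNA arm dominance
#'
#' Pairs the 5p and 3p arms of each miRNA precursor by stem name (IDs must
#' end in `-5p` or `-3p`) and calls the dominant arm as the one with the
#' higher mean expression; exact equality is a tie. Precursors with only one
#' detected arm are excluded (listed in the `"unpaired"` attribute).
#'
#' @param x an [SncExperiment-class] (normalized values when available,
#'   counts otherwise) or a numeric matrix with arm-suffixed rownames.
#' @return data.frame(precursor, expr_5p, expr_3p, dominant_arm), with
#'   attributes `"unpaired"` (single-arm stems) — IDs that do not follow the
#'   suffix convention raise an error listing them.
#' @export
armDominance <- function(x) {
    if (is(x, "SncExperiment")) {
        x <- x[featureKind(x) == "miRNA", ]
        x <- if ("normalized" %in% assayNames(x)) normalizedValues(x) else
            assay(x, "counts")
    }
    ids <- rownames(x)
    m <- regmatches(ids, regexec("^(.*)-(5p|3p)$", ids))
    bad <- ids[lengths(m) == 0]
    if (length(bad))
        stop("IDs without a -5p/-3p arm suffix: ",
             paste(bad, collapse = ", "))
    stem <- vapply(m, `[`, character(1), 2)
    arm <- vapply(m, `[`, character(1), 3)
    expr <- rowMeans(x)
    stems <- unique(stem)
    has5 <- stems %in% stem[arm == "5p"]
    has3 <- stems %in% stem[arm == "3p"]
    paired <- stems[has5 & has3]
    if (!length(paired))
        stop("no precursor with both arms present")
    e5 <- expr[match(paste0(paired, "-5p"), ids)]
    e3 <- expr[match(paste0(paired, "-3p"), ids)]
    out <- data.frame(precursor = paired, expr_5p = unname(e5),
                      expr_3p = unname(e3),
                      dominant_arm = ifelse(e5 > e3, "5p",
                                     ifelse(e3 > e5, "3p", "tie")))
    attr(out, "unpaired") <- stems[!(has5 & has3)]
    out
}

#' Cross-tissue arm-dominance concordance
#'
#' Fraction of precursors shared between two [armDominance()] tables (ties
#' excluded) whose dominant arm agrees — a measure of whether the arm usage
#' pattern in one compartment (e.g. CSF exosomes) mirrors another (e.g.
#' brain tissue).
#'
#' @param tableA,tableB data.frames from [armDominance()].
#' @return list(concordance = fraction in [0,1], shared = data.frame of the
#'   compared precursors with both calls).
#' @export
armConcordance <- function(tableA, tableB) {
    a <- tableA[tableA$dominant_arm != "tie", ]
    b <- tableB[tableB$dominant_arm != "tie", ]
    shared <- intersect(a$precursor, b$precursor)
    if (!length(shared))
        stop("no shared tie-free precursors between the two tables")
    da <- a$dominant_arm[match(shared, a$precursor)]
    db <- b$dominant_arm[match(shared, b$precursor)]
    list(concordance = mean(da == db),
         shared = data.frame(precursor = shared, arm_a = da, arm_b = db))
}

#' Cell-versus-exosome expression correlation
#'
#' Pearson correlation (with two-sided p-value) between matched cellular and
#' exosomal log-scale expression values, computed separately per feature
#' class (miRNA / piRNA).
#'
#' @param paired data.frame with columns `cell`, `exosome` and `kind` (as
#'   returned by [simulatePairedCellExosome()]), or two numeric vectors via
#'   `cell`/`exosome` arguments plus `kind`.
#' @param cell,exosome,kind alternative vector interface.
#' @return data.frame(kind, n, r, p); zero-variance classes yield `NA` with
#'   a warning.
#' @export
pairedCorrelation <- function(paired = NULL, cell = NULL, exosome = NULL,
                              kind = NULL) {
    if (!is.null(paired)) {
        cell <- paired$cell; exosome <- paired$exosome; kind <- paired$kind
    }
    if (length(cell) != length(exosome))
        stop("cell and exosome vectors must be matched")
    if (is.null(kind)) kind <- rep("all", length(cell))
    res <- lapply(split(seq_along(cell), kind), function(i) {
        if (length(i) < 3)
            stop("at least 3 matched features per class required")
        if (stats::sd(cell[i]) == 0 || stats::sd(exosome[i]) == 0) {
            warning("zero variance in class ", kind[i[1]],
                    "; correlation undefined")
            return(data.frame(kind = kind[i[1]], n = length(i),
                              r = NA_real_, p = NA_real_))
        }
        ct <- stats::cor.test(cell[i], exosome[i])
        data.frame(kind = kind[i[1]], n = length(i),
                   r = unname(ct$estimate), p = ct$p.value)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Write / read a gene model as GTF
#'
#' The exon table is serialized to GTF (1-based, inclusive coordinates; the
#' conversion from the internal representation is handled by rtracklayer)
#' with `gene_id`, `transcript_id` and `exon_number` attributes. On reading,
#' the strand-aware `exon_rank` is reconstructed from the exon order when
#' the attribute is absent.
#'
#' @param exons `GRanges` of exons with `gene_id`, `transcript_id`,
#'   `exon_rank`.
#' @param path file path.
#' @return `readGeneModelGTF` returns the exon `GRanges`.
#' @importFrom rtracklayer export import
#' @export
writeGeneModelGTF <- function(exons, path) {
    gr <- exons
    mcols(gr) <- DataFrame(source = "exoSig", type = "exon",
                           gene_id = mcols(exons)$gene_id,
                           transcript_id = mcols(exons)$transcript_id,
                           exon_number = as.character(
                               mcols(exons)$exon_rank))
    rtracklayer::export(gr, path, format = "gtf")
    invisible(path)
}

#' @rdname writeGeneModelGTF
#' @export
readGeneModelGTF <- function(path) {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[mcols(gr)$type == "exon"]
    if ("exon_number" %in% colnames(mcols(gr))) {
        rank <- as.integer(mcols(gr)$exon_number)
    } else {
        rank <- integer(length(gr))
        for (tx in split(seq_along(gr), mcols(gr)$transcript_id)) {
            o <- order(GenomicRanges::start(gr)[tx])
            if (as.character(GenomicRanges::strand(gr)[tx][1]) == "-")
                o <- rev(o)
            rank[tx[o]] <- seq_along(tx)
        }
    }
    mcols(gr) <- DataFrame(gene_id = mcols(gr)$gene_id,
                           transcript_id = mcols(gr)$transcript_id,
                           exon_rank = rank)
    gr
}

#' Write / read small-RNA loci as BED6
#'
#' BED uses 0-based half-open coordinates on disk; rtracklayer converts to
#' and from the 1-based inclusive in-memory representation. Malformed
#' records (start >= end) are rejected by name on reading.
#'
#' @param loci `GRanges` with a `locus_id` metadata column.
#' @param path file path.
#' @return `readLociBED` returns the locus `GRanges`.
#' @export
writeLociBED <- function(loci, path) {
    gr <- loci
    mcols(gr) <- DataFrame(
        name = if ("locus_id" %in% colnames(mcols(loci)))
            mcols(loci)$locus_id else sprintf("locus_%04d",
                                              seq_along(loci)),
        score = 0L)
    rtracklayer::export(gr, path, format = "bed")
    invisible(path)
}

#' @rdname writeLociBED
#' @export
readLociBED <- function(path) {
    raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(raw) < 6)
        stop("BED6 requires 6 columns")
    bad <- which(raw[[2]] >= raw[[3]])
    if (length(bad))
        stop("malformed interval (start >= end) in record(s): ",
             paste(raw[[4]][bad], collapse = ", "))
    gr <- rtracklayer::import(path, format = "bed")
    mcols(gr) <- DataFrame(locus_id = mcols(gr)$name)
    gr
}
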