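#' Simulation settings constructor
#'
#' Builds a [SimulationConfig-class] with defaults sized to the study design
#' the package targets: a signature-identification cohort of 38 controls and
#' 23 AD cases, 150 miRNA + 50 piRNA features, six planted differential
#' features (three miRNAs increased in cases; two piRNAs increased, one
#' decreased) at |log2FC| = 1.5, two age-confounded decoy features, two
#' collection centers with mild multiplicative batch effects, and lognormal
#' library sizes around 3e5 reads.
#'
#' @param nControl,nCase cohort sizes.
#' @param nMirna,nPirna number of miRNA / piRNA features (inclusive of
#'   planted and confounded ones).
#' @param plantedEffects data.frame(feature_id, log2fc) of differential truth
#'   applied to the case group. IDs starting with `piR` are treated as
#'   piRNAs.
#' @param confoundedFeatures data.frame(feature_id, age_slope): features
#'   driven by age (log2 units per year), not by diagnosis.
#' @param nbDispersion negative-binomial size k (variance m + m^2/k).
#' @param libsizeLogMean,libsizeLogSd lognormal library-size parameters.
#' @param baselineLogSd spread of baseline feature abundance (natural log).
#' @param nBatches,batchSd number of centers and the SD (log2) of the
#'   multiplicative per-(batch, feature) effect.
#' @param ageRangeControl,ageRangeCase uniform age ranges in years. The
#'   default ranges coincide (age-matched cohorts, the targeted study
#'   design); offsetting them induces group-age confounding of tunable
#'   strength.
#' @param sexRatio fraction of female subjects.
#' @param seed integer seed for subject-level randomness (cohort draws).
#' @param baselineSeed integer seed for the population-level baseline
#'   abundance profile; keep it fixed across cohorts that should share a
#'   generative truth (e.g. signature and replication cohorts).
#' @return A validated `SimulationConfig`.
#' @export
simulationConfig <- function(nControl = 38L, nCase = 23L,
                             nMirna = 150L, nPirna = 50L,
                             plantedEffects = defaultPlantedEffects(),
                             confoundedFeatures = defaultConfoundedFeatures(),
                             nbDispersion = 10,
                             libsizeLogMean = log(3e5), libsizeLogSd = 0.4,
                             baselineLogSd = 2,
                             nBatches = 2L, batchSd = 0.2,
                             ageRangeControl = c(60, 84),
                             ageRangeCase = c(60, 84),
                             sexRatio = 0.5, seed = 1L,
                             baselineSeed = 20210521L) {
    new("SimulationConfig",
        nControl = as.integer(nControl), nCase = as.integer(nCase),
        nMirna = as.integer(nMirna), nPirna = as.integer(nPirna),
        plantedEffects = as.data.frame(plantedEffects),
        confoundedFeatures = as.data.frame(confoundedFeatures),
        nbDispersion = nbDispersion,
        libsizeLogMean = libsizeLogMean, libsizeLogSd = libsizeLogSd,
        baselineLogSd = baselineLogSd,
        nBatches = as.integer(nBatches), batchSd = batchSd,
        ageRangeControl = ageRangeControl, ageRangeCase = ageRangeCase,
        sexRatio = sexRatio, seed = as.integer(seed),
        baselineSeed = as.integer(baselineSeed))
}

#' @describeIn simulationConfig default planted truth: three miRNAs up, two
#'   piRNAs up and one piRNA down in cases (|log2FC| = 1.5).
#' @param log2fc absolute planted log2 fold change.
#' @export
defaultPlantedEffects <- function(log2fc = 1.5) {
    data.frame(
        feature_id = c("miR-27a-3p", "miR-30a-5p", "miR-34c-5p",
                       "piR_019949", "piR_020364", "piR_019324"),
        log2fc = c(log2fc, log2fc, log2fc, log2fc, log2fc, -log2fc))
}

#' @describeIn simulationConfig default age-confounded decoys (one per kind,
#'   0.08 log2 units per year).
#' @param age_slope log2 change per year of age.
#' @export
defaultConfoundedFeatures <- function(age_slope = 0.08) {
    data.frame(feature_id = c("miR-agedecoy-1", "piR_agedecoy_1"),
               age_slope = age_slope)
}

#' Simulate a small-RNA cohort study with planted ground truth
#'
#' Draws a feature-by-sample matrix of negative-binomial counts whose mean is
#' `libsize_s * baseline_f * 2^(case_s * lfc_f) * 2^((age_s - mean age) *
#' slope_f) * 2^(batch effect)`, with lognormal library sizes and baseline
#' abundances, planted case/control log2 fold changes, age-driven decoy
#' features, and multiplicative per-(batch, feature) center effects. Sample
#' covariates (diagnosis, batch, age, sex) are generated alongside; CSF
#' protein biomarkers obeying the clinical AD rule can be added via
#' [simulateBiomarkers()].
#'
#' @param config a [simulationConfig()].
#' @param role cohort role for the resulting [SncExperiment-class].
#' @param biomarkers if `TRUE` (default), also draw pTau/Abeta42/Abeta40.
#' @return An `SncExperiment`; `metadata(x)$planted` and
#'   `metadata(x)$confounded` record the generative truth.
#' @examples
#' se <- simulateStudy(simulationConfig(nControl = 5, nCase = 5, seed = 7))
#' metadata(se)$planted
#' @importFrom stats rnorm rlnorm rnbinom runif rbinom
#' @export
simulateStudy <- function(config = simulationConfig(), role = "unassigned",
                          biomarkers = TRUE) {
    validObject(config)
    n0 <- config@nControl; n1 <- config@nCase; n <- n0 + n1
    diagnosis <- rep(c("control", "AD"), c(n0, n1))
    case <- as.numeric(diagnosis == "AD")

    planted <- config@plantedEffects
    confounded <- config@confoundedFeatures
    mirIds <- .makeFeatureIds(planted, confounded, config@nMirna, "miRNA")
    pirIds <- .makeFeatureIds(planted, confounded, config@nPirna, "piRNA")
    ids <- c(mirIds, pirIds)
    kind <- rep(c("miRNA", "piRNA"), c(length(mirIds), length(pirIds)))
    nf <- length(ids)

    lfc <- stats::setNames(numeric(nf), ids)
    if (nrow(planted)) lfc[planted$feature_id] <- planted$log2fc
    slope <- stats::setNames(numeric(nf), ids)
    if (nrow(confounded)) slope[confounded$feature_id] <- confounded$age_slope

    ## population-level baseline profile: its own stream, so that cohorts
    ## with different subject seeds share the same underlying sncRNA
    ## abundances (the generative truth of one study population)
    set.seed(.subSeed(config@baselineSeed, 5L))
    share <- exp(rnorm(nf, 0, config@baselineLogSd))
    ## planted / confounded features emulate detectable sncRNAs: their
    ## baseline abundance is drawn from the upper half of the profile
    fixed <- c(planted$feature_id, confounded$feature_id)
    share[ids %in% fixed] <-
        exp(abs(rnorm(sum(ids %in% fixed), 0, config@baselineLogSd)))
    share <- share / sum(share)

    set.seed(.subSeed(config@seed, 1L))
    age <- numeric(n)
    age[case == 0] <- runif(n0, config@ageRangeControl[1],
                            config@ageRangeControl[2])
    age[case == 1] <- runif(n1, config@ageRangeCase[1],
                            config@ageRangeCase[2])
    midAge <- mean(c(config@ageRangeControl, config@ageRangeCase))
    sex <- ifelse(rbinom(n, 1, config@sexRatio) == 1, "F", "M")
    batch <- sample(rep_len(seq_len(config@nBatches), n))
    libsize <- rlnorm(n, config@libsizeLogMean, config@libsizeLogSd)

    batchEff <- matrix(rnorm(nf * config@nBatches, 0, config@batchSd),
                       nf, config@nBatches)

    logMu <- outer(log2(share), log2(libsize), "+") +
        outer(lfc, case) +
        outer(slope, age - midAge) +
        batchEff[, batch, drop = FALSE]
    mu <- 2^logMu
    counts <- matrix(rnbinom(nf * n, mu = mu, size = config@nbDispersion),
                     nf, n,
                     dimnames = list(ids, sprintf("S%03d", seq_len(n))))
    storage.mode(counts) <- "integer"

    samples <- data.frame(diagnosis = diagnosis,
                          batch = paste0("B", batch),
                          age = age, sex = sex,
                          row.names = colnames(counts))
    se <- SncExperiment(counts, samples, kind = kind, role = role)
    metadata(se)$planted <- planted
    metadata(se)$confounded <- confounded
    se <- .addProvenance(se, paste0("simulated: seed=", config@seed))
    if (biomarkers)
        se <- simulateBiomarkers(se, seed = .subSeed(config@seed, 2L))
    se
}

.makeFeatureIds <- function(planted, confounded, nTotal, kindWanted) {
    pick <- function(df) {
        if (!nrow(df)) return(character())
        k <- ifelse(grepl("^piR", df$feature_id), "piRNA", "miRNA")
        df$feature_id[k == kindWanted]
    }
    fixed <- c(pick(planted), pick(confounded))
    if (length(fixed) > nTotal)
        stop("more planted/confounded ", kindWanted,
             " features than nTotal allows")
    prefix <- if (kindWanted == "piRNA") "piR_sim_" else "miR-sim-"
    nFill <- nTotal - length(fixed)
    c(fixed, sprintf("%s%03d", prefix, seq_len(nFill)))
}

#' Add CSF protein biomarkers consistent with the clinical AD rule
#'
#' Draws per-subject Abeta42, total Tau, pTau and Abeta40 values (pg/ml) such
#' that AD-labelled subjects (and MCI converters) satisfy the diagnostic rule
#' Abeta42 < 450 pg/ml and total Tau > 200 pg/ml, while controls (and stable
#' MCI) satisfy the inverse. pTau is generated as a noisy linear function of
#' Tau; Abeta40 is positive so the Abeta42/40 ratio is always defined (and
#' lower in cases).
#'
#' @param x an [SncExperiment-class] (biomarker columns are added to
#'   `colData`) or a `data.frame` with a `diagnosis` column.
#' @param seed integer seed.
#' @param ptauNoiseSd SD of the pTau residual around its Tau-linear mean.
#' @return Object of the same class as `x` with columns `Abeta42`, `Tau`,
#'   `pTau`, `Abeta40` added.
#' @export
simulateBiomarkers <- function(x, seed = 1L, ptauNoiseSd = 3) {
    tab <- if (is(x, "SncExperiment")) as.data.frame(colData(x)) else
        as.data.frame(x)
    if (nrow(tab) == 0L) {
        for (cn in c("Abeta42", "Tau", "pTau", "Abeta40"))
            tab[[cn]] <- numeric(0)
        return(.returnBiomarkers(x, tab))
    }
    if (!"diagnosis" %in% colnames(tab))
        stop("a 'diagnosis' column is required")
    known <- c("control", "AD", "MCI_stable", "MCI_converter")
    bad <- setdiff(unique(tab$diagnosis), known)
    if (length(bad))
        stop("unknown diagnosis label(s): ", paste(bad, collapse = ", "))
    set.seed(seed)
    n <- nrow(tab)
    pos <- tab$diagnosis %in% c("AD", "MCI_converter")
    ab42 <- ifelse(pos, runif(n, 260, 440), runif(n, 460, 900))
    tau <- ifelse(pos, runif(n, 250, 700), runif(n, 90, 195))
    ptau <- pmax(1, 8 + 0.09 * tau + rnorm(n, 0, ptauNoiseSd))
    ratio <- ifelse(pos, runif(n, 0.03, 0.06), runif(n, 0.08, 0.12))
    tab$Abeta42 <- ab42
    tab$Tau <- tau
    tab$pTau <- ptau
    tab$Abeta40 <- ab42 / ratio
    .returnBiomarkers(x, tab)
}

.returnBiomarkers <- function(x, tab) {
    if (is(x, "SncExperiment")) {
        for (cn in c("Abeta42", "Tau", "pTau", "Abeta40"))
            colData(x)[[cn]] <- tab[[cn]]
        .addProvenance(x, "biomarkers simulated")
    } else tab
}

#' Simulate paired cellular and exosomal expression profiles
#'
#' Generates per-feature log-expression values for a parental-cell fraction
#' and its released exosomes with a chosen population Pearson correlation
#' `rho` (via a Gaussian copula-free bivariate construction: exosome =
#' rho * cell + sqrt(1 - rho^2) * independent noise, on the standardized
#' scale). Optionally appends independent decoy features with true
#' correlation zero. Feature kinds alternate miRNA/piRNA so per-class
#' correlations can be assessed downstream.
#'
#' @param nFeatures number of paired features (>= 3).
#' @param rho target population correlation in [-1, 1]; `rho = 1` yields an
#'   exact linear dependence.
#' @param nNoise number of additional independent features appended.
#' @param seed integer seed.
#' @param meanLog2,sdLog2 location/scale of the log2 expression marginals.
#' @return data.frame(feature_id, kind, cell, exosome, class) where `class`
#'   is `"paired"` or `"noise"`.
#' @export
simulatePairedCellExosome <- function(nFeatures, rho, nNoise = 0L, seed = 1L,
                                      meanLog2 = 6, sdLog2 = 2) {
    if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
    if (nFeatures < 3) stop("nFeatures must be >= 3")
    set.seed(seed)
    z1 <- rnorm(nFeatures)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(nFeatures)
    cell <- meanLog2 + sdLog2 * z1
    exo <- meanLog2 + sdLog2 * z2
    cls <- rep("paired", nFeatures)
    if (nNoise > 0) {
        cell <- c(cell, rnorm(nNoise, meanLog2, sdLog2))
        exo <- c(exo, rnorm(nNoise, meanLog2, sdLog2))
        cls <- c(cls, rep("noise", nNoise))
    }
    nTot <- nFeatures + nNoise
    kind <- rep(c("miRNA", "piRNA"), length.out = nTot)
    data.frame(
        feature_id = sprintf("%s%03d",
                             ifelse(kind == "piRNA", "piR_pair_", "miR-pair-"),
                             seq_len(nTot)),
        kind = kind, cell = cell, exosome = exo, class = cls)
}

#' Simulate a toy gene model with small-RNA loci of known genomic context
#'
#' Lays out `nGenes` non-overlapping multi-exon genes (random strand, 2-5
#' exons each) on a single synthetic chromosome and scatters piRNA-sized
#' loci (26-31 nt) into known contexts: wholly inside the strand-aware first
#' exon, inside a later exon, inside an intron, or in intergenic space. The
#' per-locus truth category supports oracle testing of [annotateLoci()].
#'
#' @param nGenes number of genes (>= 1).
#' @param seed integer seed.
#' @param nLoci number of loci to place.
#' @return list with `exons` (a `GRanges` with `gene_id`, `transcript_id`,
#'   `exon_rank` in transcription order), `genes` (one range per gene) and
#'   `loci` (a `GRanges` with `locus_id` and `truth` in
#'   exon1/other_exon/intron/intergenic).
#' @importFrom GenomicRanges GRanges strand start end
#' @importFrom IRanges IRanges
#' @export
simulateGeneModel <- function(nGenes, seed = 1L, nLoci = 50L) {
    if (nGenes < 1) stop("nGenes must be >= 1")
    set.seed(seed)
    cursor <- 1000L
    exList <- list()
    geneRows <- list()
    for (g in seq_len(nGenes)) {
        nEx <- sample(2:5, 1)
        exW <- sample(80:300, nEx, replace = TRUE)
        inW <- if (nEx > 1) sample(100:500, nEx - 1, replace = TRUE) else
            integer()
        strand <- sample(c("+", "-"), 1)
        starts <- integer(nEx)
        pos <- cursor
        for (i in seq_len(nEx)) {
            starts[i] <- pos
            pos <- pos + exW[i] + if (i < nEx) inW[i] else 0L
        }
        ends <- starts + exW - 1L
        rank <- if (strand == "+") seq_len(nEx) else rev(seq_len(nEx))
        gid <- sprintf("GENE%03d", g)
        exList[[g]] <- data.frame(start = starts, end = ends,
                                  strand = strand, gene_id = gid,
                                  transcript_id = paste0(gid, ".t1"),
                                  exon_rank = rank)
        geneRows[[g]] <- data.frame(start = starts[1], end = ends[nEx],
                                    strand = strand, gene_id = gid)
        cursor <- ends[nEx] + sample(600:1500, 1)
    }
    exdf <- do.call(rbind, exList)
    gdf <- do.call(rbind, geneRows)
    chrLen <- cursor + 2000L
    exons <- GRanges("chrS", IRanges(exdf$start, exdf$end),
                     strand = exdf$strand, gene_id = exdf$gene_id,
                     transcript_id = exdf$transcript_id,
                     exon_rank = exdf$exon_rank)
    genes <- GRanges("chrS", IRanges(gdf$start, gdf$end),
                     strand = gdf$strand, gene_id = gdf$gene_id)

    cats <- sample(c("exon1", "other_exon", "intron", "intergenic"),
                   nLoci, replace = TRUE)
    multi <- vapply(exList, nrow, 1L) > 1L
    loci <- vector("list", nLoci)
    for (i in seq_len(nLoci)) {
        len <- sample(26:31, 1)
        cat_i <- cats[i]
        if (cat_i %in% c("other_exon", "intron") && !any(multi))
            cat_i <- cats[i] <- "exon1"
        if (cat_i == "intergenic") {
            repeat {
                st <- sample.int(chrLen - len, 1)
                cand <- c(st, st + len - 1L)
                if (!any(cand[1] <= gdf$end & cand[2] >= gdf$start)) break
            }
            loci[[i]] <- data.frame(start = cand[1], end = cand[2],
                                    strand = sample(c("+", "-"), 1))
        } else {
            gi <- if (cat_i == "exon1") sample.int(nGenes, 1) else
                sample(which(multi), 1)
            ex <- exList[[gi]]
            if (cat_i == "exon1") {
                row <- ex[ex$exon_rank == 1L, ]
                lo <- row$start; hi <- row$end
            } else if (cat_i == "other_exon") {
                laterRanks <- ex$exon_rank[ex$exon_rank >= 2L]
                r <- if (length(laterRanks) == 1L) laterRanks else
                    sample(laterRanks, 1)
                row <- ex[ex$exon_rank == r, ]
                lo <- row$start; hi <- row$end
            } else {
                j <- sample.int(nrow(ex) - 1L, 1)
                lo <- ex$end[j] + 1L; hi <- ex$start[j + 1L] - 1L
            }
            st <- sample(lo:(hi - len + 1L), 1)
            loci[[i]] <- data.frame(start = st, end = st + len - 1L,
                                    strand = ex$strand[1])
        }
    }
    ldf <- do.call(rbind, loci)
    lociGR <- GRanges("chrS", IRanges(ldf$start, ldf$end),
                      strand = ldf$strand,
                      locus_id = sprintf("piR_locus_%04d", seq_len(nLoci)),
                      truth = cats)
    list(exons = exons, genes = genes, loci = lociGR)
}
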