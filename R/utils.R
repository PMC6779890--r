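## Internal helpers shared across modules.

## Derive a reproducible sub-seed (< 2^31) from a master seed and a stream
## index, so each stochastic stage draws from its own named stream.
.subSeed <- function(seed, stream) {
    as.integer((abs(as.numeric(seed)) * 48271 + stream * 7919) %% 2147483647)
}

## Coerce sample labels to the canonical two-level factor control < case.
## Accepts a factor/character of arbitrary two-level labels, a logical
## (TRUE = case), or diagnosis labels from the clinical vocabulary
## (AD / MCI_converter -> case; control / MCI_stable -> control).
.asGroups <- function(groups) {
    if (is.logical(groups))
        return(factor(ifelse(groups, "case", "control"),
                      levels = c("control", "case")))
    g <- as.character(groups)
    diagMap <- c(control = "control", MCI_stable = "control",
                 AD = "case", MCI_converter = "case",
                 case = "case")
    if (all(g %in% names(diagMap)))
        g <- unname(diagMap[g])
    lev <- unique(g)
    if (length(lev) != 2L)
        stop("exactly two group labels required, got: ",
             paste(lev, collapse = ", "))
    if (all(sort(lev) == c("case", "control")))
        lev <- c("control", "case")
    factor(g, levels = lev)
}

## Diagnosis-derived groups for an SncExperiment.
.seGroups <- function(x) {
    if (!"diagnosis" %in% colnames(colData(x)))
        stop("colData lacks a 'diagnosis' column; pass groups explicitly")
    .asGroups(colData(x)$diagnosis)
}

## Welch-standardized absolute mean difference, vectorized over many label
## assignments at once. X is features x samples; G is a samples x B 0/1
## matrix, one column per label assignment (1 = case). Returns features x B.
## Implemented with two matrix products so permutation nulls cost two BLAS
## calls rather than B full passes.
.morScoreMat <- function(X, G, eps = 1e-8) {
    n <- ncol(X)
    n1 <- colSums(G)
    n0 <- n - n1
    if (any(n1 < 2) || any(n0 < 2))
        stop("both groups need at least 2 samples")
    rs <- rowSums(X)
    rq <- rowSums(X * X)
    S1 <- X %*% G
    Q1 <- (X * X) %*% G
    m1 <- sweep(S1, 2, n1, "/")
    m0 <- sweep(rs - S1, 2, n0, "/")
    v1 <- sweep(Q1 - sweep(m1 * m1, 2, n1, "*"), 2, n1 - 1, "/")
    v0 <- sweep((rq - Q1) - sweep(m0 * m0, 2, n0, "*"), 2, n0 - 1, "/")
    se <- sqrt(pmax(sweep(v1, 2, n1, "/") + sweep(v0, 2, n0, "/"), 0))
    abs(m1 - m0) / pmax(se, eps)
}

## Empirical upper quantile used for permutation critical values:
## the smallest value v in the pooled null with
## (#null <= v) / N >= 1 - alpha (sorted-order statistic at
## ceiling((1 - alpha) * N)).
.nullQuantile <- function(null, alpha) {
    s <- sort(null)
    s[ceiling((1 - alpha) * length(s))]
}

## Stratified indices: sample within each class with replacement, preserving
## class sizes.
.stratifiedResample <- function(groups) {
    idx <- seq_along(groups)
    unlist(lapply(split(idx, groups), function(i)
        i[sample.int(length(i), length(i), replace = TRUE)]),
        use.names = FALSE)
}

## All C(n, n1) case-assignment indicator matrices (n x B), or NULL when the
## enumeration would exceed `limit`.
.enumerateArrangements <- function(n, n1, limit = 10000) {
    total <- choose(n, n1)
    if (total > limit) return(NULL)
    combos <- utils::combn(n, n1)
    G <- matrix(0, n, ncol(combos))
    G[cbind(as.vector(combos),
            rep(seq_len(ncol(combos)), each = n1))] <- 1
    G
}

## Random case-assignment indicators: B label permutations of the observed
## group vector.
.randomArrangements <- function(groups, B) {
    n <- length(groups)
    case <- groups == levels(groups)[2]
    G <- matrix(0, n, B)
    for (b in seq_len(B))
        G[sample.int(n), b] <- as.numeric(case)
    G
}
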