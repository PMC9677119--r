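## Shared fixtures and independent oracles for the test suite. Oracles
## deliberately avoid the package's own code paths.

## The 20 printed Moon side-chain values, hard-coded independently of
## the package registry.
MOON_REF <- c(
    F =  1.43, L =  1.26, I =  1.15, P =  1.13, Y =  0.94,
    V =  0.80, M =  0.79, W =  0.63, A =  0.46, C =  0.24,
    E = -0.27, G = -0.30, T = -0.33, S = -0.35, D = -0.85,
    Q = -0.88, N = -1.08, R = -1.19, H = -1.65, K = -1.93)

AA20 <- names(MOON_REF)

## Per-residue sum oracle: split and add, nothing shared with
## peptideHydrophobicity()'s vectorised path.
oracleHydro <- function(peptides) {
    vapply(strsplit(peptides, ""), function(rs) sum(MOON_REF[rs]),
           numeric(1))
}

## Random peptide helper (test-local, independent of the generator).
randomPeptides <- function(n, len = 9) {
    vapply(seq_len(n), function(i)
        paste(sample(AA20, len, replace = TRUE), collapse = ""),
        character(1))
}

## Confusion-count oracle: one explicit loop over records.
oracleConfusion <- function(actual, predicted) {
    tp <- fp <- tn <- fn <- 0L
    for (i in seq_along(actual)) {
        if (actual[i] && predicted[i]) tp <- tp + 1L
        else if (!actual[i] && predicted[i]) fp <- fp + 1L
        else if (!actual[i] && !predicted[i]) tn <- tn + 1L
        else fn <- fn + 1L
    }
    c(tp = tp, fp = fp, tn = tn, fn = fn)
}

## Mann-Whitney concordance oracle for AUC: exhaustive enumeration of
## positive-negative pairs, ties counting one half.
oracleAUC <- function(scores, actual) {
    pos <- scores[actual]
    neg <- scores[!actual]
    tot <- 0
    for (p in pos)
        for (q in neg)
            tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    tot / (length(pos) * length(neg))
}

## Closed-form Welch t-test oracle.
oracleWelch <- function(a, b) {
    na <- length(a); nb <- length(b)
    va <- sum((a - mean(a))^2) / (na - 1)
    vb <- sum((b - mean(b))^2) / (nb - 1)
    se2 <- va / na + vb / nb
    t <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(t), df)
    list(t = t, df = df, p = p)
}

## Closed-form pooled t-test oracle.
oraclePooled <- function(a, b) {
    na <- length(a); nb <- length(b)
    sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
    p <- 2 * stats::pt(-abs(t), df)
    list(t = t, df = df, p = p)
}

## Small well-formed PredictorRun fixture.
fixtureRun <- function() {
    PredictorRun(
        peptide = c("AAAAAAAAA", "KKKKKKKKK", "LLLLLLLLL", "GGGGGGGGG"),
        predicted_score = c(0.70, 0.551, 0.90, 0.10),
        strong_binder = c(TRUE, TRUE, TRUE, FALSE),
        measured_score = c(1, 0, 1, 0),
        assay = c("EL", "EL", "BA", "BA"),
        tool = "toolX", allele = "HLA-A*02:01")
}
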