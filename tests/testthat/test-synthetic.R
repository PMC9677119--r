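test_that("background peptides follow the requested residue frequencies", {
    expect_identical(genBackgroundPeptides(0), character(0))

    degenerate <- residueFreqs("uniform") * 0
    degenerate["A"] <- 1
    expect_identical(unique(genBackgroundPeptides(5, 4, degenerate,
                                                  seed = 1)), "AAAA")

    peps <- genBackgroundPeptides(10000, 9, seed = 99)
    tab <- table(strsplit(paste(peps, collapse = ""), "")[[1]])
    freq <- as.numeric(tab[AA20]) / (10000 * 9)
    se <- sqrt((1 / 20) * (19 / 20) / (10000 * 9))
    expect_true(all(abs(freq - 1 / 20) < 4 * se))

    bad <- residueFreqs("uniform"); bad["A"] <- 0.5
    expect_error(genBackgroundPeptides(5, 9, bad), "sum to 1")
})

test_that("motif presets score anchor matches above mismatches", {
    a2 <- motifPreset("A2")
    expect_gt(trueBindingScore(a2, "ALAAAAAAL"),
              trueBindingScore(a2, "AGAAAAAAG"))
    b27 <- motifPreset("B27")
    expect_gt(trueBindingScore(b27, "ARAAAAAAA"),
              trueBindingScore(b27, "AAAAAAAAA"))
    b8 <- motifPreset("B8")
    expect_gt(trueBindingScore(b8, "ALRAKAAAL"),
              trueBindingScore(b8, "ALAAAAAAL"))

    ## scores bounded in (0, 1) for random input
    s <- trueBindingScore(a2, genBackgroundPeptides(500, 9, seed = 4))
    expect_true(all(s > 0 & s < 1))
    ## deterministic
    expect_identical(trueBindingScore(a2, "ALAAAAAAL"),
                     trueBindingScore(a2, "ALAAAAAAL"))
    expect_error(trueBindingScore(a2, "ALAA"), "anchor position")
})

test_that("predictor scores reduce to the truth in the noise-free limit", {
    peps <- genBackgroundPeptides(300, 9, seed = 5)
    true <- trueBindingScore(motifPreset("A2"), peps)
    pred <- genPredictorScores(peps, true, BiasedPredictor(noiseSd = 0,
                                                           beta = 0))
    expect_lte(max(abs(pred - true)), 1e-6)
    expect_true(all(pred > 0 & pred < 1))
})

test_that("a positive beta tilts residuals with hydrophobicity", {
    peps <- genBackgroundPeptides(2000, 9, seed = 6)
    true <- trueBindingScore(motifPreset("A2"), peps)
    pred <- genPredictorScores(peps, true,
                               BiasedPredictor(noiseSd = 0.5, beta = 0.4),
                               seed = 7)
    h <- peptideHydrophobicity(peps)
    resid <- qlogis(pmin(pmax(pred, 1e-6), 1 - 1e-6)) -
        qlogis(pmin(pmax(true, 1e-6), 1 - 1e-6))
    expect_gt(cor(resid, h, method = "spearman"), 0.5)

    ## fixed seed reproduces scores exactly
    pred2 <- genPredictorScores(peps, true,
                                BiasedPredictor(noiseSd = 0.5, beta = 0.4),
                                seed = 7)
    expect_identical(pred, pred2)
})

test_that("bias estimation recovers the injected coefficient", {
    peps <- genBackgroundPeptides(20000, 9, seed = 8)
    true <- trueBindingScore(motifPreset("A2"), peps)
    pred <- genPredictorScores(peps, true,
                               BiasedPredictor(noiseSd = 0.5, beta = 0.4),
                               seed = 9)
    est <- estimateBias(peps, true, pred)
    expect_lt(abs(est$beta_hat - 0.4) / 0.4, 0.1)
})

test_that("training sets honour the spec's fractions and EL binarity", {
    spec0 <- TrainingSetSpec(n = 2000, nonExtremeFraction = 0,
                             baFraction = 0.2)
    ts0 <- genTrainingSet(spec0, seed = 10)
    expect_true(all(ts0$measured_score %in% c(0, 1)))

    ts <- genTrainingSet(TrainingSetSpec(n = 5000), seed = 11)
    el <- ts$measured_score[ts$assay == "EL"]
    expect_true(all(el %in% c(0, 1)))
    nonx <- mean(ts$measured_score > 0 & ts$measured_score < 1)
    se <- sqrt(0.15 * 0.85 / 5000)
    expect_lt(abs(nonx - 0.15), 4 * se)
    ## non-extreme records only among BA
    expect_true(all(ts$assay[ts$measured_score > 0 &
                                 ts$measured_score < 1] == "BA"))

    expect_error(TrainingSetSpec(nonExtremeFraction = 0.5,
                                 baFraction = 0.2), "cannot exceed")

    ## EL-only spec: everything binary
    el_only <- genTrainingSet(TrainingSetSpec(n = 1000,
                                              nonExtremeFraction = 0,
                                              baFraction = 0),
                              seed = 12)
    expect_true(all(el_only$measured_score %in% c(0, 1)))
    expect_true(all(el_only$assay == "EL"))
})

test_that("the binarisation threshold tracks the binder fraction", {
    ts <- genTrainingSet(TrainingSetSpec(n = 20000, binderFraction = 0.05),
                         motif = motifPreset("A2"), seed = 13)
    rate <- mean(ts$measured_score[ts$assay == "EL"] == 1)
    ## A2's discrete motif classes make ~4% the closest achievable rate
    ## not exceeding 5%
    expect_gt(rate, 0.02)
    expect_lte(rate, 0.06)
})

test_that("synthetic proteomes are seeded, sized and FASTA-stable", {
    prot <- genSyntheticProteome(nProteins = 100, meanLength = 517,
                                 seed = 14)
    expect_equal(length(fragmentProteins(prot, k = 9)), 50900L)

    one <- genSyntheticProteome(nProteins = 1, meanLength = 9, seed = 15)
    expect_length(fragmentProteins(one, k = 9), 1L)

    f1 <- withr::local_tempfile(fileext = ".fasta")
    f2 <- withr::local_tempfile(fileext = ".fasta")
    Biostrings::writeXStringSet(genSyntheticProteome(10, 50, seed = 16), f1)
    Biostrings::writeXStringSet(genSyntheticProteome(10, 50, seed = 16), f2)
    expect_identical(readLines(f1), readLines(f2))

    expect_error(genSyntheticProteome(5, meanLength = 4), "minLength")

    varied <- genSyntheticProteome(30, 50, sdLength = 20, seed = 17)
    expect_gt(length(unique(Biostrings::width(varied))), 1L)
    expect_true(all(Biostrings::width(varied) >= 9))
})

test_that("generators leave the caller's RNG stream untouched", {
    set.seed(500)
    before <- .Random.seed
    invisible(genBackgroundPeptides(50, 9, seed = 1))
    invisible(genTrainingSet(TrainingSetSpec(n = 100), seed = 2))
    expect_identical(.Random.seed, before)
})
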