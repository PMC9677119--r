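test_that("a perfect predictor audits to all-ones metrics and AUC 1", {
    set.seed(120)
    pep <- randomPeptides(60)
    measured <- rep(c(1, 0), times = c(12, 48))
    run <- PredictorRun(pep, predicted_score = measured,
                        strong_binder = measured == 1,
                        measured_score = measured,
                        tool = "perfect")
    rep <- runTrainingAudit(run)
    r <- reportContent(rep)$runs[[1]]
    expect_equal(r$threshold, 1)
    expect_equal(r$confusion$fp + r$confusion$fn, 0L)
    all_row <- r$stratified_metrics[1, ]
    expect_equal(unlist(all_row[c("accuracy", "precision",
                                  "recall", "f1")]),
                 c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
    expect_equal(r$roc$auc, 1)
    expect_equal(r$binder_count, 12L)
})

test_that("the training audit reproduces the injected-bias signature", {
    pair <- genBiasedPair(n = 4000, seed = 42)
    rep <- runTrainingAudit(list(pair$unbiased, pair$biased))
    expect_identical(reportMode(rep), "training")
    ct <- reportContent(rep)
    u <- ct$runs[[1]]; b <- ct$runs[[2]]
    expect_gt(b$binder_hydro$mean, u$binder_hydro$mean)
    su <- u$stratified_metrics; sb <- b$stratified_metrics
    expect_lt(sb$precision[sb$peptide_case == "Hydrophobic only"],
              su$precision[su$peptide_case == "Hydrophobic only"])
    expect_lt(sb$recall[sb$peptide_case == "Hydrophilic only"],
              su$recall[su$peptide_case == "Hydrophilic only"])
    ## cross-run comparison present, BA/EL contrast present
    expect_length(ct$comparisons, 1L)
    expect_false(is.null(ct$ba_el))
    expect_identical(ct$ba_el$group_a, "BA")
})

test_that("training audit errors are annotated with the run label", {
    run <- PredictorRun(c("AAAAAAAAA", "GGGGGGGGG"), c(0.9, 0.1),
                        strong_binder = FALSE,
                        measured_score = c(1, 0), tool = "flagless")
    expect_error(runTrainingAudit(run), "flagless")
    ## a fixed threshold rescues a flagless run
    rep <- runTrainingAudit(run, thresholds = 0.5)
    expect_equal(reportContent(rep)$runs[[1]]$threshold, 0.5)

    nomeas <- PredictorRun("AAAAAAAAA", 0.9, strong_binder = TRUE)
    expect_error(runTrainingAudit(nomeas), "measured score")
})

test_that("proteome audits carry no actual-label sections", {
    prot <- genSyntheticProteome(nProteins = 5, meanLength = 80, seed = 21)
    pool <- fragmentProteins(prot, k = 9)
    true <- trueBindingScore(motifPreset("A2"), pool)
    mk <- function(label, beta) {
        pred <- genPredictorScores(pool, true,
                                   BiasedPredictor(label, 0.5, beta),
                                   seed = 22)
        PredictorRun(pool, pred, tool = label)
    }
    rep <- runProteomeAudit(prot, list(mk("plain", 0), mk("tilted", 0.4)),
                            thresholds = c(plain = 0.6, tilted = 0.6))
    expect_identical(reportMode(rep), "proteome")
    ct <- reportContent(rep)
    expect_equal(ct$pool$n, length(pool))
    for (r in ct$runs) {
        expect_null(r$confusion)
        expect_null(r$roc)
        expect_null(r$stratified_metrics)
    }
    ## the hydrophobicity-biased run's binders are more hydrophobic than
    ## the pool by construction
    tilted <- ct$runs[[2]]
    expect_gt(tilted$binder_hydro$mean, ct$pool$hydro$mean)

    expect_error(runProteomeAudit(pool, mk("plain", 0), thresholds = NULL),
                 "fixed thresholds")
    short <- Biostrings::AAStringSet(c(p1 = "MKT"))
    expect_error(runProteomeAudit(short, mk("plain", 0), thresholds = 0.5),
                 "shorter than 9")
})

test_that("identical runs under two labels compare with t = 0", {
    set.seed(23)
    pep <- randomPeptides(200)
    score <- runif(200)
    runs <- list(PredictorRun(pep, score, tool = "left"),
                 PredictorRun(pep, score, tool = "right"))
    rep <- runProteomeAudit(pep, runs, thresholds = 0.5)
    cmp <- reportContent(rep)$comparisons[[1]]
    expect_equal(cmp$t, 0)
    expect_equal(cmp$p, 1)
})

test_that("empty binder sets skip the comparison with a note", {
    set.seed(24)
    pep <- randomPeptides(50)
    runs <- list(PredictorRun(pep, runif(50, 0, 0.4), tool = "low"),
                 PredictorRun(pep, runif(50, 0.6, 1), tool = "high"))
    rep <- runProteomeAudit(pep, runs,
                            thresholds = c(low = 0.99, high = 0.5))
    ct <- reportContent(rep)
    expect_length(ct$comparisons, 0L)
    expect_length(ct$skipped_comparisons, 1L)
    expect_equal(ct$runs[[1]]$binder_count, 0L)
    expect_null(ct$runs[[1]]$binder_hydro)
})

test_that("report export is deterministic and JSON round-trips byte-exactly", {
    pair <- genBiasedPair(n = 1500, seed = 31)
    rep <- runTrainingAudit(list(pair$unbiased, pair$biased), seed = 31)
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    exportReport(rep, d1)
    exportReport(rep, d2)
    files <- list.files(d1)
    expect_true(all(c("report.json", "thresholds.tsv", "metrics_table.tsv",
                      "comparisons.tsv", "violin_data.tsv",
                      "audit_log.txt") %in% files))
    for (f in files)
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))

    back <- importReport(file.path(d1, "report.json"))
    expect_identical(reportMode(back), "training")
    d3 <- withr::local_tempdir()
    exportReport(back, d3)
    expect_identical(readLines(file.path(d3, "report.json")),
                     readLines(file.path(d1, "report.json")))
})

test_that("proteome reports omit ROC files and round-trip too", {
    set.seed(32)
    pep <- randomPeptides(300)
    run <- PredictorRun(pep, runif(300), tool = "only")
    rep <- runProteomeAudit(pep, run, thresholds = 0.9)
    d <- withr::local_tempdir()
    exportReport(rep, d)
    expect_false(any(grepl("^roc_points", list.files(d))))
    expect_false("metrics_table.tsv" %in% list.files(d))
    back <- importReport(file.path(d, "report.json"))
    d2 <- withr::local_tempdir()
    exportReport(back, d2)
    expect_identical(readLines(file.path(d, "report.json")),
                     readLines(file.path(d2, "report.json")))
})

test_that("the full pipeline is byte-reproducible under a fixed seed", {
    mkreport <- function() {
        pair <- genBiasedPair(n = 1000, seed = 77)
        runTrainingAudit(list(pair$unbiased, pair$biased), seed = 77)
    }
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    exportReport(mkreport(), d1)
    exportReport(mkreport(), d2)
    for (f in list.files(d1))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
})

test_that("binder counts in the report equal the labelled-set sizes", {
    pair <- genBiasedPair(n = 1200, seed = 55)
    rep <- runTrainingAudit(list(pair$unbiased, pair$biased))
    ct <- reportContent(rep)
    for (run in list(pair$unbiased, pair$biased)) {
        sec <- Filter(function(r) r$label == toolLabel(run), ct$runs)[[1]]
        expect_equal(sec$binder_count,
                     sum(labelPredictedBinders(run, sec$threshold)))
    }
})
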