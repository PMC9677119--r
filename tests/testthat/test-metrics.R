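test_that("confusion counts match the record-by-record tally", {
    cc <- confusionCounts(list(actual = c(TRUE, TRUE, FALSE, FALSE),
                               predicted = c(TRUE, FALSE, TRUE, FALSE)))
    expect_equal(c(cc@tp, cc@fn, cc@fp, cc@tn), c(1L, 1L, 1L, 1L))

    set.seed(101)
    actual <- runif(200) > 0.6
    cc2 <- confusionCounts(list(actual = actual, predicted = actual))
    expect_equal(cc2@fp + cc2@fn, 0L)

    predicted <- runif(200) > 0.4
    cc3 <- confusionCounts(list(actual = actual, predicted = predicted))
    o <- oracleConfusion(actual, predicted)
    expect_equal(c(cc3@tp, cc3@fp, cc3@tn, cc3@fn),
                 unname(o[c("tp", "fp", "tn", "fn")]))

    expect_error(confusionCounts(list(actual = logical(0),
                                      predicted = logical(0))), "no records")
})

test_that("metrics follow their formulas, with NA for 0/0 cases", {
    m <- computeMetrics(new("ConfusionCounts", tp = 1L, fp = 1L,
                            tn = 1L, fn = 1L))
    expect_equal(unlist(m[c("accuracy", "precision", "recall", "f1")]),
                 c(accuracy = 0.5, precision = 0.5, recall = 0.5, f1 = 0.5))

    perfect <- computeMetrics(new("ConfusionCounts", tp = 5L, fp = 0L,
                                  tn = 7L, fn = 0L))
    expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
                 c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

    degen <- computeMetrics(new("ConfusionCounts", tp = 0L, fp = 0L,
                                tn = 3L, fn = 2L))
    expect_true(is.na(degen$precision))
    expect_equal(degen$recall, 0)
    expect_true(is.na(degen$f1))

    expect_error(computeMetrics(new("ConfusionCounts", tp = 0L, fp = 0L,
                                    tn = 0L, fn = 0L)), "zero")
})

test_that("accuracy is label-symmetric; precision and recall are not", {
    set.seed(55)
    actual <- runif(120) > 0.7
    predicted <- runif(120) > 0.5
    m1 <- computeMetrics(confusionCounts(list(actual = actual,
                                              predicted = predicted)))
    m2 <- computeMetrics(confusionCounts(list(actual = !actual,
                                              predicted = !predicted)))
    expect_equal(m1$accuracy, m2$accuracy)
    expect_false(isTRUE(all.equal(m1$precision, m2$precision)))
    expect_false(isTRUE(all.equal(m1$recall, m2$recall)))
})

test_that("ROC is monotone, anchored, and its AUC is the concordance", {
    roc <- rocCurve(c(0.9, 0.8, 0.4, 0.3), c(TRUE, FALSE, TRUE, FALSE))
    expect_equal(aucValue(roc), 0.75)
    pts <- rocPoints(roc)
    expect_equal(pts$fpr[1], 0)
    expect_equal(pts$tpr[1], 0)
    expect_equal(pts$fpr[nrow(pts)], 1)
    expect_equal(pts$tpr[nrow(pts)], 1)
    expect_false(is.unsorted(pts$fpr))
    expect_false(is.unsorted(pts$tpr))

    sep <- rocCurve(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
    expect_equal(aucValue(sep), 1.0)
    ties <- rocCurve(rep(0.5, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
    expect_equal(aucValue(ties), 0.5)

    expect_error(rocCurve(c(0.1, 0.2), c(TRUE, TRUE)), "negative")
})

test_that("trapezoidal AUC equals exhaustive Mann-Whitney on random data", {
    set.seed(202)
    for (i in 1:20) {
        n <- sample(10:200, 1)
        ## coarse scores force ties
        scores <- round(runif(n), 1)
        actual <- runif(n) < 0.4
        if (!any(actual) || all(actual)) next
        expect_equal(aucValue(rocCurve(scores, actual)),
                     oracleAUC(scores, actual), tolerance = 1e-12)
    }
})

test_that("own AUC agrees with pROC on a shared instance", {
    skip_if_not_installed("pROC")
    set.seed(303)
    scores <- round(runif(150), 2)
    actual <- runif(150) < 0.3
    ours <- aucValue(rocCurve(scores, actual))
    theirs <- as.numeric(pROC::auc(pROC::roc(
        response = actual, predictor = scores, quiet = TRUE,
        direction = "<")))
    expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("stratified metrics partition the overall confusion counts", {
    set.seed(404)
    n <- 300
    run <- PredictorRun(randomPeptides(n), runif(n),
                        strong_binder = runif(n) > 0.9,
                        measured_score = runif(n))
    lab <- binderLabels(run)
    tab <- stratifiedMetrics(lab)
    expect_identical(tab$peptide_case,
                     c("All", "Hydrophobic only", "Hydrophilic only",
                       "Balanced only"))
    for (col in c("tp", "fp", "tn", "fn"))
        expect_equal(sum(tab[[col]][-1]), tab[[col]][1])
    expect_equal(sum(tab$tp[1], tab$fp[1], tab$tn[1], tab$fn[1]), n)
})

test_that("an empty stratum yields zero counts and NA metrics, no crash", {
    ## all-alanine peptides are all Hydrophobic (H = 4.14)
    run <- PredictorRun(rep("AAAAAAAAA", 4), c(0.9, 0.8, 0.2, 0.1),
                        strong_binder = c(TRUE, TRUE, FALSE, FALSE),
                        measured_score = c(1, 1, 0, 0))
    tab <- stratifiedMetrics(binderLabels(run))
    hydrophilic <- tab[tab$peptide_case == "Hydrophilic only", ]
    expect_equal(hydrophilic$tp + hydrophilic$fp +
                     hydrophilic$tn + hydrophilic$fn, 0L)
    expect_true(is.na(hydrophilic$accuracy))
    hydrophobic <- tab[tab$peptide_case == "Hydrophobic only", ]
    all_row <- tab[tab$peptide_case == "All", ]
    expect_equal(unlist(hydrophobic[-1]), unlist(all_row[-1]))
})
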