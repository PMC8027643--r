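test_that("confusion-matrix metrics reproduce the balanced-test row", {
    # 75/75 with Sn 0.893 and Sp 0.920 implies TP=67 FP=6 FN=8 TN=69
    r <- classificationMetrics(67, 6, 8, 69)
    expect_equal(truncateDecimals(r@accuracy), 0.906)
    expect_equal(truncateDecimals(r@f1), 0.905)
    expect_equal(truncateDecimals(r@mcc), 0.813)
    expect_equal(r@sensitivity, 67 / 75)
    expect_equal(r@specificity, 69 / 75)
})

test_that("degenerate confusion matrices are handled as defined", {
    perfect <- classificationMetrics(10, 0, 0, 10)
    expect_equal(c(perfect@sensitivity, perfect@specificity,
                   perfect@accuracy, perfect@f1, perfect@mcc),
                 rep(1, 5))
    # everything called positive on a balanced set: MCC 0 with warning
    expect_warning(allPos <- classificationMetrics(10, 10, 0, 0), "MCC")
    expect_equal(allPos@mcc, 0)
    expect_equal(allPos@accuracy, 0.5)
    expect_error(classificationMetrics(0, 0, 0, 0), "empty")
})

test_that("truncation (not rounding) matches the published convention", {
    expect_equal(truncateDecimals(0.8136), 0.813)
    expect_equal(truncateDecimals(0.7869), 0.786)
    expect_equal(truncateDecimals(0.9999), 0.999)
})

test_that("rank AUC equals the pair-count and trapezoid formulations", {
    expect_equal(rocAuc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
    expect_equal(rocAuc(c(1, 0, 1), c(0.9, 0.8, 0.7)), 0.5)
    expect_equal(rocAuc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
    expect_error(rocAuc(c(1, 1), c(0.2, 0.3)), "both classes")

    brute <- function(truth, scores) {
        pos <- scores[truth == 1]; neg <- scores[truth == 0]
        tot <- 0
        for (p in pos) for (q in neg)
            tot <- tot + (p > q) + 0.5 * (p == q)
        tot / (length(pos) * length(neg))
    }
    set.seed(2)
    for (i in 1:100) {
        truth <- c(rep(1, 8), rep(0, 8))
        scores <- sample(seq(0, 1, by = 0.1), 16, replace = TRUE)
        expect_equal(rocAuc(truth, scores), brute(truth, scores),
                     tolerance = 1e-12)
        # trapezoidal ROC integration via an independent implementation
        expect_equal(rocAuc(truth, scores),
                     as.numeric(pROC::auc(pROC::roc(truth, scores,
                                                    quiet = TRUE,
                                                    direction = "<"))),
                     tolerance = 1e-12)
    }
})

test_that("stratified folds are seeded, balanced and leak-free", {
    y <- rep(c(0L, 1L), each = 25)
    f1 <- pepCross:::.stratifiedFolds(y, 10, seed = 4)
    f2 <- pepCross:::.stratifiedFolds(y, 10, seed = 4)
    expect_identical(f1, f2)
    for (cl in 0:1) {
        sizes <- table(f1[y == cl])
        expect_lte(diff(range(sizes)), 1)
    }
    expect_error(pepCross:::.stratifiedFolds(y, 30, seed = 1),
                 "smallest class")
})

test_that("cross-validation recovers a separable synthetic signal", {
    m <- smallFC4()
    cv <- crossValidate(m, folds = 5, seed = 7, grids = tinyGrids())
    expect_length(cv$foldAccuracy, 5L)
    expect_gte(cv$meanAccuracy, 0.9)
    cv2 <- crossValidate(m, folds = 5, seed = 7, grids = tinyGrids())
    expect_identical(cv$foldId, cv2$foldId)
    expect_identical(cv$foldAccuracy, cv2$foldAccuracy)
})

test_that("the reuse tuning mode runs and stays near the per-fold mode", {
    m <- smallFC4()
    cv <- crossValidate(m, folds = 3, seed = 1, grids = tinyGrids(),
                        tune = "reuse")
    expect_gte(cv$meanAccuracy, 0.9)
})

test_that("Kruskal-Wallis matches hand-ranked arithmetic", {
    same <- kruskalWallis(list(c(1, 2, 3), c(1, 2, 3)))
    expect_equal(same$H, 0, tolerance = 1e-12)
    expect_equal(same$p.value, 1, tolerance = 1e-12)

    kw <- kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))
    # ranks 1..6, R1 = 6, R2 = 15: H = 12/(6*7) * (36/3 + 225/3) - 3*7
    expect_equal(kw$H, 12 / 42 * (12 + 75) - 21, tolerance = 1e-12)

    mono <- kruskalWallis(list(exp(c(1, 2, 3)), exp(c(4, 5, 6))))
    expect_equal(mono$H, kw$H, tolerance = 1e-12)

    ident <- kruskalWallis(list(rep(2, 4), rep(2, 3)))
    expect_equal(ident$H, 0)
    expect_equal(ident$p.value, 1)

    expect_error(kruskalWallis(list(1:3)), "two groups")
    expect_error(kruskalWallis(list(1:3, numeric(0))), "non-empty")
})
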