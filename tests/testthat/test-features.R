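test_that("the four compositions carry their published cardinalities", {
    expect_length(featureNames(featureComposition("FC1")), 64L)
    expect_length(featureNames(featureComposition("FC2")), 12L)
    expect_length(featureNames(featureComposition("FC3")), 76L)
    expect_length(featureNames(featureComposition("FC4")), 43L)

    fc4 <- featureComposition("FC4")
    expect_length(fc4@blocks$structural, 9L)
    expect_setequal(setdiff(featureNames(featureComposition("FC2")),
                            fc4@blocks$structural),
                    c("tPSA", "NRB", "HBD"))
    expect_equal(fc4@blocks$dpc,
                 paste0("DPC_", c("RR", "KK", "KR", "RQ", "RK",
                                  "GL", "GF", "LG", "GA", "VC")))
    expect_length(featureComposition("FC3")@blocks$dpc, 40L)
    expect_length(fc4@blocks$pseaac, 22L)
})

test_that("assembly produces ordered, deterministic rows", {
    ps <- PeptideSet(c(p = "RRRRR", q = "KRKWG"))
    m4 <- assembleFeatures(ps, "FC4")
    expect_equal(dim(featureValues(m4)), c(2L, 43L))
    expect_equal(colnames(featureValues(m4)),
                 featureNames(featureComposition("FC4")))
    # RRRRR: DPC_RR = 1, the other nine listed dipeptides 0
    row <- featureValues(m4)["p", ]
    expect_equal(unname(row[["DPC_RR"]]), 1)
    others <- paste0("DPC_", c("KK", "KR", "RQ", "RK", "GL", "GF",
                               "LG", "GA", "VC"))
    expect_equal(unname(row[others]), rep(0, 9))

    m2 <- assembleFeatures(ps, "FC2")
    expect_equal(dim(featureValues(m2)), c(2L, 12L))
    expect_equal(featureValues(m2)["q", ], structDescriptors("KRKWG"))

    again <- assembleFeatures(ps, "FC4")
    expect_identical(featureValues(again), featureValues(m4))

    short <- PeptideSet(c(s = "RK"))
    expect_error(assembleFeatures(short, "FC4"), "3 residues")
})

test_that("Kendall tau matches a brute-force tau-b pair count", {
    expect_equal(kendallTau(c(1, 2, 3), c(1, 2, 3)), 1)
    expect_equal(kendallTau(c(1, 2, 3), c(3, 2, 1)), -1)

    bruteTauB <- function(x, y) {
        n <- length(x); C <- 0; D <- 0; tx <- 0; ty <- 0
        for (i in 1:(n - 1)) for (j in (i + 1):n) {
            dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
            if (dx == 0 && dy == 0) next
            else if (dx == 0) tx <- tx + 1
            else if (dy == 0) ty <- ty + 1
            else if (dx == dy) C <- C + 1
            else D <- D + 1
        }
        (C - D) / sqrt((C + D + tx) * (C + D + ty))
    }
    expect_equal(kendallTau(c(1, 2, 2, 3), c(1, 2, 3, 3)),
                 bruteTauB(c(1, 2, 2, 3), c(1, 2, 3, 3)))
    set.seed(41)
    for (i in 1:10) {
        x <- sample(1:5, 12, replace = TRUE)
        y <- sample(1:5, 12, replace = TRUE)
        if (sd(x) == 0 || sd(y) == 0) next
        expect_equal(kendallTau(x, y), bruteTauB(x, y), tolerance = 1e-12)
    }
    expect_warning(v <- kendallTau(rep(1, 5), 1:5), "constant")
    expect_true(is.nan(v))
})

test_that("feature ranking is rank-based with name-ordered ties", {
    set.seed(9)
    n <- 1000
    lab <- rep(c(0L, 1L), n / 2)
    vals <- cbind(perfect = as.numeric(lab),
                  noise = rnorm(n),
                  dupA = NA, dupB = NA)
    vals[, "dupA"] <- vals[, "noise"]
    vals[, "dupB"] <- vals[, "noise"]
    rownames(vals) <- paste0("r", seq_len(n))
    m <- new("PeptideFeatureMatrix", values = vals, fc = "FC4", label = lab)
    rk <- rankFeatures(m)
    expect_equal(rk$feature[1], "perfect")
    expect_equal(rk$tau[1], 1)
    expect_lt(rk$tau[rk$feature == "noise"], 0.1)
    # duplicated columns tie and sort by name
    dupPos <- which(rk$feature %in% c("dupA", "dupB", "noise"))
    expect_equal(diff(dupPos), c(1L, 1L))
    expect_equal(rk$feature[dupPos], sort(c("dupA", "dupB", "noise")))

    # invariance to strictly monotone transforms
    vals2 <- vals
    vals2[, "noise"] <- exp(vals2[, "noise"])
    m2 <- new("PeptideFeatureMatrix", values = vals2, fc = "FC4",
              label = lab)
    expect_equal(rankFeatures(m2)$tau, rk$tau, tolerance = 1e-12)

    bad <- new("PeptideFeatureMatrix", values = vals, fc = "FC4",
               label = rep(1L, n))
    expect_error(rankFeatures(bad), "single-class")
})

test_that("feature matrices survive a CSV round trip", {
    m <- smallFC4()
    f <- tempfile(fileext = ".csv")
    writeFeatureMatrix(m, f)
    back <- readFeatureMatrix(f, fc = "FC4")
    expect_equal(featureValues(back), featureValues(m), tolerance = 1e-12)
    expect_equal(featureLabels(back), featureLabels(m))
})
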