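# Planted-signal matrix: one named structural column carries the label,
# everything else is seeded noise spread over the other groups.
plantedMatrix <- function(n = 300, seed = 7) {
    set.seed(seed)
    lab <- rep(c(1L, 0L), each = n / 2)
    vals <- cbind(NetC = lab * 4 + rnorm(n, sd = 0.5),
                  MW = rnorm(n),
                  f_Arg = rnorm(n),
                  DPC_RR = rnorm(n),
                  DPC_KK = rnorm(n),
                  PseAAC_A = rnorm(n),
                  PseAAC_tau1 = rnorm(n))
    rownames(vals) <- paste0("r", seq_len(n))
    new("PeptideFeatureMatrix", values = vals, fc = "FC4", label = lab)
}

test_that("grouped information normalises to one and finds the signal", {
    m <- plantedMatrix()
    gi <- groupedInformation(m, nTrees = 150, seed = 7)
    expect_equal(sum(gi), 1, tolerance = 1e-9)
    expect_true(all(gi >= 0))
    expect_gt(gi[["structural"]], 0.5)
})

test_that("pure-noise importances split close to group feature shares", {
    set.seed(13)
    n <- 200
    lab <- rep(c(1L, 0L), each = n / 2)
    vals <- matrix(rnorm(n * 8), n, 8)
    colnames(vals) <- c("MW", "NetC", "f_Arg", "f_Lys",
                        "DPC_RR", "DPC_KK", "PseAAC_A", "PseAAC_C")
    rownames(vals) <- paste0("r", seq_len(n))
    m <- new("PeptideFeatureMatrix", values = vals, fc = "FC4",
             label = lab)
    gi <- groupedInformation(m, nTrees = 300, seed = 5)
    share <- c(structural = 2, AAC = 2, DPC = 2, PseAAC = 2) / 8
    expect_true(all(abs(gi[names(share)] - share) < 0.1))
})

test_that("grouped information is stable under column permutation", {
    m <- plantedMatrix()
    perm <- new("PeptideFeatureMatrix",
                values = m@values[, c(4, 1, 6, 2, 7, 3, 5)],
                fc = "FC4", label = m@label)
    a <- groupedInformation(m, nTrees = 500, seed = 7)
    b <- groupedInformation(perm, nTrees = 500, seed = 7)
    expect_true(all(abs(a[names(b)] - b) < 0.05))
})

test_that("unassigned or doubly-assigned features are rejected", {
    m <- plantedMatrix()
    expect_error(groupedInformation(m, grouping = list(a = "NetC")),
                 "unassigned")
    g <- pepCross:::.defaultGrouping(colnames(m@values))
    g$extra <- "NetC"
    expect_error(groupedInformation(m, grouping = g), "more than one")
})

test_that("my entropy importances agree directionally with ranger", {
    m <- plantedMatrix()
    mine <- ertImportance(m, nTrees = 200, seed = 3)
    df <- data.frame(m@values, y = factor(m@label))
    rf <- ranger::ranger(y ~ ., data = df, num.trees = 200,
                         splitrule = "extratrees", importance = "impurity",
                         seed = 3)
    expect_equal(names(which.max(mine)), "NetC")
    expect_equal(names(which.max(rf$variable.importance)), "NetC")
})

test_that("PCA returns ordered variance ratios with centred projections", {
    set.seed(7)
    n <- 5000; d <- 10
    vals <- matrix(rnorm(n * d), n, d,
                   dimnames = list(paste0("r", 1:n), paste0("f", 1:d)))
    m <- new("PeptideFeatureMatrix", values = vals, fc = "FC2",
             label = rep(NA_integer_, n))
    pc <- pca3d(m)
    expect_equal(diff(pc$evr) <= 1e-12, c(TRUE, TRUE))
    expect_true(all(abs(pc$evr - 0.1) < 0.02))
    expect_equal(unname(colMeans(pc$projections)), rep(0, 3),
                 tolerance = 1e-9)
    expect_null(pc$bc)

    # rank-1 input: all variance on the first component
    v1 <- outer(rnorm(50), rnorm(5))
    dimnames(v1) <- list(paste0("r", 1:50), paste0("f", 1:5))
    m1 <- new("PeptideFeatureMatrix", values = v1, fc = "FC2",
              label = rep(NA_integer_, 50))
    pc1 <- suppressWarnings(pca3d(m1))
    expect_equal(pc1$evr[1], 1, tolerance = 1e-9)
    expect_equal(unname(pc1$evr[2:3]), c(0, 0), tolerance = 1e-9)
})

test_that("labelled PCA reports a class-overlap coefficient per PC", {
    m <- plantedMatrix()
    pc <- pca3d(m)
    expect_length(pc$bc, 3L)
    expect_true(all(pc$bc >= 0 & pc$bc <= 1))
    # the planted class separation leaks into the components, so at
    # least one of them shows clearly reduced overlap
    expect_lt(min(pc$bc), 0.8)
})

test_that("Bhattacharyya coefficient hits its closed-form anchors", {
    set.seed(21)
    a <- rnorm(500)
    expect_equal(bhattacharyyaCoefficient(a, a), 1, tolerance = 1e-12)
    expect_equal(bhattacharyyaCoefficient(runif(400, 0, 1),
                                          runif(400, 5, 6)), 0)
    # uniform on [0,1] vs uniform on [0,1/2]: BC -> 1/sqrt(2)
    u <- runif(4000, 0, 1); v <- runif(4000, 0, 0.5)
    expect_equal(bhattacharyyaCoefficient(u, v), 1 / sqrt(2),
                 tolerance = 0.03)
    # symmetry, and the all-identical edge case
    b <- rnorm(300, 2)
    expect_equal(bhattacharyyaCoefficient(a, b),
                 bhattacharyyaCoefficient(b, a))
    expect_equal(bhattacharyyaCoefficient(rep(3, 5), rep(3, 7)), 1)
    expect_error(bhattacharyyaCoefficient(numeric(0), 1:3), "empty")
})
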