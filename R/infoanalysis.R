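# ---- extremely randomized trees with entropy importance ----------------
#
# Minimal Extra-Trees ensemble used only for feature importance: at every
# node, K randomly chosen candidate features each receive one uniformly
# random cut-point in their node range; the candidate with the largest
# information gain (Shannon entropy decrease) wins. Importance of a
# feature is the total weighted entropy decrease it produced, averaged
# over trees.

.entropy <- function(y) {
    p <- tabulate(y + 1L, 2L) / length(y)
    p <- p[p > 0]
    -sum(p * log2(p))
}

.ertTree <- function(x, y, k, minSplit, importance) {
    n0 <- nrow(x)
    recurse <- function(idx) {
        n <- length(idx)
        ysub <- y[idx]
        h <- .entropy(ysub)
        if (n < minSplit || h == 0) return(invisible(NULL))
        # candidate features that still vary inside the node
        rng <- apply(x[idx, , drop = FALSE], 2L, range)
        varying <- which(rng[1L, ] < rng[2L, ])
        if (length(varying) == 0L) return(invisible(NULL))
        cand <- if (length(varying) <= k) varying else
            sample(varying, k)
        bestGain <- -Inf; bestFeat <- NA_integer_; bestLeft <- NULL
        for (f in cand) {
            cut <- stats::runif(1L, rng[1L, f], rng[2L, f])
            left <- idx[x[idx, f] < cut]
            if (length(left) == 0L || length(left) == n) next
            right <- setdiff(idx, left)
            gain <- h - (length(left) * .entropy(y[left]) +
                         length(right) * .entropy(y[right])) / n
            if (gain > bestGain) {
                bestGain <- gain; bestFeat <- f; bestLeft <- left
            }
        }
        if (!is.finite(bestGain) || is.na(bestFeat))
            return(invisible(NULL))
        importance[bestFeat] <<- importance[bestFeat] + (n / n0) * bestGain
        recurse(bestLeft)
        recurse(setdiff(idx, bestLeft))
        invisible(NULL)
    }
    recurse(seq_len(n0))
    importance
}

#' Per-feature importance from an extremely randomized trees ensemble
#'
#' Entropy-criterion importances: each split contributes its weighted
#' information gain to the split feature; per-tree importances are
#' normalised and averaged over the ensemble.
#'
#' @param m a labelled [PeptideFeatureMatrix-class].
#' @param nTrees ensemble size (default 500).
#' @param k candidate features per split; default `sqrt(d)` rounded down.
#' @param minSplit minimum node size eligible for splitting.
#' @param seed integer seed.
#' @return named numeric vector over features, summing to 1.
#' @export
ertImportance <- function(m, nTrees = 500L, k = NULL, minSplit = 2L,
                          seed = 1L) {
    y <- m@label
    if (anyNA(y)) stop("all rows must be labelled")
    x <- m@values
    d <- ncol(x)
    if (is.null(k)) k <- max(1L, floor(sqrt(d)))
    total <- numeric(d)
    .withSeed(seed, {
        for (t in seq_len(nTrees)) {
            imp <- .ertTree(x, y, k, minSplit, numeric(d))
            s <- sum(imp)
            if (s > 0) total <- total + imp / s
        }
    })
    if (sum(total) == 0)
        stop("no informative split found; labels may be constant")
    stats::setNames(total / sum(total), colnames(x))
}

# default grouping of feature names into the four descriptor families
.defaultGrouping <- function(featNames) {
    list(structural = intersect(featNames, .STRUCT_DESCRIPTOR_NAMES),
         AAC = intersect(featNames, c("f_Lys", "f_Arg")),
         DPC = grep("^DPC_", featNames, value = TRUE),
         PseAAC = grep("^PseAAC_", featNames, value = TRUE))
}

#' Normalised cumulative information per descriptor group
#'
#' Sums the [ertImportance()] of the features inside each group
#' (structure-based, AAC, DPC, PseAAC by default) and normalises the
#' sums to 1. Every feature must belong to exactly one group.
#'
#' @param m a labelled [PeptideFeatureMatrix-class].
#' @param grouping named list group -> feature names; defaults to the
#'   four descriptor families inferred from the feature names.
#' @param nTrees,seed forwarded to [ertImportance()].
#' @return named numeric vector over groups, values >= 0 summing to 1.
#' @export
groupedInformation <- function(m, grouping = NULL, nTrees = 500L,
                               seed = 1L) {
    featNames <- colnames(m@values)
    if (is.null(grouping)) grouping <- .defaultGrouping(featNames)
    grouping <- grouping[lengths(grouping) > 0L]
    flat <- unlist(grouping, use.names = FALSE)
    if (anyDuplicated(flat))
        stop("feature assigned to more than one group")
    missing <- setdiff(featNames, flat)
    if (length(missing) > 0L)
        stop("unassigned feature(s): ", paste(missing, collapse = ", "))
    imp <- ertImportance(m, nTrees = nTrees, seed = seed)
    g <- vapply(grouping, function(f) sum(imp[f]), numeric(1))
    g / sum(g)
}

#' Three-component PCA with explained variance and class overlap
#'
#' Columns are standardised first (zero-variance columns dropped with a
#' message); the top three principal components are extracted with a
#' deterministic sign convention (the largest-magnitude loading of each
#' component is made positive). When labels are present, the per-PC
#' Bhattacharyya coefficient between the class-conditional projection
#' distributions is reported.
#'
#' @param m a [PeptideFeatureMatrix-class] with >= 4 rows and >= 3
#'   usable columns (fewer columns return the available components with
#'   a warning).
#' @param bins histogram bins for the Bhattacharyya coefficients.
#' @return list with `projections` (n x <=3 matrix), `evr`,
#'   `cumulativeEvr`, and `bc` (per-PC, or `NULL` when unlabelled).
#' @export
pca3d <- function(m, bins = 20L) {
    x <- m@values
    if (nrow(x) < 4L) stop("PCA needs at least 4 rows")
    sdv <- apply(x, 2L, stats::sd)
    if (any(sdv == 0)) {
        message("dropping ", sum(sdv == 0), " zero-variance column(s)")
        x <- x[, sdv > 0, drop = FALSE]
    }
    xs <- scale(x)
    pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
    nc <- min(3L, ncol(pc$rotation))
    if (nc < 3L)
        warning("rank below 3: returning ", nc, " component(s)")
    evrAll <- pc$sdev^2 / sum(pc$sdev^2)
    rot <- pc$rotation[, seq_len(nc), drop = FALSE]
    for (j in seq_len(nc)) {
        peak <- which.max(abs(rot[, j]))
        if (rot[peak, j] < 0) rot[, j] <- -rot[, j]
    }
    proj <- xs %*% rot
    colnames(proj) <- paste0("PC", seq_len(nc))
    lab <- m@label
    bc <- NULL
    if (!anyNA(lab) && length(unique(lab)) == 2L) {
        bc <- vapply(seq_len(nc), function(j)
            bhattacharyyaCoefficient(proj[lab == 1L, j],
                                     proj[lab == 0L, j], bins),
            numeric(1))
        names(bc) <- colnames(proj)
    }
    list(projections = proj,
         evr = evrAll[seq_len(nc)],
         cumulativeEvr = sum(evrAll[seq_len(nc)]),
         bc = bc)
}

#' Bhattacharyya coefficient between two samples
#'
#' Histogram overlap on shared equal-width bins spanning the pooled
#' range: BC = sum over bins of sqrt(p_i q_i) with p, q the bin mass
#' fractions. 1 for identical distributions, 0 for disjoint supports.
#'
#' @param a,b non-empty numeric samples.
#' @param bins number of shared bins (default 20).
#' @return BC in \[0, 1\].
#' @export
bhattacharyyaCoefficient <- function(a, b, bins = 20L) {
    if (length(a) == 0L || length(b) == 0L) stop("empty sample")
    lo <- min(a, b); hi <- max(a, b)
    if (lo == hi) return(1)   # all mass in one shared bin
    breaks <- seq(lo, hi, length.out = bins + 1L)
    binOf <- function(v) pmin(pmax(findInterval(v, breaks,
                                                rightmost.closed = TRUE),
                                   1L), bins)
    p <- tabulate(binOf(a), bins) / length(a)
    q <- tabulate(binOf(b), bins) / length(b)
    sum(sqrt(p * q))
}

#' Export PCA projections as CSV (id, PC1..PCk, label)
#'
#' @param pca result of [pca3d()].
#' @param m the [PeptideFeatureMatrix-class] the PCA was computed from.
#' @param path output CSV.
#' @export
writePcaProjections <- function(pca, m, path) {
    df <- data.frame(id = rownames(m@values), pca$projections,
                     label = m@label, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}
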