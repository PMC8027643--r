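#' Confusion-matrix counts from labels and predictions
#'
#' @param truth,pred binary vectors (1 = CPP, 0 = non-CPP).
#' @return named integer vector `c(TP=, FP=, FN=, TN=)`.
#' @export
confusionCounts <- function(truth, pred) {
    stopifnot(length(truth) == length(pred))
    c(TP = sum(truth == 1L & pred == 1L),
      FP = sum(truth == 0L & pred == 1L),
      FN = sum(truth == 1L & pred == 0L),
      TN = sum(truth == 0L & pred == 0L))
}

#' Sensitivity, specificity, accuracy, F1 and MCC from a confusion matrix
#'
#' Degenerate denominators yield 0 with a warning (in particular an MCC
#' denominator of zero). `scores` adds the rank-based AUC.
#'
#' @param tp,fp,fn,tn confusion-matrix counts (or pass a named vector from
#'   [confusionCounts()] as `tp`).
#' @param truth,scores optional labels and scores for the AUC.
#' @return a [MetricsReport-class].
#' @examples
#' classificationMetrics(67, 6, 8, 69)   # ensemble-style balanced test
#' @export
classificationMetrics <- function(tp, fp = NULL, fn = NULL, tn = NULL,
                                  truth = NULL, scores = NULL) {
    if (is.null(fp) && length(tp) == 4L) {
        cm <- tp
        tp <- cm[["TP"]]; fp <- cm[["FP"]]; fn <- cm[["FN"]]; tn <- cm[["TN"]]
    }
    tot <- tp + fp + fn + tn
    if (tot == 0L) stop("empty confusion matrix")
    safe <- function(num, den, what) {
        if (den == 0) {
            warning(what, " denominator is zero; reporting 0")
            return(0)
        }
        num / den
    }
    sn <- safe(tp, tp + fn, "sensitivity")
    sp <- safe(tn, tn + fp, "specificity")
    acc <- (tp + tn) / tot
    f1 <- safe(2 * tp, 2 * tp + fp + fn, "F1")
    mccDen <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    mcc <- if (mccDen == 0) {
        warning("MCC denominator is zero; reporting 0")
        0
    } else (tp * tn - fp * fn) / mccDen
    auc <- if (!is.null(truth) && !is.null(scores))
        rocAuc(truth, scores) else NA_real_
    new("MetricsReport",
        tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
        tn = as.integer(tn),
        sensitivity = sn, specificity = sp, accuracy = acc, f1 = f1,
        mcc = mcc, auc = auc)
}

setMethod("show", "MetricsReport", function(object) {
    cat("MetricsReport\n")
    cat(sprintf("  confusion: TP=%d FP=%d FN=%d TN=%d\n",
                object@tp, object@fp, object@fn, object@tn))
    cat(sprintf("  Sn=%.3f Sp=%.3f Acc=%.3f F1=%.3f MCC=%.3f",
                object@sensitivity, object@specificity, object@accuracy,
                object@f1, object@mcc))
    if (!is.na(object@auc)) cat(sprintf(" AUC=%.4f", object@auc))
    cat("\n")
})

#' @describeIn classificationMetrics Metrics as a plain named list
#'   (handy for JSON export).
#' @param report a `MetricsReport`.
#' @export
metricsAsList <- function(report) {
    list(TP = report@tp, FP = report@fp, FN = report@fn, TN = report@tn,
         sensitivity = report@sensitivity, specificity = report@specificity,
         accuracy = report@accuracy, f1 = report@f1, mcc = report@mcc,
         auc = report@auc)
}

#' Truncate (not round) to k decimals
#'
#' Published tables in this area truncate metrics at the third decimal
#' (an MCC of 0.8136 prints as 0.813); this helper reproduces that.
#'
#' @param x numeric.
#' @param k decimals kept.
#' @export
truncateDecimals <- function(x, k = 3L) trunc(x * 10^k) / 10^k

#' Rank-formulation ROC AUC
#'
#' Probability that a random positive outscores a random negative, ties
#' counted one half (the Mann-Whitney formulation).
#'
#' @param truth binary labels with both classes present.
#' @param scores numeric scores.
#' @return AUC in \[0, 1\].
#' @export
rocAuc <- function(truth, scores) {
    pos <- truth == 1L
    nPos <- sum(pos); nNeg <- sum(!pos)
    if (nPos == 0L || nNeg == 0L)
        stop("AUC needs both classes present")
    r <- rank(scores)   # midranks handle ties as 1/2
    (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Stratified k-fold cross-validation of the voting framework
#'
#' Folds are stratified with a seeded shuffle (per-class fold sizes differ
#' by at most one). Inside each training fold the scaler is refit and -
#' in the default `tune = "perfold"` mode - the grid search is re-run, so
#' no information leaks from the held-out fold. `tune = "reuse"` tunes
#' once on the full data and only refits members per fold; faster, and
#' useful for parity experiments, but not leak-free at the tuning level.
#'
#' @param m a labelled [PeptideFeatureMatrix-class].
#' @param folds number of folds (default 10).
#' @param seed seed controlling fold assignment and member fits.
#' @param grids hyperparameter grids (default [defaultGrids()]).
#' @param tune `"perfold"` or `"reuse"`.
#' @param tuneFolds folds used inside each grid search.
#' @return list with `foldAccuracy` (numeric vector), `meanAccuracy`,
#'   and `foldId` (the assignment used).
#' @export
crossValidate <- function(m, folds = 10L, seed = 1L, grids = NULL,
                          tune = c("perfold", "reuse"), tuneFolds = 3L) {
    tune <- match.arg(tune)
    y <- m@label
    if (anyNA(y)) stop("all rows must be labelled")
    x <- m@values
    if (is.null(grids)) grids <- defaultGrids(ncol(x))
    foldId <- .stratifiedFolds(y, folds, seed)

    if (tune == "reuse") {
        scaler0 <- .fitScaler(x)
        xs0 <- .applyScaler(x, scaler0)
        tuned <- lapply(stats::setNames(nm = c("ann", "gpc", "svm")),
            function(kind)
                gridSearchFit(kind, xs0, y, grids[[kind]],
                              folds = tuneFolds, seed = seed + 11L)$params)
    }

    accs <- vapply(seq_len(folds), function(f) {
        tr <- foldId != f
        mtr <- new("PeptideFeatureMatrix", values = x[tr, , drop = FALSE],
                   fc = m@fc, label = y[tr])
        fw <- if (tune == "perfold") {
            trainFramework(mtr, seed = seed + f, grids = grids,
                           tuneFolds = tuneFolds)
        } else {
            scaler <- .fitScaler(x[tr, , drop = FALSE])
            xs <- .applyScaler(x[tr, , drop = FALSE], scaler)
            members <- lapply(stats::setNames(nm = c("ann", "gpc", "svm")),
                function(kind)
                    .fitMember(kind, xs, y[tr], tuned[[kind]],
                               seed = seed + f, probModel = TRUE))
            new("CPPFramework", fc = m@fc, featureNames = colnames(x),
                scaler = scaler, members = members, hyper = tuned,
                seed = as.integer(seed))
        }
        p <- predictProba(fw, x[!tr, , drop = FALSE])
        mean(classifyProb(p) == y[!tr])
    }, numeric(1))
    list(foldAccuracy = accs, meanAccuracy = mean(accs), foldId = foldId)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with the chi-square approximation on k - 1
#' degrees of freedom (delegates to [stats::kruskal.test()]).
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return named list with `H` and `p.value`.
#' @examples
#' kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))   # H = 3.857...
#' @export
kruskalWallis <- function(groups) {
    if (!is.list(groups) || length(groups) < 2L)
        stop("need a list of at least two groups")
    if (any(lengths(groups) < 1L)) stop("every group must be non-empty")
    values <- unlist(groups, use.names = FALSE)
    g <- factor(rep(seq_along(groups), lengths(groups)))
    if (stats::sd(values) == 0) {
        # all observations identical: no rank variation at all
        return(list(H = 0, p.value = 1))
    }
    kt <- stats::kruskal.test(values, g)
    list(H = unname(kt$statistic), p.value = kt$p.value)
}
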