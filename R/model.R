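#' Default hyperparameter grids for the three classifiers
#'
#' SVM: RBF cost and kernel width (the width grid includes 1/d, the
#' inverse feature count). GPC: RBF length-scale, translated internally
#' to the kernel width sigma = 1/(2 l^2). ANN: single-hidden-layer size
#' and L2 weight decay.
#'
#' @param d feature count, used for the 1/d kernel-width grid point.
#' @return named list of grids, one per member (`ann`, `gpc`, `svm`).
#' @export
defaultGrids <- function(d) {
    list(ann = list(size = c(5L, 15L, 30L),
                    decay = c(1e-4, 1e-2)),
         gpc = list(lengthscale = c(0.5, 1, 2, 5)),
         svm = list(C = c(0.1, 1, 10, 100),
                    gamma = c(0.001, 0.01, 0.1, 1 / d)))
}

# Fit one member on scaled features. `probModel` controls whether the
# SVM pays for Platt scaling (only needed for the final refit).
.fitMember <- function(kind, x, y, params, seed, probModel = TRUE,
                       maxit = 300L) {
    .withSeed(seed, switch(kind,
        ann = nnet::nnet(x = x, y = as.numeric(y), size = params$size,
                         decay = params$decay, maxit = maxit,
                         entropy = TRUE, trace = FALSE,
                         MaxNWts = 100000L),
        gpc = kernlab::gausspr(x = x, y = factor(y, levels = c(0, 1)),
                               kernel = "rbfdot",
                               kpar = list(sigma = 1 / (2 * params$lengthscale^2)),
                               type = "classification", scaled = FALSE),
        svm = kernlab::ksvm(x = x, y = factor(y, levels = c(0, 1)),
                            kernel = "rbfdot",
                            kpar = list(sigma = params$gamma),
                            C = params$C, prob.model = probModel,
                            scaled = FALSE),
        stop("unknown classifier kind: ", kind)))
}

# P(class = 1) from a fitted member on scaled features.
.memberProba <- function(kind, model, x) {
    switch(kind,
        ann = as.numeric(stats::predict(model, x)),
        gpc = {
            p <- kernlab::predict(model, x, type = "probabilities")
            as.numeric(p[, "1"])
        },
        svm = {
            p <- kernlab::predict(model, x, type = "probabilities")
            as.numeric(p[, "1"])
        })
}

.memberClass <- function(kind, model, x) {
    switch(kind,
        ann = as.integer(as.numeric(stats::predict(model, x)) > 0.5),
        gpc = as.integer(as.character(kernlab::predict(model, x))),
        svm = as.integer(as.character(kernlab::predict(model, x))))
}

#' Exhaustive grid search for one classifier
#'
#' Every grid point is scored by stratified k-fold mean accuracy on the
#' (already standardised) training matrix; the best point - first in grid
#' order on ties - is refit on all rows. A grid point whose fit fails is
#' recorded and skipped. Deterministic given `seed`.
#'
#' @param kind `"ann"`, `"gpc"` or `"svm"`.
#' @param x standardised numeric matrix.
#' @param y binary labels (0/1).
#' @param grid named list of candidate values (see [defaultGrids()]).
#' @param folds stratified folds for the search (default 10).
#' @param seed integer seed.
#' @return list with `model` (refit on all rows), `params`, `cvAccuracy`,
#'   and `trace` (a data.frame of all evaluated points).
#' @export
gridSearchFit <- function(kind, x, y, grid, folds = 10L, seed = 1L) {
    stopifnot(is.matrix(x), length(y) == nrow(x))
    pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
    if (nrow(pts) == 0L) stop("empty hyperparameter grid")
    foldId <- .stratifiedFolds(y, folds, seed)
    acc <- rep(NA_real_, nrow(pts))
    for (p in seq_len(nrow(pts))) {
        params <- as.list(pts[p, , drop = FALSE])
        ok <- TRUE
        hits <- 0L
        for (f in seq_len(folds)) {
            tr <- foldId != f
            fit <- tryCatch(
                .fitMember(kind, x[tr, , drop = FALSE], y[tr], params,
                           seed = seed + 1000L * p + f, probModel = FALSE),
                error = function(e) NULL)
            if (is.null(fit)) { ok <- FALSE; break }
            pred <- .memberClass(kind, fit, x[!tr, , drop = FALSE])
            hits <- hits + sum(pred == y[!tr])
        }
        if (ok) acc[p] <- hits / length(y)
    }
    if (all(is.na(acc)))
        stop("no grid point for ", kind, " produced a usable fit")
    best <- which.max(acc)   # first max in grid order
    params <- as.list(pts[best, , drop = FALSE])
    model <- .fitMember(kind, x, y, params, seed = seed + 7L,
                        probModel = TRUE)
    list(model = model, params = params, cvAccuracy = acc[best],
         trace = cbind(pts, accuracy = acc))
}

#' Train the three-classifier soft-voting framework
#'
#' Fits the standardisation scaler on the input rows, grid-searches each
#' member (MLP, Gaussian process classifier, RBF-SVM) by stratified
#' cross-validated accuracy, and refits the winners on all rows. Member
#' seeds are derived deterministically from the framework seed.
#'
#' @param m a labelled [PeptideFeatureMatrix-class] (both classes present,
#'   balanced or not).
#' @param seed framework seed.
#' @param grids hyperparameter grids; default [defaultGrids()].
#' @param tuneFolds folds used inside the grid search (default 5).
#' @return a [CPPFramework-class].
#' @export
trainFramework <- function(m, seed = 1L, grids = NULL, tuneFolds = 5L) {
    y <- m@label
    if (anyNA(y)) stop("all training rows must be labelled")
    if (length(unique(y)) < 2L) stop("training labels are single-class")
    x <- m@values
    if (min(table(y)) < 10L)
        warning("fewer than 10 rows in a class; tuning will be unstable")
    if (is.null(grids)) grids <- defaultGrids(ncol(x))
    scaler <- .fitScaler(x)
    xs <- .applyScaler(x, scaler)
    offsets <- c(ann = 101L, gpc = 202L, svm = 303L)
    fits <- lapply(names(offsets), function(kind)
        gridSearchFit(kind, xs, y, grids[[kind]], folds = tuneFolds,
                      seed = seed + offsets[[kind]]))
    names(fits) <- names(offsets)
    new("CPPFramework",
        fc = m@fc,
        featureNames = colnames(x),
        scaler = scaler,
        members = lapply(fits, `[[`, "model"),
        hyper = lapply(fits, `[[`, "params"),
        seed = as.integer(seed))
}

#' Ensemble probability: unweighted mean of the three members
#'
#' @param fw a [CPPFramework-class].
#' @param newdata a [PeptideFeatureMatrix-class] or numeric matrix whose
#'   columns cover the framework's feature names.
#' @return numeric vector of CPP probabilities in \[0, 1\].
#' @export
predictProba <- function(fw, newdata) {
    x <- if (is(newdata, "PeptideFeatureMatrix")) newdata@values else
        as.matrix(newdata)
    miss <- setdiff(fw@featureNames, colnames(x))
    if (length(miss) > 0L)
        stop("missing feature(s): ", paste(miss, collapse = ", "))
    x <- x[, fw@featureNames, drop = FALSE]
    xs <- .applyScaler(x, fw@scaler)
    probs <- vapply(c("ann", "gpc", "svm"), function(kind)
        .memberProba(kind, fw@members[[kind]], xs),
        numeric(nrow(xs)))
    if (nrow(xs) == 1L) probs <- matrix(probs, nrow = 1L)
    p <- rowMeans(probs)
    pmin(pmax(p, 0), 1)
}

#' Threshold rule: CPP iff probability exceeds 0.5
#'
#' Probabilities of exactly 0.5 are labelled non-CPP.
#'
#' @param p probabilities in \[0, 1\].
#' @return integer labels (1 = CPP, 0 = non-CPP).
#' @examples
#' classifyProb(c(0.6, 0.5, 0))   # 1 0 0
#' @export
classifyProb <- function(p) {
    if (any(p < 0 | p > 1 | is.na(p)))
        stop("probabilities must lie in [0, 1]")
    as.integer(p > 0.5)
}

#' @describeIn predictProba End-to-end prediction for a PeptideSet:
#'   assembles the framework's composition, averages the members and
#'   applies the 0.5 threshold.
#' @param x a [PeptideSet-class].
#' @export
predictPeptides <- function(fw, x) {
    m <- assembleFeatures(x, fw@fc)
    p <- predictProba(fw, m)
    data.frame(id = peptideIds(x), probability = p,
               label = classifyProb(p), stringsAsFactors = FALSE)
}

setMethod("show", "CPPFramework", function(object) {
    cat(sprintf("CPPFramework (%s, %d features, seed %d)\n",
                object@fc, length(object@featureNames), object@seed))
    for (k in names(object@hyper)) {
        h <- object@hyper[[k]]
        cat(sprintf("  %s: %s\n", k,
                    paste(names(h), unlist(h), sep = "=", collapse = ", ")))
    }
})

#' Persist / restore a trained framework
#'
#' One archive file: serialized members plus a JSON metadata header
#' (composition, feature names, hyperparameters, seed) retrievable with
#' [frameworkMeta()].
#'
#' @param fw a [CPPFramework-class].
#' @param path archive file path.
#' @return `path` (save) / the restored framework (load).
#' @export
saveFramework <- function(fw, path) {
    meta <- list(package = "pepCross", class = "CPPFramework",
                 fc = fw@fc, featureNames = fw@featureNames,
                 hyper = fw@hyper, seed = fw@seed)
    saveRDS(list(meta_json = jsonlite::toJSON(meta, auto_unbox = TRUE),
                 framework = fw), path)
    invisible(path)
}

#' @rdname saveFramework
#' @export
loadFramework <- function(path) {
    obj <- readRDS(path)
    if (!is.list(obj) || !is(obj$framework, "CPPFramework"))
        stop("not a pepCross framework archive: ", path)
    obj$framework
}

#' @rdname saveFramework
#' @export
frameworkMeta <- function(path) {
    obj <- readRDS(path)
    jsonlite::fromJSON(obj$meta_json)
}
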