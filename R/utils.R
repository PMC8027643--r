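# Evaluate expr under a fixed RNG state, restoring the caller's state.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Stratified fold assignment: within each class, a seeded shuffle is dealt
# round-robin so per-class fold sizes differ by at most one.
.stratifiedFolds <- function(labels, folds, seed) {
    if (min(table(labels)) < folds)
        stop("folds (", folds, ") exceeds the size of the smallest class")
    assign <- integer(length(labels))
    .withSeed(seed, {
        for (cl in unique(labels)) {
            idx <- which(labels == cl)
            idx <- sample(idx)
            assign[idx] <- rep_len(seq_len(folds), length(idx))
        }
    })
    assign
}

# Column scaler with zero-variance guard (scale forced to 1).
.fitScaler <- function(x) {
    ctr <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    scl[scl == 0 | is.na(scl)] <- 1
    list(center = ctr, scale = scl)
}

.applyScaler <- function(x, scaler) {
    x <- sweep(x, 2L, scaler$center[colnames(x)])
    sweep(x, 2L, scaler$scale[colnames(x)], "/")
}
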