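# Published dipeptide selections (Kendall-correlation ranked lists).
.DPC40 <- c("RR", "KK", "KR", "RQ", "RK", "WR", "WK", "NR", "KW", "WF",
            "RS", "FQ", "RW", "RI", "QR", "GR", "RM", "IW", "RL", "QN",
            "ET", "CN", "PG", "PL", "GI", "TV", "FC", "FG", "GP", "LS",
            "SE", "CV", "GT", "FL", "CC", "VC", "GA", "LG", "GF", "GL")
.DPC10 <- c("RR", "KK", "KR", "RQ", "RK", "GL", "GF", "LG", "GA", "VC")

# FC4 keeps the 9 best-correlated structural descriptors: everything in
# the 12-descriptor block except tPSA, NRB and HBD.
.FC4_STRUCT <- c("MW", "cLogP", "Fsp3", "HBA", "NAR", "NPA", "NG",
                 "NetC", "NNCAA")

.pseaacNames <- function(lambda = 2L)
    c(paste0("PseAAC_", AA_ALPHABET20), paste0("PseAAC_tau", seq_len(lambda)))

#' Construct one of the four published feature compositions
#'
#' FC1: f\[Lys\]/f\[Arg\] + the 40 selected dipeptides + the 22 PseAAC
#' components (64 features, sequence-based only). FC2: the 12
#' structure-based descriptors. FC3: FC2 followed by the FC1 blocks (76
#' features; the running text of the source analysis quotes "73
#' descriptors" for this composition, which disagrees with its own
#' block-by-block enumeration of 12+2+40+22 - the enumeration is what is
#' implemented). FC4: 9 structural descriptors (all of FC2 except tPSA,
#' NRB, HBD) + f\[Lys\]/f\[Arg\] + 10 selected dipeptides + 22 PseAAC
#' components (43 features).
#'
#' @param id `"FC1"`, `"FC2"`, `"FC3"` or `"FC4"`.
#' @return a [FeatureComposition-class].
#' @examples
#' length(featureNames(featureComposition("FC4")))   # 43
#' @export
featureComposition <- function(id = c("FC4", "FC1", "FC2", "FC3")) {
    id <- match.arg(id)
    aac <- c("f_Lys", "f_Arg")
    blocks <- switch(id,
        FC1 = list(aac = aac,
                   dpc = paste0("DPC_", .DPC40),
                   pseaac = .pseaacNames()),
        FC2 = list(structural = .STRUCT_DESCRIPTOR_NAMES),
        FC3 = list(structural = .STRUCT_DESCRIPTOR_NAMES,
                   aac = aac,
                   dpc = paste0("DPC_", .DPC40),
                   pseaac = .pseaacNames()),
        FC4 = list(structural = .FC4_STRUCT,
                   aac = aac,
                   dpc = paste0("DPC_", .DPC10),
                   pseaac = .pseaacNames()))
    new("FeatureComposition", id = id, blocks = blocks)
}

#' @describeIn featureComposition Ordered feature names of a composition.
#' @param fc a `FeatureComposition`.
#' @export
featureNames <- function(fc) unlist(fc@blocks, use.names = FALSE)

setMethod("show", "FeatureComposition", function(object) {
    cat(sprintf("FeatureComposition %s: %d features\n", object@id,
                length(featureNames(object))))
    for (b in names(object@blocks))
        cat(sprintf("  %s: %d\n", b, length(object@blocks[[b]])))
})

#' Assemble the feature matrix of a PeptideSet under a composition
#'
#' One row per peptide, columns in composition order. The structural
#' block comes from [structDescriptors()], the AAC block from
#' [aacFractions()], the DPC block from [dipeptideComposition()] over the
#' composition's dipeptide list, and the PseAAC block from [pseudoAAC()]
#' with lambda = 2 (so records must be at least 3 residues long).
#'
#' @param x a [PeptideSet-class].
#' @param fc a [FeatureComposition-class] or its id.
#' @param properties standardised property table for the PseAAC block.
#' @return a [PeptideFeatureMatrix-class].
#' @export
assembleFeatures <- function(x, fc = "FC4", properties = aaPropertyTable()) {
    if (is.character(fc)) fc <- featureComposition(fc)
    seqs <- peptideSequences(x)
    if (any(nchar(seqs) < 3L) && any(c("pseaac", "dpc") %in% names(fc@blocks)))
        stop("records shorter than 3 residues cannot carry the PseAAC block")
    wants <- names(fc@blocks)
    dpcList <- if ("dpc" %in% wants)
        sub("^DPC_", "", fc@blocks$dpc) else NULL

    rows <- lapply(seqs, function(s) {
        out <- numeric(0)
        if ("structural" %in% wants) {
            sd <- structDescriptors(s)
            out <- c(out, sd[fc@blocks$structural])
        }
        if ("aac" %in% wants) {
            a <- aacFractions(s)
            out <- c(out, f_Lys = unname(a[["f_Lys"]]),
                     f_Arg = unname(a[["f_Arg"]]))
        }
        if ("dpc" %in% wants) {
            d <- dipeptideComposition(s, dpcList)
            names(d) <- paste0("DPC_", names(d))
            out <- c(out, d)
        }
        if ("pseaac" %in% wants)
            out <- c(out, pseudoAAC(s, properties))
        out
    })
    m <- do.call(rbind, rows)
    rownames(m) <- peptideIds(x)
    stopifnot(identical(colnames(m), featureNames(fc)))
    new("PeptideFeatureMatrix", values = m, fc = fc@id,
        label = peptideLabels(x))
}

#' @describeIn assembleFeatures Numeric matrix of a `PeptideFeatureMatrix`.
#' @param m a `PeptideFeatureMatrix`.
#' @export
featureValues <- function(m) m@values

#' @describeIn assembleFeatures Row labels of a `PeptideFeatureMatrix`.
#' @export
featureLabels <- function(m) m@label

setMethod("show", "PeptideFeatureMatrix", function(object) {
    cat(sprintf("PeptideFeatureMatrix (%s): %d peptides x %d features\n",
                object@fc, nrow(object@values), ncol(object@values)))
})

#' Write / read a feature matrix as CSV
#'
#' Layout: first column `id`, one named column per feature, and a final
#' `label` column when labels are present.
#'
#' @param m a [PeptideFeatureMatrix-class].
#' @param path CSV file.
#' @return `path` (write) or the re-imported object (read).
#' @export
writeFeatureMatrix <- function(m, path) {
    df <- data.frame(id = rownames(m@values), m@values,
                     check.names = FALSE)
    if (!all(is.na(m@label))) df$label <- m@label
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeFeatureMatrix
#' @param fc composition id recorded on import.
#' @export
readFeatureMatrix <- function(path, fc = "FC4") {
    df <- utils::read.csv(path, check.names = FALSE)
    lab <- if ("label" %in% names(df)) as.integer(df$label) else
        rep(NA_integer_, nrow(df))
    keep <- setdiff(names(df), c("id", "label"))
    v <- as.matrix(df[, keep, drop = FALSE])
    rownames(v) <- as.character(df$id)
    new("PeptideFeatureMatrix", values = v, fc = fc, label = lab)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected rank correlation; delegates to
#' `stats::cor(method = "kendall")`, which implements tau-b. A constant
#' vector has undefined tau: the function warns and returns `NaN`.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return tau in \[-1, 1\], or `NaN` for a constant input.
#' @export
kendallTau <- function(x, y) {
    if (length(x) != length(y) || length(x) < 2L)
        stop("x and y must have equal length >= 2")
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warning("constant vector: Kendall tau undefined")
        return(NaN)
    }
    stats::cor(x, y, method = "kendall")
}

#' Rank features by |tau| against the binary label
#'
#' @param m a labelled [PeptideFeatureMatrix-class].
#' @return data.frame with columns `feature` and `tau` (absolute value),
#'   sorted by decreasing |tau|; ties broken by feature name.
#' @export
rankFeatures <- function(m) {
    lab <- m@label
    if (anyNA(lab)) stop("all rows must be labelled")
    if (length(unique(lab)) < 2L)
        stop("labels are single-class; ranking undefined")
    tau <- vapply(colnames(m@values), function(f) {
        v <- m@values[, f]
        if (stats::sd(v) == 0) return(NA_real_)
        abs(stats::cor(v, lab, method = "kendall"))
    }, numeric(1))
    df <- data.frame(feature = colnames(m@values), tau = tau,
                     stringsAsFactors = FALSE)
    df <- df[order(-df$tau, df$feature, na.last = TRUE), ]
    rownames(df) <- NULL
    df
}

#' Select the top-k features by label correlation
#'
#' Supports re-selection for new training sets; it never replaces the
#' published FC lists, which stay hardcoded in [featureComposition()].
#'
#' @param m a labelled [PeptideFeatureMatrix-class].
#' @param k number of features to keep.
#' @return character vector of feature names.
#' @export
selectTopFeatures <- function(m, k) {
    rk <- rankFeatures(m)
    utils::head(rk$feature, k)
}
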