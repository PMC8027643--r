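#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet
NULL

#' The 20 standard amino-acid one-letter codes
#'
#' Alphabet used throughout the package. Every `PeptideSet` sequence is
#' validated against it; any other character is an error at construction.
#'
#' @export
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' PeptideSet: a labelled collection of peptide primary structures
#'
#' Thin wrapper around a [Biostrings::AAStringSet] restricted to the 20
#' standard residues. Names are peptide identifiers (unique within the set);
#' `source` records where each sequence came from (`"fasta"`, `"pdb"` or
#' `"synthetic"`); `label` is the optional binary class (1 = CPP,
#' 0 = non-CPP, `NA` = unlabelled).
#'
#' @slot sequences [Biostrings::AAStringSet] with unique names.
#' @slot source character vector, one entry per peptide.
#' @slot label integer vector, one entry per peptide (0, 1 or `NA`).
#' @export
setClass("PeptideSet",
         slots = c(sequences = "AAStringSet",
                   source = "character",
                   label = "integer"))

setValidity("PeptideSet", function(object) {
    n <- length(object@sequences)
    if (n == 0L)
        return("PeptideSet must contain at least one peptide")
    ids <- names(object@sequences)
    if (is.null(ids) || anyNA(ids) || any(ids == ""))
        return("every peptide needs a non-empty id")
    if (anyDuplicated(ids))
        return(sprintf("duplicate peptide id: '%s'",
                       ids[anyDuplicated(ids)]))
    if (length(object@source) != n || length(object@label) != n)
        return("source and label must have one entry per peptide")
    seqs <- as.character(object@sequences)
    if (any(nchar(seqs) == 0L))
        return("empty sequence not allowed")
    bad <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "")[[1]]),
                   AA_ALPHABET20)
    if (length(bad) > 0L) {
        off <- which(vapply(seqs, function(s)
            any(strsplit(s, "")[[1]] %in% bad), logical(1)))[1L]
        return(sprintf(
            "non-standard residue character '%s' in record '%s'",
            bad[1L], ids[off]))
    }
    ok <- is.na(object@label) | object@label %in% c(0L, 1L)
    if (!all(ok))
        return("labels must be 0, 1 or NA")
    TRUE
})

#' FilterReport: accounting of dataset preprocessing
#'
#' Returned alongside the kept records by [preprocessDataset()]. The four
#' removal counts plus the kept records always sum to the input size.
#'
#' @slot nInput number of records presented.
#' @slot nLengthRemoved removed by the 5-30 residue length filter.
#' @slot nDuplicateRemoved removed as exact duplicate sequences.
#' @slot nOutlierRemoved removed by the per-descriptor |z| >= 3 rule.
#' @slot keptIds ids surviving all filters, in input order.
#' @export
setClass("FilterReport",
         slots = c(nInput = "integer",
                   nLengthRemoved = "integer",
                   nDuplicateRemoved = "integer",
                   nOutlierRemoved = "integer",
                   keptIds = "character"))

setValidity("FilterReport", function(object) {
    tot <- object@nLengthRemoved + object@nDuplicateRemoved +
        object@nOutlierRemoved + length(object@keptIds)
    if (tot != object@nInput)
        return("removal counts plus kept records must equal the input size")
    TRUE
})

#' FeatureComposition: a named, ordered descriptor selection
#'
#' The four published compositions are constructed with
#' [featureComposition()]: FC1 (64 sequence-based features), FC2 (the 12
#' structure-based descriptors), FC3 (FC2 + FC1, 76 features) and FC4 (43
#' features: 9 structural + f\[Lys\]/f\[Arg\] + 10 dipeptides + 22 PseAAC).
#'
#' @slot id one of `"FC1"`, `"FC2"`, `"FC3"`, `"FC4"`.
#' @slot blocks named list of character vectors (block -> feature names),
#'   in assembly order.
#' @export
setClass("FeatureComposition",
         slots = c(id = "character", blocks = "list"))

.FC_EXPECTED_LENGTHS <- c(FC1 = 64L, FC2 = 12L, FC3 = 76L, FC4 = 43L)

setValidity("FeatureComposition", function(object) {
    if (!object@id %in% names(.FC_EXPECTED_LENGTHS))
        return("id must be one of FC1..FC4")
    feats <- unlist(object@blocks, use.names = FALSE)
    if (anyDuplicated(feats))
        return("duplicated feature name across blocks")
    want <- .FC_EXPECTED_LENGTHS[[object@id]]
    if (length(feats) != want)
        return(sprintf("%s must contain exactly %d features, got %d",
                       object@id, want, length(feats)))
    TRUE
})

#' PeptideFeatureMatrix: peptides x features with optional labels
#'
#' @slot values numeric matrix, rows = peptides (rownames = ids),
#'   columns = features in composition order.
#' @slot fc the feature-composition id the columns follow.
#' @slot label integer vector parallel to the rows (may be all `NA`).
#' @export
setClass("PeptideFeatureMatrix",
         slots = c(values = "matrix", fc = "character", label = "integer"))

setValidity("PeptideFeatureMatrix", function(object) {
    if (!is.numeric(object@values))
        return("values must be a numeric matrix")
    if (anyNA(object@values))
        return("feature matrix must not contain missing values")
    if (is.null(rownames(object@values)) || is.null(colnames(object@values)))
        return("values needs row ids and feature names")
    if (length(object@label) != nrow(object@values))
        return("label must have one entry per row")
    TRUE
})

#' CPPFramework: the fitted three-classifier soft-voting ensemble
#'
#' Produced by [trainFramework()]. Holds the feature scaler (centre/scale
#' fitted on the training rows), the three fitted members (MLP, Gaussian
#' process classifier, RBF-SVM), the grid-search-selected hyperparameters
#' and the seed everything was derived from. Prediction averages the three
#' member probabilities; the label rule is CPP iff the mean is > 0.5.
#'
#' @slot fc feature-composition id the framework was trained on.
#' @slot featureNames column order expected at prediction time.
#' @slot scaler list with numeric vectors `center` and `scale`.
#' @slot members list of fitted models: `ann`, `gpc`, `svm`.
#' @slot hyper list of chosen hyperparameters per member.
#' @slot seed integer seed of record.
#' @export
setClass("CPPFramework",
         slots = c(fc = "character", featureNames = "character",
                   scaler = "list", members = "list", hyper = "list",
                   seed = "integer"))

setValidity("CPPFramework", function(object) {
    if (!all(c("ann", "gpc", "svm") %in% names(object@members)))
        return("members must contain ann, gpc and svm")
    if (!all(c("center", "scale") %in% names(object@scaler)))
        return("scaler must contain center and scale")
    TRUE
})

#' MetricsReport: confusion-matrix quality metrics
#'
#' @slot tp,fp,fn,tn confusion-matrix counts.
#' @slot sensitivity,specificity,accuracy,f1,mcc,auc the derived metrics
#'   (`auc` is `NA` unless scores were supplied).
#' @export
setClass("MetricsReport",
         slots = c(tp = "integer", fp = "integer", fn = "integer",
                   tn = "integer",
                   sensitivity = "numeric", specificity = "numeric",
                   accuracy = "numeric", f1 = "numeric", mcc = "numeric",
                   auc = "numeric"))

setValidity("MetricsReport", function(object) {
    cnt <- c(object@tp, object@fp, object@fn, object@tn)
    if (any(cnt < 0L))
        return("confusion-matrix counts must be non-negative")
    if (sum(cnt) == 0L)
        return("empty confusion matrix")
    TRUE
})
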