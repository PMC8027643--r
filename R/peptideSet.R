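#' Construct a PeptideSet
#'
#' @param sequences character vector of one-letter sequences (uppercased
#'   internally) or an [Biostrings::AAStringSet].
#' @param ids peptide identifiers; defaults to `names(sequences)`.
#' @param source origin tag recycled across peptides (`"fasta"`, `"pdb"`,
#'   `"synthetic"`).
#' @param label optional binary labels (1 = CPP, 0 = non-CPP); `NA` when
#'   unknown.
#' @return A [PeptideSet-class] object.
#' @examples
#' ps <- PeptideSet(c(p1 = "RRRRR", p2 = "GALFL"), label = c(1, 0))
#' peptideIds(ps)
#' @export
PeptideSet <- function(sequences, ids = names(sequences),
                       source = "fasta", label = NA) {
    seqs <- toupper(as.character(sequences))
    if (is.null(ids))
        stop("peptide ids are required (name the sequences or pass ids=)")
    names(seqs) <- ids
    n <- length(seqs)
    new("PeptideSet",
        sequences = AAStringSet(seqs),
        source = rep_len(as.character(source), n),
        label = rep_len(suppressWarnings(as.integer(label)), n))
}

#' @describeIn PeptideSet Peptide identifiers.
#' @param x a `PeptideSet`.
#' @export
peptideIds <- function(x) names(x@sequences)

#' @describeIn PeptideSet Sequences as a named character vector.
#' @export
peptideSequences <- function(x) {
    s <- as.character(x@sequences)
    names(s) <- names(x@sequences)
    s
}

#' @describeIn PeptideSet Binary labels (may contain `NA`).
#' @export
peptideLabels <- function(x) x@label

#' @describeIn PeptideSet Source tag per peptide.
#' @export
peptideSource <- function(x) x@source

#' @export
setMethod("length", "PeptideSet", function(x) length(x@sequences))

#' @export
setMethod("[", "PeptideSet", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i))
        i <- match(i, peptideIds(x))
    new("PeptideSet",
        sequences = x@sequences[i],
        source = x@source[i],
        label = x@label[i])
})

setMethod("show", "PeptideSet", function(object) {
    n <- length(object)
    lab <- object@label
    cat(sprintf("PeptideSet with %d peptide%s\n", n, if (n == 1L) "" else "s"))
    cat(sprintf("  lengths: %d-%d residues\n",
                min(Biostrings::width(object@sequences)),
                max(Biostrings::width(object@sequences))))
    if (all(is.na(lab))) {
        cat("  labels: none\n")
    } else {
        cat(sprintf("  labels: %d CPP / %d non-CPP / %d NA\n",
                    sum(lab == 1L, na.rm = TRUE),
                    sum(lab == 0L, na.rm = TRUE), sum(is.na(lab))))
    }
    head <- utils::head(peptideSequences(object), 3L)
    for (i in seq_along(head))
        cat(sprintf("  %s: %s\n", names(head)[i], head[[i]]))
    if (n > 3L) cat("  ...\n")
})

#' Combine two PeptideSets
#'
#' @param x,y `PeptideSet` objects with disjoint ids.
#' @return the concatenated `PeptideSet`.
#' @export
combinePeptideSets <- function(x, y) {
    new("PeptideSet",
        sequences = AAStringSet(c(peptideSequences(x), peptideSequences(y))),
        source = c(x@source, y@source),
        label = c(x@label, y@label))
}

setMethod("show", "FilterReport", function(object) {
    cat("FilterReport\n")
    cat(sprintf("  input:              %d\n", object@nInput))
    cat(sprintf("  removed (length):   %d\n", object@nLengthRemoved))
    cat(sprintf("  removed (duplicate):%d\n", object@nDuplicateRemoved))
    cat(sprintf("  removed (outlier):  %d\n", object@nOutlierRemoved))
    cat(sprintf("  kept:               %d\n", length(object@keptIds)))
})
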