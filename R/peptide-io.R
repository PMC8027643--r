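#' Standard three-letter to one-letter residue mapping
#' @keywords internal
.AA_THREE_TO_ONE <- c(
    ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
    GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
    MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
    SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y")

#' Read peptides from a FASTA file
#'
#' Headers become ids; sequences are uppercased and validated against the
#' 20-letter alphabet. A character outside the alphabet is an error naming
#' both the character and the record.
#'
#' @param path FASTA file with at least one record.
#' @param label optional labels applied across records.
#' @return a [PeptideSet-class].
#' @export
readFastaPeptides <- function(path, label = NA) {
    if (!file.exists(path)) stop("cannot read FASTA file: ", path)
    set <- readAAStringSet(path)
    if (length(set) == 0L) stop("FASTA file contains no records: ", path)
    ids <- sub("\\s.*$", "", names(set))
    if (anyDuplicated(ids))
        stop("duplicate FASTA header: '", ids[anyDuplicated(ids)], "'")
    PeptideSet(as.character(set), ids = ids, source = "fasta", label = label)
}

#' Write a PeptideSet to FASTA
#'
#' @param x a `PeptideSet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFastaPeptides <- function(x, path) {
    writeXStringSet(x@sequences, path)
    invisible(path)
}

#' Read a labelled peptide table (CSV with id, sequence, label columns)
#'
#' @param path CSV file; `label` column optional.
#' @return a [PeptideSet-class].
#' @export
readPeptideTable <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("id", "sequence")
    if (!all(need %in% names(df)))
        stop("peptide table needs columns id and sequence")
    lab <- if ("label" %in% names(df)) df$label else NA
    PeptideSet(df$sequence, ids = as.character(df$id),
               source = "fasta", label = lab)
}

#' Extract a peptide sequence from a PDB file
#'
#' The sequence is taken from the SEQRES records of the selected chain when
#' present, otherwise from the ordered C-alpha trace of the ATOM records
#' (first occurrence per residue number). Three-letter codes are mapped via
#' the built-in standard table, extendable through `mapping` (e.g.
#' `c(MSE = "M")`); an unmapped code is an error.
#'
#' Only the primary structure is used downstream: every descriptor in this
#' package is computed from the sequence-derived molecular graph, so the
#' folded coordinates never influence the features.
#'
#' @param path PDB file.
#' @param chain chain identifier; mandatory when the file holds several
#'   chains.
#' @param mapping named character vector extending the three-to-one table.
#' @param id record id; defaults to the file name without extension.
#' @return a single-peptide [PeptideSet-class] with `source = "pdb"`.
#' @export
readPdbSequence <- function(path, chain = NULL, mapping = NULL, id = NULL) {
    if (!file.exists(path)) stop("cannot read PDB file: ", path)
    pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
    map <- c(.AA_THREE_TO_ONE, mapping)

    seqres <- pdb$seqres
    atom <- pdb$atom
    atom <- atom[atom$type %in% c("ATOM", "HETATM") & atom$elety == "CA", ,
                 drop = FALSE]
    chains <- union(names(seqres), atom$chain)
    chains <- chains[!is.na(chains)]
    if (length(chains) == 0L)
        stop("no protein records found in ", path)
    if (is.null(chain)) {
        if (length(chains) > 1L)
            stop("PDB file has chains ", paste(chains, collapse = ", "),
                 "; select one with chain=")
        chain <- chains[1L]
    }
    if (!chain %in% chains)
        stop("chain '", chain, "' not present in ", path)

    three <- if (!is.null(seqres) && chain %in% names(seqres)) {
        as.character(seqres[names(seqres) == chain])
    } else {
        tr <- atom[atom$chain == chain, , drop = FALSE]
        if (nrow(tr) == 0L)
            stop("no SEQRES and no C-alpha ATOM records for chain ", chain)
        tr <- tr[!duplicated(tr$resno), , drop = FALSE]
        tr <- tr[order(tr$resno), , drop = FALSE]
        tr$resid
    }
    one <- map[toupper(three)]
    if (anyNA(one))
        stop("unmapped residue code '", toupper(three)[which(is.na(one))[1L]],
             "' in ", path, "; extend mapping= to handle it")
    if (is.null(id))
        id <- sub("\\.[^.]*$", "", basename(path))
    PeptideSet(paste(one, collapse = ""), ids = id, source = "pdb")
}

#' Apply the dataset preprocessing filters
#'
#' Removal happens in three ordered stages: (1) sequences shorter than
#' `minLen` or longer than `maxLen` residues; (2) exact duplicate sequences
#' (case-insensitive; the first occurrence is kept); (3) records whose
#' structural descriptors are outliers, i.e. any per-descriptor |z-score|
#' >= `zThresh` computed on the length/duplicate survivors (sample standard
#' deviation; zero-variance descriptors contribute z = 0).
#'
#' @param x a [PeptideSet-class].
#' @param features optional numeric matrix row-aligned to `x` on which the
#'   outlier z-scores are computed; defaults to the 12 structure-based
#'   descriptors of each peptide.
#' @param minLen,maxLen inclusive length bounds (defaults 5 and 30).
#' @param zThresh outlier threshold on |z| (default 3).
#' @return list with elements `peptides` (the kept [PeptideSet-class]) and
#'   `report` (a [FilterReport-class]).
#' @examples
#' ps <- PeptideSet(c(a = "RKKRR", b = "RKKRR", c = "GG"))
#' preprocessDataset(ps)$report
#' @export
preprocessDataset <- function(x, features = NULL, minLen = 5L, maxLen = 30L,
                              zThresh = 3) {
    n <- length(x)
    seqs <- peptideSequences(x)
    if (!is.null(features)) {
        features <- as.matrix(features)
        if (nrow(features) != n)
            stop("feature matrix is misaligned with the records (",
                 nrow(features), " rows for ", n, " peptides)")
    }

    len <- nchar(seqs)
    keepLen <- len >= minLen & len <= maxLen
    nLen <- sum(!keepLen)

    dupe <- duplicated(toupper(seqs)) & keepLen
    nDup <- sum(dupe)
    keep <- keepLen & !dupe

    surv <- which(keep)
    if (length(surv) > 1L) {
        feat <- if (is.null(features)) {
            structDescriptorMatrix(x[surv])
        } else {
            features[surv, , drop = FALSE]
        }
        mu <- colMeans(feat)
        sdv <- apply(feat, 2L, stats::sd)
        sdv[sdv == 0 | is.na(sdv)] <- Inf   # constant descriptor: z = 0
        z <- abs(sweep(sweep(feat, 2L, mu), 2L, sdv, "/"))
        out <- apply(z, 1L, function(r) any(r >= zThresh))
        nOut <- sum(out)
        keep[surv[out]] <- FALSE
    } else {
        nOut <- 0L
    }

    kept <- x[which(keep)]
    report <- new("FilterReport",
                  nInput = n,
                  nLengthRemoved = as.integer(nLen),
                  nDuplicateRemoved = as.integer(nDup),
                  nOutlierRemoved = as.integer(nOut),
                  keptIds = peptideIds(kept))
    list(peptides = kept, report = report)
}
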