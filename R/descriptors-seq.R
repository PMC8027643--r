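#' Standardised amino-acid property table for PseAAC
#'
#' Loads hydrophobicity (H1), hydrophilicity (H2) and side-chain mass (M)
#' per residue and standardises each column to mean 0 and (sample)
#' standard deviation 1 over the 20 residues. The shipped table holds the
#' canonical values used by the classic type-1 pseudo-amino-acid
#' composition; a drop-in CSV with columns `residue,H1,H2,M` can replace
#' it.
#'
#' @param path CSV file; defaults to the packaged table.
#' @return 20 x 3 numeric matrix, rownames = residues, columns H1, H2, M.
#' @export
aaPropertyTable <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "aa_properties.csv",
                            package = "pepCross", mustWork = TRUE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("residue", "H1", "H2", "M") %in% names(df)))
        stop("property table needs columns residue, H1, H2, M")
    m <- as.matrix(df[, c("H1", "H2", "M")])
    rownames(m) <- df$residue
    if (!setequal(rownames(m), AA_ALPHABET20))
        stop("property table must cover exactly the 20 standard residues")
    m <- m[AA_ALPHABET20, , drop = FALSE]
    scale(m)[, , drop = FALSE]
}

#' Arginine and lysine composition fractions
#'
#' @param sequence one-letter peptide sequence (length >= 1).
#' @return named vector `c(f_Arg=, f_Lys=)`, counts over total residues.
#' @examples
#' aacFractions("KRKRKRKRKR")   # 0.5, 0.5
#' @export
aacFractions <- function(sequence) {
    res <- strsplit(toupper(sequence), "")[[1]]
    if (length(res) == 0L) stop("empty sequence")
    c(f_Arg = sum(res == "R") / length(res),
      f_Lys = sum(res == "K") / length(res))
}

#' All 400 ordered dipeptides (AA, AC, ..., YY)
#' @return character vector of length 400.
#' @export
allDipeptides <- function() {
    as.vector(t(outer(AA_ALPHABET20, AA_ALPHABET20, paste0)))
}

#' Dipeptide composition
#'
#' For each requested dipeptide, the count of overlapping occurrences in
#' the sequence divided by the number of dipeptide windows (L - 1).
#'
#' @param sequence one-letter sequence of length >= 2.
#' @param dipeptides dipeptides to report; defaults to all 400.
#' @return named numeric vector of fractions.
#' @examples
#' dipeptideComposition("GLGL", c("GL", "LG"))   # 2/3, 1/3
#' @export
dipeptideComposition <- function(sequence, dipeptides = allDipeptides()) {
    res <- strsplit(toupper(sequence), "")[[1]]
    L <- length(res)
    if (L < 2L) stop("dipeptide composition needs at least 2 residues")
    windows <- paste0(res[-L], res[-1L])
    tab <- table(windows)
    out <- stats::setNames(numeric(length(dipeptides)), dipeptides)
    hit <- intersect(dipeptides, names(tab))
    out[hit] <- as.numeric(tab[hit]) / (L - 1L)
    out
}

#' Sequence-order correlation between two residues
#'
#' Mean of the squared differences of the three standardised properties
#' (hydrophobicity, hydrophilicity, side-chain mass) between the residues.
#' Symmetric, zero for identical residues.
#'
#' @param r1,r2 one-letter residue codes.
#' @param table standardised property table from [aaPropertyTable()].
#' @return non-negative scalar.
#' @export
thetaCorrelation <- function(r1, r2, table = aaPropertyTable()) {
    if (!r1 %in% rownames(table) || !r2 %in% rownames(table))
        stop("residues must be standard one-letter codes")
    mean((table[r1, ] - table[r2, ])^2)
}

#' Type-1 pseudo-amino-acid composition
#'
#' The classic 20 + lambda formulation: the first 20 components are the
#' residue composition fractions and the remaining lambda components are
#' the sequence-order correlation factors
#' tau_k = mean over i of theta(R_i, R_{i+k}), k = 1..lambda, all jointly
#' normalised so the vector sums to 1:
#' component u = f_u / D (u <= 20), component 20+k = w tau_k / D with
#' D = sum(f) + w sum(tau).
#'
#' @param sequence one-letter sequence with length > `lambda`.
#' @param properties standardised property table (see [aaPropertyTable()]).
#' @param lambda number of correlation tiers (default 2, giving the
#'   22-component vector).
#' @param w weight of the sequence-order part (default 0.05).
#' @return named numeric vector of length 20 + lambda summing to 1.
#' @examples
#' sum(pseudoAAC("RKWRKW"))   # 1
#' @export
pseudoAAC <- function(sequence, properties = aaPropertyTable(), lambda = 2L,
                      w = 0.05) {
    res <- strsplit(toupper(sequence), "")[[1]]
    L <- length(res)
    if (L <= lambda)
        stop("sequence of length ", L, " too short for lambda = ", lambda)
    bad <- setdiff(res, AA_ALPHABET20)
    if (length(bad) > 0L) stop("non-standard residue '", bad[1L], "'")

    f <- as.numeric(table(factor(res, levels = AA_ALPHABET20))) / L
    tau <- vapply(seq_len(lambda), function(k) {
        i <- seq_len(L - k)
        mean(vapply(i, function(ii)
            thetaCorrelation(res[ii], res[ii + k], properties), numeric(1)))
    }, numeric(1))
    D <- sum(f) + w * sum(tau)
    out <- c(f, w * tau) / D
    names(out) <- c(paste0("PseAAC_", AA_ALPHABET20),
                    paste0("PseAAC_tau", seq_len(lambda)))
    out
}
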