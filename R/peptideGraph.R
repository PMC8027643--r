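#' MolecularGraph: atom/bond graph of a linear peptide
#'
#' Built by [buildPeptideGraph()] from per-residue templates condensed with
#' loss of one water per peptide bond. Atoms carry element, implicit
#' hydrogen count and aromatic flag; bonds carry order, aromatic/ring
#' flags and an amide flag on the backbone peptide bonds. Hydrogens are
#' implicit throughout.
#'
#' @slot atoms data.frame with columns `name`, `elem`, `nH`, `arom`.
#' @slot bonds data.frame with columns `i`, `j` (atom indices), `order`,
#'   `arom`, `ring`, `amide`.
#' @slot sequence the one-letter sequence the graph was built from.
#' @export
setClass("MolecularGraph",
         slots = c(atoms = "data.frame", bonds = "data.frame",
                   sequence = "character"))

setMethod("show", "MolecularGraph", function(object) {
    cat(sprintf("MolecularGraph of '%s': %d heavy atoms, %d bonds, %s\n",
                object@sequence, nrow(object@atoms), nrow(object@bonds),
                molecularFormula(object)))
})

# Side-chain templates. Atom rows: name, element, implicit H, aromatic.
# Bond rows: from, to, order, aromatic (aromatic implies in-ring); "CA"
# refers to the backbone alpha carbon of the same residue. Proline closes
# its ring onto the backbone nitrogen ("N").
.sc <- function(atoms, bonds) list(atoms = atoms, bonds = bonds)
.at <- function(...) {
    m <- rbind(...)
    data.frame(name = m[, 1], elem = m[, 2], nH = as.integer(m[, 3]),
               arom = as.logical(m[, 4]), stringsAsFactors = FALSE)
}
.bd <- function(...) {
    m <- rbind(...)
    data.frame(a = m[, 1], b = m[, 2], order = as.integer(m[, 3]),
               arom = as.logical(m[, 4]), stringsAsFactors = FALSE)
}

.RESIDUE_TEMPLATES <- list(
    G = .sc(NULL, NULL),
    A = .sc(.at(c("CB", "C", 3, FALSE)),
            .bd(c("CA", "CB", 1, FALSE))),
    V = .sc(.at(c("CB", "C", 1, FALSE), c("CG1", "C", 3, FALSE),
                c("CG2", "C", 3, FALSE)),
            .bd(c("CA", "CB", 1, FALSE), c("CB", "CG1", 1, FALSE),
                c("CB", "CG2", 1, FALSE))),
    L = .sc(.at(c("CB", "C", 2, FALSE), c("CG", "C", 1, FALSE),
                c("CD1", "C", 3, FALSE), c("CD2", "C", 3, FALSE)),
            .bd(c("CA", "CB", 1, FALSE), c("CB", "CG", 1, FALSE),
                c("CG", "CD1", 1, FALSE), c("CG", "CD2", 1, FALSE))),
    I = .sc(.at(c("CB", "C", 1, FALSE), c("CG1", "C", 2, FALSE),
                c("CG2", "C", 3, FALSE), c("CD1", "C", 3, FALSE)),
            .bd(c("CA", "CB", 1, FALSE), c("CB", "CG1", 1, FALSE),
                c("CB", "CG2", 1, FALSE), c("CG1", "CD1", 1, FALSE))),
    S = .sc(.at(c("CB", "C", 2, FALSE), c("OG", "O", 1, FALSE)),
            .bd(c("CA", "CB", 1, FALSE), c("CB", "OG", 1, FALSE))),
    T = .sc(.at(c("CB", "C", 1, FALSE), c("OG1", "O", 1, FALSE),
                c("CG2", "C", 3, FALSE)),
            .bd(c("CA", "CB", 1, FALSE), c("CB", "OG1", 1, FALSE),
                c("CB", "CG2", 1, FALSE))),
    C = .sc(.at(c("CB", "C", 2, FALSE), c("SG", "S", 1, FALSE)),
            .bd(c("CA", "CB", 1, FALSE), c("CB", "SG", 1, FALSE))),
    M = .sc(.at(c("CB", "C", 2, FALSE), c("CG", "C", 2, FALSE),
                c("SD", "S", 0, FALSE), c("CE", "C", 3, FALSE)),
            .bd(c("CA", "CB", 1, FALSE), c("CB", "CG", 1, FALSE),
                c("CG", "SD", 1, FALSE), c("SD", "CE", 1, FALSE))),
    D = .sc(.at(c("CB", "C", 2, FALSE), c("CG", "C", 0, FALSE),
                c("OD1", "O", 0, FALSE), c("OD2", "O", 1, FALSE)),
            .bd(c("CA", "CB", 1, FALSE), c("CB", "CG", 1, FALSE),
                c("CG", "OD1", 2, FALSE), c("CG", "OD2", 1, FALSE))),
    E = .sc(.at(c("CB", "C", 2, FALSE), c("CG", "C", 2, FALSE),
                c("CD", "C", 0, FALSE), c("OE1", "O", 0, FALSE),
                c("OE2", "O", 1, FALSE)),
            .bd(c("CA", "CB", 1, FALSE), c("CB", "CG", 1, FALSE),
                c("CG", "CD", 1, FALSE), c("CD", "OE1", 2, FALSE),
                c("CD", "OE2", 1, FALSE))),
    N = .sc(.at(c("CB", "C", 2, FALSE), c("CG", "C", 0, FALSE),
                c("OD1", "O", 0, FALSE), c("ND2", "N", 2, FALSE)),
            .bd(c("CA", "CB", 1, FALSE), c("CB", "CG", 1, FALSE),
                c("CG", "OD1", 2, FALSE), c("CG", "ND2", 1, FALSE))),
    Q = .sc(.at(c("CB", "C", 2, FALSE), c("CG", "C", 2, FALSE),
                c("CD", "C", 0, FALSE), c("OE1", "O", 0, FALSE),
                c("NE2", "N", 2, FALSE)),
            .bd(c("CA", "CB", 1, FALSE), c("CB", "CG", 1, FALSE),
                c("CG", "CD", 1, FALSE), c("CD", "OE1", 2, FALSE),
                c("CD", "NE2", 1, FALSE))),
    K = .sc(.at(c("CB", "C", 2, FALSE), c("CG", "C", 2, FALSE),
                c("CD", "C", 2, FALSE), c("CE", "C", 2, FALSE),
                c("NZ", "N", 2, FALSE)),
            .bd(c("CA", "CB", 1, FALSE), c("CB", "CG", 1, FALSE),
                c("CG", "CD", 1, FALSE), c("CD", "CE", 1, FALSE),
                c("CE", "NZ", 1, FALSE))),
    R = .sc(.at(c("CB", "C", 2, FALSE), c("CG", "C", 2, FALSE),
                c("CD", "C", 2, FALSE), c("NE", "N", 1, FALSE),
                c("CZ", "C", 0, FALSE), c("NH1", "N", 1, FALSE),
                c("NH2", "N", 2, FALSE)),
            .bd(c("CA", "CB", 1, FALSE), c("CB", "CG", 1, FALSE),
                c("CG", "CD", 1, FALSE), c("CD", "NE", 1, FALSE),
                c("NE", "CZ", 1, FALSE), c("CZ", "NH1", 2, FALSE),
                c("CZ", "NH2", 1, FALSE))),
    H = .sc(.at(c("CB", "C", 2, FALSE), c("CG", "C", 0, TRUE),
                c("ND1", "N", 0, TRUE), c("CE1", "C", 1, TRUE),
                c("NE2", "N", 1, TRUE), c("CD2", "C", 1, TRUE)),
            .bd(c("CA", "CB", 1, FALSE), c("CB", "CG", 1, FALSE),
                c("CG", "ND1", 1, TRUE), c("ND1", "CE1", 1, TRUE),
                c("CE1", "NE2", 1, TRUE), c("NE2", "CD2", 1, TRUE),
                c("CD2", "CG", 1, TRUE))),
    F = .sc(.at(c("CB", "C", 2, FALSE), c("CG", "C", 0, TRUE),
                c("CD1", "C", 1, TRUE), c("CE1", "C", 1, TRUE),
                c("CZ", "C", 1, TRUE), c("CE2", "C", 1, TRUE),
                c("CD2", "C", 1, TRUE)),
            .bd(c("CA", "CB", 1, FALSE), c("CB", "CG", 1, FALSE),
                c("CG", "CD1", 1, TRUE), c("CD1", "CE1", 1, TRUE),
                c("CE1", "CZ", 1, TRUE), c("CZ", "CE2", 1, TRUE),
                c("CE2", "CD2", 1, TRUE), c("CD2", "CG", 1, TRUE))),
    Y = .sc(.at(c("CB", "C", 2, FALSE), c("CG", "C", 0, TRUE),
                c("CD1", "C", 1, TRUE), c("CE1", "C", 1, TRUE),
                c("CZ", "C", 0, TRUE), c("CE2", "C", 1, TRUE),
                c("CD2", "C", 1, TRUE), c("OH", "O", 1, FALSE)),
            .bd(c("CA", "CB", 1, FALSE), c("CB", "CG", 1, FALSE),
                c("CG", "CD1", 1, TRUE), c("CD1", "CE1", 1, TRUE),
                c("CE1", "CZ", 1, TRUE), c("CZ", "CE2", 1, TRUE),
                c("CE2", "CD2", 1, TRUE), c("CD2", "CG", 1, TRUE),
                c("CZ", "OH", 1, FALSE))),
    W = .sc(.at(c("CB", "C", 2, FALSE), c("CG", "C", 0, TRUE),
                c("CD1", "C", 1, TRUE), c("NE1", "N", 1, TRUE),
                c("CE2", "C", 0, TRUE), c("CD2", "C", 0, TRUE),
                c("CE3", "C", 1, TRUE), c("CZ3", "C", 1, TRUE),
                c("CH2", "C", 1, TRUE), c("CZ2", "C", 1, TRUE)),
            .bd(c("CA", "CB", 1, FALSE), c("CB", "CG", 1, FALSE),
                c("CG", "CD1", 1, TRUE), c("CD1", "NE1", 1, TRUE),
                c("NE1", "CE2", 1, TRUE), c("CE2", "CD2", 1, TRUE),
                c("CD2", "CG", 1, TRUE), c("CD2", "CE3", 1, TRUE),
                c("CE3", "CZ3", 1, TRUE), c("CZ3", "CH2", 1, TRUE),
                c("CH2", "CZ2", 1, TRUE), c("CZ2", "CE2", 1, TRUE))),
    P = .sc(.at(c("CB", "C", 2, FALSE), c("CG", "C", 2, FALSE),
                c("CD", "C", 2, FALSE)),
            .bd(c("CA", "CB", 1, FALSE), c("CB", "CG", 1, FALSE),
                c("CG", "CD", 1, FALSE), c("CD", "N", 1, FALSE)))
)

#' Build the molecular graph of a linear peptide
#'
#' Residue templates are condensed with loss of one water per peptide
#' bond; the model is the neutral (uncharged) molecule with a free
#' N-terminal amine and a free C-terminal carboxylic acid. Aromatic flags
#' cover the Phe/Tyr benzene, both Trp indole rings and the His imidazole
#' (neutral, N-epsilon-H tautomer). The peptide bonds are flagged amide.
#'
#' @param sequence one-letter sequence over the 20 standard residues.
#' @return a [MolecularGraph-class].
#' @examples
#' g <- buildPeptideGraph("GG")
#' molecularFormula(g)   # "C4H8N2O3"
#' @export
buildPeptideGraph <- function(sequence) {
    res <- strsplit(toupper(sequence), "")[[1]]
    if (length(res) < 1L) stop("empty sequence")
    bad <- setdiff(res, AA_ALPHABET20)
    if (length(bad) > 0L)
        stop("non-standard residue '", bad[1L], "' in sequence")
    L <- length(res)

    atoms <- list(); bonds <- list()
    for (i in seq_len(L)) {
        r <- res[i]
        nm <- function(a) paste0(i, ":", a)
        nHN <- if (r == "P") 0L else 1L
        if (i == 1L) nHN <- nHN + 1L          # free N-terminal amine
        nHCA <- if (r == "G") 2L else 1L
        atoms[[length(atoms) + 1L]] <- data.frame(
            name = nm(c("N", "CA", "C", "O")),
            elem = c("N", "C", "C", "O"),
            nH = c(nHN, nHCA, 0L, 0L),
            arom = FALSE, stringsAsFactors = FALSE)
        proRing <- r == "P"
        bonds[[length(bonds) + 1L]] <- data.frame(
            a = c(nm("N"), nm("CA"), nm("C")),
            b = c(nm("CA"), nm("C"), nm("O")),
            order = c(1L, 1L, 2L),
            arom = FALSE,
            ring = c(proRing, FALSE, FALSE),
            amide = FALSE, stringsAsFactors = FALSE)
        tmpl <- .RESIDUE_TEMPLATES[[r]]
        if (!is.null(tmpl$atoms)) {
            sa <- tmpl$atoms
            sa$name <- nm(sa$name)
            atoms[[length(atoms) + 1L]] <- sa
            sb <- tmpl$bonds
            sb$a <- nm(sb$a); sb$b <- nm(sb$b)
            # proline: CA-CB, CB-CG, CG-CD, CD-N all sit in the ring
            sb$ring <- if (proRing) TRUE else sb$arom
            sb$amide <- FALSE
            bonds[[length(bonds) + 1L]] <- sb
        }
        if (i < L) {
            bonds[[length(bonds) + 1L]] <- data.frame(
                a = nm("C"), b = paste0(i + 1L, ":N"),
                order = 1L, arom = FALSE, ring = FALSE, amide = TRUE,
                stringsAsFactors = FALSE)
        }
    }
    # C-terminal hydroxyl
    atoms[[length(atoms) + 1L]] <- data.frame(
        name = paste0(L, ":OXT"), elem = "O", nH = 1L, arom = FALSE,
        stringsAsFactors = FALSE)
    bonds[[length(bonds) + 1L]] <- data.frame(
        a = paste0(L, ":C"), b = paste0(L, ":OXT"),
        order = 1L, arom = FALSE, ring = FALSE, amide = FALSE,
        stringsAsFactors = FALSE)

    atoms <- do.call(rbind, atoms)
    bonds <- do.call(rbind, bonds)
    idx <- stats::setNames(seq_len(nrow(atoms)), atoms$name)
    bonds$i <- unname(idx[bonds$a])
    bonds$j <- unname(idx[bonds$b])
    if (anyNA(bonds$i) || anyNA(bonds$j))
        stop("internal template error: dangling bond")
    bonds <- bonds[, c("i", "j", "order", "arom", "ring", "amide")]
    new("MolecularGraph", atoms = atoms, bonds = bonds,
        sequence = paste(res, collapse = ""))
}

#' Molecular formula of a graph (Hill notation)
#'
#' @param graph a [MolecularGraph-class].
#' @return formula string such as `"C4H8N2O3"`.
#' @export
molecularFormula <- function(graph) {
    counts <- table(graph@atoms$elem)
    h <- sum(graph@atoms$nH)
    ord <- c("C", "H", "N", "O", "S")
    n <- stats::setNames(integer(length(ord)), ord)
    n[names(counts)] <- as.integer(counts)
    n["H"] <- n["H"] + h
    paste0(vapply(ord[n > 0], function(e)
        paste0(e, if (n[[e]] > 1L) n[[e]] else ""), character(1)),
        collapse = "")
}

# heavy-atom degree vector
.degrees <- function(graph) {
    d <- integer(nrow(graph@atoms))
    tab <- table(c(graph@bonds$i, graph@bonds$j))
    d[as.integer(names(tab))] <- as.integer(tab)
    d
}

# list of neighbour indices per atom
.neighbours <- function(graph) {
    nb <- vector("list", nrow(graph@atoms))
    for (k in seq_len(nrow(graph@bonds))) {
        i <- graph@bonds$i[k]; j <- graph@bonds$j[k]
        nb[[i]] <- c(nb[[i]], j)
        nb[[j]] <- c(nb[[j]], i)
    }
    nb
}

# TRUE per atom: sp3 carbon (all single bonds, not aromatic)
.isSp3Carbon <- function(graph) {
    hasMulti <- logical(nrow(graph@atoms))
    mb <- graph@bonds[graph@bonds$order > 1L | graph@bonds$arom, , drop = FALSE]
    hasMulti[unique(c(mb$i, mb$j))] <- TRUE
    graph@atoms$elem == "C" & !graph@atoms$arom & !hasMulti
}
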