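# Average atomic weights (CIAAW-style values matching common toolkits)
.ATOMIC_WEIGHTS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.067)

#' Molecular weight from the graph
#'
#' Sum of average atomic weights over heavy atoms plus implicit hydrogens.
#'
#' @param graph a [MolecularGraph-class].
#' @return molecular weight in g/mol.
#' @export
molecularWeight <- function(graph) {
    sum(.ATOMIC_WEIGHTS[graph@atoms$elem]) +
        sum(graph@atoms$nH) * .ATOMIC_WEIGHTS[["H"]]
}

#' Fraction of sp3-hybridised carbons
#'
#' Carbons with only single bonds and no aromatic flag count as sp3; the
#' fraction is over all carbons.
#'
#' @param graph a [MolecularGraph-class] containing at least one carbon.
#' @return fraction in \[0, 1\].
#' @export
computeFsp3 <- function(graph) {
    isC <- graph@atoms$elem == "C"
    if (!any(isC)) stop("carbon-free graph: Fsp3 undefined")
    sum(.isSp3Carbon(graph)) / sum(isC)
}

#' Topological polar surface area (Ertl fragment contributions)
#'
#' Each N and O atom contributes its published Ertl fragment value chosen
#' by environment (hydrogen count, bond orders, aromaticity). Sulfur and
#' phosphorus contribute zero, matching the original parameterisation.
#'
#' @param graph a [MolecularGraph-class].
#' @return tPSA in Angstrom^2.
#' @export
computeTPSA <- function(graph) {
    at <- graph@atoms
    dbl <- logical(nrow(at))
    b2 <- graph@bonds[graph@bonds$order == 2L, , drop = FALSE]
    dbl[unique(c(b2$i, b2$j))] <- TRUE
    tot <- 0
    for (k in seq_len(nrow(at))) {
        e <- at$elem[k]; h <- at$nH[k]
        if (e == "N") {
            tot <- tot + if (at$arom[k]) {
                if (h > 0L) 15.79 else 12.89
            } else if (dbl[k]) {
                if (h > 0L) 23.85 else 12.36
            } else {
                if (h >= 2L) 26.02 else if (h == 1L) 12.03 else 3.24
            }
        } else if (e == "O") {
            tot <- tot + if (at$arom[k]) 13.14
                else if (dbl[k]) 17.07
                else if (h >= 1L) 20.23 else 9.23
        }
    }
    tot
}

#' Lipinski hydrogen-bond acceptor count (N + O atoms)
#' @param graph a [MolecularGraph-class].
#' @return integer count.
#' @export
countHBA <- function(graph)
    sum(graph@atoms$elem %in% c("N", "O"))

#' Lipinski hydrogen-bond donor count (hydrogens on N or O)
#' @param graph a [MolecularGraph-class].
#' @return integer count.
#' @export
countHBD <- function(graph)
    sum(graph@atoms$nH[graph@atoms$elem %in% c("N", "O")])

#' Number of aromatic rings (smallest-set-of-smallest-rings basis)
#'
#' Computed as the cycle rank of the aromatic subgraph (edges - vertices +
#' components), which equals the SSSR count for the fused systems that
#' occur in peptides; the Trp indole contributes 2.
#'
#' @param graph a [MolecularGraph-class].
#' @return integer count.
#' @export
countAromaticRings <- function(graph) {
    ab <- graph@bonds[graph@bonds$arom, , drop = FALSE]
    if (nrow(ab) == 0L) return(0L)
    verts <- unique(c(ab$i, ab$j))
    # union-find over the aromatic subgraph
    parent <- stats::setNames(verts, verts)
    find <- function(v) {
        while (parent[[as.character(v)]] != v) v <- parent[[as.character(v)]]
        v
    }
    for (k in seq_len(nrow(ab))) {
        ri <- find(ab$i[k]); rj <- find(ab$j[k])
        if (ri != rj) parent[[as.character(ri)]] <- rj
    }
    comps <- length(unique(vapply(verts, find, numeric(1))))
    as.integer(nrow(ab) - length(verts) + comps)
}

#' Number of rotatable bonds (strict definition)
#'
#' Counts non-ring single bonds whose two atoms each have at least two
#' heavy-atom neighbours, excluding C-N bonds whose carbon bears a double
#' bond to O or N (amides and the guanidine of Arg).
#'
#' @param graph a [MolecularGraph-class].
#' @return integer count.
#' @export
countRotatableBonds <- function(graph) {
    deg <- .degrees(graph)
    # carbons double-bonded to O or N (amide / amidine carbon)
    cdbl <- logical(nrow(graph@atoms))
    b2 <- graph@bonds[graph@bonds$order == 2L, , drop = FALSE]
    for (k in seq_len(nrow(b2))) {
        i <- b2$i[k]; j <- b2$j[k]
        ei <- graph@atoms$elem[i]; ej <- graph@atoms$elem[j]
        if (ei == "C" && ej %in% c("O", "N")) cdbl[i] <- TRUE
        if (ej == "C" && ei %in% c("O", "N")) cdbl[j] <- TRUE
    }
    n <- 0L
    for (k in seq_len(nrow(graph@bonds))) {
        bd <- graph@bonds[k, ]
        if (bd$order != 1L || bd$ring || bd$arom) next
        if (deg[bd$i] < 2L || deg[bd$j] < 2L) next
        ei <- graph@atoms$elem[bd$i]; ej <- graph@atoms$elem[bd$j]
        amideLike <- (ei == "C" && ej == "N" && cdbl[bd$i]) ||
                     (ej == "C" && ei == "N" && cdbl[bd$j])
        if (amideLike) next
        n <- n + 1L
    }
    n
}

# Wildman-Crippen atomic contributions for the atom environments that
# occur in linear peptides of the 20 standard residues (neutral form).
.CRIPPEN <- c(C1 = 0.1441, C2 = 0.0000, C3 = -0.2035, C4 = -0.2051,
              C5 = -0.2783, C10 = -0.0516, C11 = 0.1193, C12 = -0.0967,
              C18 = 0.1581, C19 = 0.2955, C21 = 0.1360, C22 = 0.4619,
              C23 = 0.5437, CS = 0.08129,
              N1 = -1.0190, N2 = -0.7096, N5 = 0.08387, N7 = -0.3187,
              N11 = -0.3239, NS = -0.4806,
              O2 = -0.2893, O9 = -0.1526, OS = -0.1188,
              S1 = 0.6482,
              H1 = 0.1230, H2 = -0.2677, H3 = 0.2142, H4 = 0.2980)

#' Crippen cLogP (atomic contribution sum)
#'
#' Implements the Wildman-Crippen additive logP model with typing rules
#' written out for the peptide atom universe: aliphatic/aromatic carbon
#' classes, amine/amide/imine/aromatic nitrogens, hydroxyl and carbonyl
#' oxygens, thioether/thiol sulfur, and the four hydrogen classes
#' (hydrocarbon, alcohol/thiol, N-H, acid O-H).
#'
#' @param graph a [MolecularGraph-class].
#' @return estimated 1-octanol/water partition coefficient.
#' @export
computeCLogP <- function(graph) {
    at <- graph@atoms
    nb <- .neighbours(graph)
    dblTo <- function(k) {
        b <- graph@bonds
        sel <- (b$i == k | b$j == k) & b$order == 2L
        other <- ifelse(b$i[sel] == k, b$j[sel], b$i[sel])
        at$elem[other]
    }
    hetero <- c("N", "O", "S")
    total <- 0
    for (k in seq_len(nrow(at))) {
        e <- at$elem[k]; h <- at$nH[k]; ar <- at$arom[k]
        nbr <- nb[[k]]
        nbrElem <- at$elem[nbr]
        nbrArom <- at$arom[nbr]
        type <- NULL
        if (e == "C") {
            if (ar) {
                nAromNbr <- sum(nbrArom)
                type <- if (h > 0L) "C18"
                    else if (nAromNbr >= 3L) "C19"
                    else if (any(nbrElem == "C" & !nbrArom)) "C21"
                    else if (any(nbrElem == "N" & !nbrArom)) "C22"
                    else if (any(nbrElem == "O" & !nbrArom)) "C23"
                    else "CS"
            } else if (length(dblTo(k)) > 0L && any(dblTo(k) %in% hetero)) {
                type <- "C5"
            } else {
                hasHet <- any(nbrElem %in% hetero)
                hasArom <- any(nbrArom)
                type <- if (!hasHet && !hasArom) {
                    if (h >= 2L) "C1" else "C2"
                } else if (hasHet) {
                    if (h >= 2L) "C3" else "C4"
                } else {
                    if (h == 2L) "C10" else if (h == 1L) "C11" else "C12"
                }
            }
            total <- total + .CRIPPEN[[type]] + h * .CRIPPEN[["H1"]]
        } else if (e == "N") {
            type <- if (ar) "N11"
                else if (length(dblTo(k)) > 0L) "N5"
                else if (h >= 2L) "N1"
                else if (h == 1L) "N2"
                else "N7"
            total <- total + .CRIPPEN[[type]] + h * .CRIPPEN[["H3"]]
        } else if (e == "O") {
            if (h >= 1L) {
                # acid O-H when the carbon carries a double bond to O/N
                parent <- nbr[1L]
                acid <- at$elem[parent] == "C" &&
                    any(dblTo(parent) %in% hetero)
                total <- total + .CRIPPEN[["O2"]] +
                    if (acid) .CRIPPEN[["H4"]] else .CRIPPEN[["H2"]]
            } else {
                total <- total + .CRIPPEN[["O9"]]
            }
        } else if (e == "S") {
            total <- total + .CRIPPEN[["S1"]] + h * .CRIPPEN[["H2"]]
        }
    }
    unname(total)
}

#' Charge-group counts and net formal charge at pH 7.4
#'
#' Counting rules on the sequence: NG is the number of arginines
#' (guanidinium groups); NNCAA the number of Asp plus Glu; NPA the number
#' of lysines plus one for the N-terminal alpha-amine unless the first
#' residue is proline; NetC the integer formal-charge model
#' (Arg, Lys = +1; Asp, Glu = -1; His neutral; the two termini cancel).
#' `model = "hh"` switches NetC to a Henderson-Hasselbalch fractional sum
#' over the ionisable groups at the given pH.
#'
#' @param sequence one-letter peptide sequence.
#' @param model `"formal"` (default) or `"hh"`.
#' @param pH used by the fractional model only.
#' @return named vector with `NPA`, `NG`, `NNCAA`, `NetC`.
#' @examples
#' computeChargeGroups("KAK")   # NPA = 3
#' @export
computeChargeGroups <- function(sequence, model = c("formal", "hh"),
                                pH = 7.4) {
    model <- match.arg(model)
    res <- strsplit(toupper(sequence), "")[[1]]
    bad <- setdiff(res, AA_ALPHABET20)
    if (length(bad) > 0L) stop("non-standard residue '", bad[1L], "'")
    cnt <- function(a) sum(res == a)
    ng <- cnt("R")
    nncaa <- cnt("D") + cnt("E")
    npa <- cnt("K") + if (res[1L] != "P") 1L else 0L
    netc <- if (model == "formal") {
        (cnt("R") + cnt("K")) - (cnt("D") + cnt("E"))
    } else {
        # EMBOSS-style pKa set
        pos <- function(pka, n) n / (1 + 10^(pH - pka))
        neg <- function(pka, n) -n / (1 + 10^(pka - pH))
        pos(12.5, cnt("R")) + pos(10.8, cnt("K")) + pos(6.5, cnt("H")) +
            pos(8.6, 1) +                       # N-terminus
            neg(3.9, cnt("D")) + neg(4.1, cnt("E")) +
            neg(8.5, cnt("C")) + neg(10.1, cnt("Y")) +
            neg(3.6, 1)                         # C-terminus
    }
    c(NPA = npa, NG = ng, NNCAA = nncaa, NetC = netc)
}

.STRUCT_DESCRIPTOR_NAMES <- c("MW", "cLogP", "tPSA", "Fsp3", "NRB", "HBD",
                              "HBA", "NAR", "NPA", "NG", "NetC", "NNCAA")

#' The twelve structure-based descriptors of a peptide
#'
#' Builds the residue-template molecular graph and evaluates molecular
#' weight, Crippen cLogP, Ertl tPSA, Fsp3, rotatable bonds, H-bond donors
#' and acceptors, aromatic rings, and the four charge-group counts. All
#' values depend on the sequence only.
#'
#' @param sequence one-letter peptide sequence.
#' @return named numeric vector of length 12 in the order
#'   MW, cLogP, tPSA, Fsp3, NRB, HBD, HBA, NAR, NPA, NG, NetC, NNCAA.
#' @examples
#' structDescriptors("GG")[c("MW", "tPSA", "NRB")]
#' @export
structDescriptors <- function(sequence) {
    g <- buildPeptideGraph(sequence)
    ch <- computeChargeGroups(sequence)
    out <- c(MW = molecularWeight(g),
             cLogP = computeCLogP(g),
             tPSA = computeTPSA(g),
             Fsp3 = computeFsp3(g),
             NRB = countRotatableBonds(g),
             HBD = countHBD(g),
             HBA = countHBA(g),
             NAR = countAromaticRings(g),
             ch[c("NPA", "NG")],
             NetC = unname(ch[["NetC"]]),
             NNCAA = unname(ch[["NNCAA"]]))
    out[.STRUCT_DESCRIPTOR_NAMES]
}

#' Structure-based descriptor matrix for a PeptideSet
#'
#' @param x a [PeptideSet-class].
#' @return numeric matrix, one row per peptide, 12 named columns.
#' @export
structDescriptorMatrix <- function(x) {
    seqs <- peptideSequences(x)
    m <- t(vapply(seqs, structDescriptors,
                  numeric(length(.STRUCT_DESCRIPTOR_NAMES))))
    rownames(m) <- peptideIds(x)
    m
}
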