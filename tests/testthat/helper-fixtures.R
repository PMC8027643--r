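# Shared fixture builders. Everything is generated in code; the only file
# fixture is the frozen cheminformatics reference table (computed once
# with RDKit 2024.09.2, an independent oracle).

rdkitReference <- function() {
    read.csv(test_path("fixtures", "rdkit_reference.csv"),
             stringsAsFactors = FALSE)
}

pdbAtomLine <- function(serial, resname, chain, resno, elem = "C",
                        name = "CA") {
    sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, resname, chain, resno,
            resno * 1.5, 0, 0, 1, 0, elem)
}

seqresLines <- function(chain, res3) {
    rows <- split(res3, ceiling(seq_along(res3) / 13))
    vapply(seq_along(rows), function(i)
        sprintf("SEQRES  %2d %s %4d  %s", i, chain, length(res3),
                paste(rows[[i]], collapse = " ")),
        character(1))
}

# Build a throwaway PDB file for a sequence of 3-letter codes.
writeTestPdb <- function(res3, chain = "A", seqres = TRUE, atoms = TRUE,
                         path = tempfile(fileext = ".pdb")) {
    lines <- character(0)
    for (ch in unique(chain)) {
        sel <- if (length(chain) == 1L) seq_along(res3) else
            which(chain == ch)
        if (seqres)
            lines <- c(lines, seqresLines(ch, res3[sel]))
    }
    if (atoms) {
        for (i in seq_along(res3)) {
            ch <- if (length(chain) == 1L) chain else chain[i]
            lines <- c(lines, pdbAtomLine(i, res3[i], ch, i))
        }
    }
    writeLines(c(lines, "END"), path)
    path
}

one2three <- function(seq1) {
    map <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
             G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
             M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
             S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")
    unname(map[strsplit(seq1, "")[[1]]])
}

# Small grids that keep model unit tests fast.
tinyGrids <- function() {
    list(ann = list(size = 3L, decay = 1e-2),
         gpc = list(lengthscale = 1),
         svm = list(C = 1, gamma = 0.05))
}

# Memoised small labelled benchmark + its FC4 matrix, reused across tests.
.fixtureCache <- new.env(parent = emptyenv())
smallBenchmark <- function() {
    if (is.null(.fixtureCache$bench)) {
        .fixtureCache$bench <- makeBenchmark(30, 30, seed = 7)$peptides
    }
    .fixtureCache$bench
}
smallFC4 <- function() {
    if (is.null(.fixtureCache$fc4)) {
        .fixtureCache$fc4 <- assembleFeatures(smallBenchmark(), "FC4")
    }
    .fixtureCache$fc4
}
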