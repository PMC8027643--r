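test_that("FASTA records are read in order with validated sequences", {
    f <- tempfile(fileext = ".fasta")
    writeLines(c(">p1", "RRRRR"), f)
    ps <- readFastaPeptides(f)
    expect_equal(peptideIds(ps), "p1")
    expect_equal(unname(peptideSequences(ps)), "RRRRR")

    writeLines(c(">a", "GG", ">b", "KK"), f)
    ps <- readFastaPeptides(f)
    expect_equal(peptideIds(ps), c("a", "b"))
    expect_equal(unname(peptideSequences(ps)), c("GG", "KK"))

    writeLines(c(">x", "GB"), f)
    expect_error(readFastaPeptides(f), "'B'.*'x'")

    writeLines(c(">a", "GG", ">a", "KK"), f)
    expect_error(readFastaPeptides(f), "duplicate")

    writeLines(character(0), f)
    expect_error(readFastaPeptides(f), "no records")
})

test_that("FASTA write/read round trip preserves sequences", {
    ps <- PeptideSet(c(a = "RKWRK", b = "GALFLGFLGAAG", c = "PPPGG"))
    f <- tempfile(fileext = ".fasta")
    writeFastaPeptides(ps, f)
    back <- readFastaPeptides(f)
    expect_identical(peptideSequences(back), peptideSequences(ps))
})

test_that("PDB sequences come from SEQRES, else the C-alpha trace", {
    f <- writeTestPdb(c("GLY", "GLY"))
    expect_equal(unname(peptideSequences(readPdbSequence(f))), "GG")

    f <- writeTestPdb(c("ARG", "LYS", "ARG"), seqres = FALSE)
    ps <- readPdbSequence(f)
    expect_equal(unname(peptideSequences(ps)), "RKR")
    expect_equal(peptideSource(ps), "pdb")

    # both extraction paths agree on complete standard records
    for (s in c("GRKDE", "WFHYT", "PKPGG")) {
        fBoth <- writeTestPdb(one2three(s))
        fAtom <- writeTestPdb(one2three(s), seqres = FALSE)
        expect_equal(unname(peptideSequences(readPdbSequence(fBoth))), s)
        expect_equal(unname(peptideSequences(readPdbSequence(fAtom))), s)
    }
})

test_that("PDB residue mapping is extendable and errors are explicit", {
    f <- writeTestPdb(c("ARG", "MSE", "LYS"), seqres = FALSE)
    expect_error(readPdbSequence(f), "MSE")
    ps <- readPdbSequence(f, mapping = c(MSE = "M"))
    expect_equal(unname(peptideSequences(ps)), "RMK")

    fMulti <- tempfile(fileext = ".pdb")
    writeLines(c(pdbAtomLine(1, "GLY", "A", 1), pdbAtomLine(2, "GLY", "A", 2),
                 pdbAtomLine(3, "LYS", "B", 1), pdbAtomLine(4, "LYS", "B", 2),
                 "END"), fMulti)
    expect_error(readPdbSequence(fMulti), "chain")
    expect_equal(unname(peptideSequences(readPdbSequence(fMulti, chain = "B"))),
                 "KK")

    fEmpty <- tempfile(fileext = ".pdb")
    writeLines("END", fEmpty)
    expect_error(readPdbSequence(fEmpty), "no protein")
})

test_that("length filter keeps exactly the 5-30 residue window", {
    ps <- PeptideSet(c(l4 = "GGGG",
                       l5 = "GGGGG",
                       l30 = strrep("G", 30),
                       l31 = strrep("G", 31)))
    # distinct-looking features so nothing else triggers
    out <- preprocessDataset(ps, features = matrix(0, 4, 1))
    expect_equal(out$report@nLengthRemoved, 2L)
    expect_setequal(peptideIds(out$peptides), c("l5", "l30"))
})

test_that("duplicate sequences are removed keeping the first occurrence", {
    ps <- PeptideSet(c(a = "RKWRK", b = "RKWRK", c = "GALFL"))
    out <- preprocessDataset(ps)
    expect_equal(out$report@nDuplicateRemoved, 1L)
    expect_equal(peptideIds(out$peptides), c("a", "c"))
})

test_that("a z-score of about 3.02 trips the outlier filter", {
    # eleven records; one feature value 100, ten zeros: the outlier has
    # |z| = 90.909 / 30.151 = 3.015 >= 3 under the sample SD
    seqs <- vapply(1:11, function(i)
        paste0(strrep("G", 4), AA_ALPHABET20[i]), character(1))
    ps <- PeptideSet(seqs, ids = paste0("p", 1:11))
    feat <- matrix(c(100, rep(0, 10)), ncol = 1)
    out <- preprocessDataset(ps, features = feat)
    expect_equal(out$report@nOutlierRemoved, 1L)
    expect_false("p1" %in% peptideIds(out$peptides))
})

test_that("the filter report accounts for every input record", {
    ps <- makeBenchmark(15, 15, seed = 3)$peptides
    out <- preprocessDataset(ps)
    rep <- out$report
    expect_equal(rep@nInput,
                 rep@nLengthRemoved + rep@nDuplicateRemoved +
                     rep@nOutlierRemoved + length(rep@keptIds))
    # idempotence at the length/duplicate stages
    again <- preprocessDataset(out$peptides)
    expect_equal(again$report@nLengthRemoved, 0L)
    expect_equal(again$report@nDuplicateRemoved, 0L)
})

test_that("misaligned feature matrices are rejected", {
    ps <- PeptideSet(c(a = "RKWRK", b = "GALFL"))
    expect_error(preprocessDataset(ps, features = matrix(0, 3, 2)),
                 "misaligned")
})
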