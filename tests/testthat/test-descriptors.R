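test_that("peptide graphs carry the right formula and amide bonds", {
    expect_equal(molecularFormula(buildPeptideGraph("G")), "C2H5NO2")
    expect_equal(molecularFormula(buildPeptideGraph("GG")), "C4H8N2O3")
    expect_equal(sum(buildPeptideGraph("GGG")@bonds$amide), 2L)
    expect_equal(sum(buildPeptideGraph("W")@bonds$arom), 10L)
    # proline ring: N-CA plus the four side-chain bonds
    expect_equal(sum(buildPeptideGraph("P")@bonds$ring), 5L)
    expect_error(buildPeptideGraph("GX"), "'X'")
    expect_error(buildPeptideGraph(""), "empty")
})

test_that("hand-enumerated descriptor values are reproduced", {
    gg <- buildPeptideGraph("GG")
    expect_equal(molecularWeight(gg), 132.12, tolerance = 0.01 / 132)
    expect_equal(computeTPSA(gg), 92.42, tolerance = 1e-6)
    expect_equal(countRotatableBonds(gg), 3L)
    expect_equal(countHBA(gg), 5L)
    expect_equal(countHBD(gg), 4L)
    expect_equal(countAromaticRings(gg), 0L)

    expect_equal(computeFsp3(buildPeptideGraph("GGGGG")), 0.5)
    expect_equal(computeFsp3(buildPeptideGraph("AAA")), 6 / 9)
    expect_equal(countAromaticRings(buildPeptideGraph("FWH")), 4L)
    expect_error(computeFsp3(buildPeptideGraph("G")), NA)
})

test_that("all descriptors match the frozen cheminformatics oracle", {
    ref <- rdkitReference()
    for (i in seq_len(nrow(ref))) {
        g <- buildPeptideGraph(ref$seq[i])
        expect_equal(molecularFormula(g), ref$formula[i], label = ref$seq[i])
        expect_equal(molecularWeight(g), ref$MW[i], tolerance = 0.01 / ref$MW[i],
                     label = paste(ref$seq[i], "MW"))
        expect_lt(abs(computeTPSA(g) - ref$tPSA[i]), 0.01)
        expect_lt(abs(computeCLogP(g) - ref$cLogP[i]), 0.01)
        expect_equal(computeFsp3(g), ref$Fsp3[i], tolerance = 1e-5)
        expect_equal(countHBA(g), ref$HBA[i], label = paste(ref$seq[i], "HBA"))
        expect_equal(countHBD(g), ref$HBD[i], label = paste(ref$seq[i], "HBD"))
        expect_equal(countAromaticRings(g), ref$NAR[i],
                     label = paste(ref$seq[i], "NAR"))
        expect_equal(countRotatableBonds(g), ref$NRB[i],
                     label = paste(ref$seq[i], "NRB"))
    }
})

test_that("MW, tPSA, HBA and HBD are additive under peptide-bond joins", {
    pairs <- list(c("GRK", "WDE"), c("AAA", "KKK"), c("FWH", "STY"))
    for (p in pairs) {
        a <- buildPeptideGraph(p[1]); b <- buildPeptideGraph(p[2])
        ab <- buildPeptideGraph(paste0(p[1], p[2]))
        expect_equal(molecularWeight(ab),
                     molecularWeight(a) + molecularWeight(b) - 18.015,
                     tolerance = 1e-9)
        # condensation swaps COOH + NH2 for the amide: -20.23 - 13.99
        expect_equal(computeTPSA(ab),
                     computeTPSA(a) + computeTPSA(b) - 20.23 -
                         (26.02 - 12.03),
                     tolerance = 1e-9)
        expect_equal(countHBA(ab), countHBA(a) + countHBA(b) - 1L)
        expect_equal(countHBD(ab), countHBD(a) + countHBD(b) - 2L)
    }
})

test_that("appending Trp raises cLogP more than appending Ser", {
    for (base in c("GG", "RKR", "AFL")) {
        b <- computeCLogP(buildPeptideGraph(base))
        dW <- computeCLogP(buildPeptideGraph(paste0(base, "W"))) - b
        dS <- computeCLogP(buildPeptideGraph(paste0(base, "S"))) - b
        expect_gt(dW, dS)
    }
})

test_that("charge-group counting follows the stated rules", {
    expect_equal(computeChargeGroups("GRGRG")[["NG"]], 2L)
    expect_equal(computeChargeGroups("KAK")[["NPA"]], 3L)
    expect_equal(computeChargeGroups("PKK")[["NPA"]], 2L)  # Pro N-terminus
    de <- computeChargeGroups("DE")
    expect_equal(de[["NNCAA"]], 2L)
    expect_equal(de[["NetC"]], -2L)
    expect_equal(computeChargeGroups("GG")[["NetC"]], 0L)
    # fractional model: a lysine-rich peptide stays cationic at pH 7.4
    hh <- computeChargeGroups("KKKKK", model = "hh")
    expect_gt(hh[["NetC"]], 4)
})

test_that("structural descriptors depend on the sequence only", {
    for (s in c("GRKDE", "WFHYT")) {
        fromSeq <- structDescriptors(s)
        pdb <- readPdbSequence(writeTestPdb(one2three(s)))
        fromPdb <- structDescriptors(peptideSequences(pdb)[[1]])
        expect_identical(fromSeq, fromPdb)
    }
})

test_that("the descriptor matrix is row-aligned and fully named", {
    ps <- PeptideSet(c(a = "GRKDE", b = "WFHYT"))
    m <- structDescriptorMatrix(ps)
    expect_equal(dim(m), c(2L, 12L))
    expect_equal(rownames(m), c("a", "b"))
    expect_equal(m["a", ], structDescriptors("GRKDE"))
})
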