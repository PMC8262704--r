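test_that("residue distances: hand geometry under both metrics", {
    A <- rbind(c(0, 0, 0), c(0, 0, 2))
    B <- rbind(c(0, 0, 5))
    expect_equal(residueDistance(A, B, "closest"), 3)
    expect_equal(residueDistance(A, B, "com"), 4)
    ## single-atom residues agree under both metrics
    P <- rbind(c(1, 2, 2)); Q <- rbind(c(1, 2, 7))
    expect_equal(residueDistance(P, Q, "closest"), 5)
    expect_equal(residueDistance(P, Q, "com"), 5)
    ## mass weighting moves the centroid
    expect_equal(residueDistance(A, B, "com", massA = c(3, 1),
                                 massB = 1), 4.5)
    ## closest never exceeds com by more than the spread of the sets
    expect_lte(residueDistance(A, B, "closest"),
               residueDistance(A, B, "com") + 2)
    expect_error(residueDistance(A[0, , drop = FALSE], B),
                 class = "iemUsageError")
})

test_that("distance matrices are symmetric, subgroup-aware, equivariant", {
    fx <- makeToyStructure("dipeptide", dir = tempdir())
    s <- readPDB(fx$pdb)
    dmAll <- buildDistanceMatrix(s, "closest", "all")
    dmBB <- buildDistanceMatrix(s, "closest", "backbone")
    V <- matrixValues(dmAll)
    expect_equal(V, t(V))
    expect_equal(unname(diag(V)), c(0, 0))
    ## backbone restriction changes the dipeptide distance (closest
    ## all-atom contact involves a side-chain methyl)
    expect_false(isTRUE(all.equal(V[1, 2], matrixValues(dmBB)[1, 2])))
    ## hand value: closest backbone contact is O1 - H2
    a <- atoms(s)
    bb <- ResidueIEM:::BACKBONE_ATOMS
    d <- Inf
    for (i in which(a$resIndex == 1 & a$elety %in% bb))
        for (j in which(a$resIndex == 2 & a$elety %in% bb))
            d <- min(d, sqrt(sum((unlist(a[i, c("x", "y", "z")]) -
                                  unlist(a[j, c("x", "y", "z")]))^2)))
    expect_equal(matrixValues(dmBB)[1, 2], d, ignore_attr = TRUE)

    ## permutation equivariance on a helix
    fx5 <- makeToyStructure("helix", dir = tempdir(), n = 5)
    s5 <- readPDB(fx5$pdb)
    perm <- c(4, 2, 5, 1, 3)
    D1 <- matrixValues(buildDistanceMatrix(s5, "com"))
    D2 <- matrixValues(buildDistanceMatrix(permuteResidues(s5, perm),
                                           "com"))
    expect_equal(unname(D1[perm, perm]), unname(D2))
})

test_that("empty subgroup selections yield NA with a warning", {
    lines <- c(pdbLine(serial = 1, name = "N", resname = "GLY", resno = 1),
               pdbLine(serial = 2, name = "CA", resname = "GLY", resno = 1,
                       x = 1.5),
               pdbLine(serial = 3, name = "CA", resname = "ALA", resno = 2,
                       x = 6),
               pdbLine(serial = 4, name = "CB", resname = "ALA", resno = 2,
                       x = 7.5))
    s <- readPDB(writePdbFixture(lines))
    expect_warning(dm <- buildDistanceMatrix(s, "closest", "sidechain"),
                   "empty")
    V <- matrixValues(dm)
    expect_true(is.na(V[1, 2]))
    expect_true(is.na(V[1, 1]))
    expect_equal(V[2, 2], 0, ignore_attr = TRUE)
})

test_that("combined matrix partitions cells by the distance threshold", {
    ## three single-atom residues: pair 1-2 close, pairs with 3 far
    df <- data.frame(chain = "A", resno = 1:3,
                     resid = c("DUA", "DUB", "DUA"), elety = "Q1",
                     element = "C", x = c(0, 3, 40), y = 0, z = 0)
    tab <- data.frame(residue = c("DUA", "DUB"), atom = "Q1",
                      charge = c(0.5, -0.5), sigma = 3.4, epsilon = 0.1,
                      gb_rho = 1.5, gb_scale = 0.8)
    ps <- assignParameters(structureFromDf(df),
                           loadParameterSet(writeParamFixture(tab)))
    iem <- buildIEM(ps, solventModel("vacuum"))
    dm <- buildDistanceMatrix(ps, "closest")

    cm <- combineMatrices(iem, dm, threshold = 5)
    isE <- isEnergyCell(cm)
    expect_equal(sum(isE[upper.tri(isE)]), 1)
    expect_true(isE[1, 2])
    expect_equal(matrixValues(cm)[1, 2],
                 energyMatrix(iem, "total")[1, 2])
    expect_equal(matrixValues(cm)[1, 3], matrixValues(dm)[1, 3])

    ## threshold extremes
    cmAll <- combineMatrices(iem, dm, threshold = Inf)
    expect_true(all(isEnergyCell(cmAll)[upper.tri(diag(3))]))
    cmNone <- combineMatrices(iem, dm, threshold = 0)
    expect_false(any(isEnergyCell(cmNone)))
    ## every off-diagonal cell is exactly one of the two
    expect_true(all(matrixValues(cmNone)[upper.tri(diag(3))] ==
                    matrixValues(dm)[upper.tri(diag(3))]))
})

test_that("combining mismatched matrices is refused", {
    fx <- makeToyStructure("dipeptide", dir = tempdir())
    ps <- assignParameters(readPDB(fx$pdb), loadParameterSet(fx$params))
    iem <- buildIEM(ps, solventModel("vacuum"), subgroup = "all")
    dmBB <- buildDistanceMatrix(ps, "closest", subgroup = "backbone")
    expect_error(combineMatrices(iem, dmBB), class = "iemUsageError")
})

test_that("matrix exports round-trip through TSV and JSON", {
    fx <- makeToyStructure("helix", dir = tempdir(), n = 4)
    ps <- assignParameters(readPDB(fx$pdb), loadParameterSet(fx$params))
    iem <- buildIEM(ps, solventModel("vacuum"))
    tsv <- tempfile(fileext = ".tsv")
    writeMatrixTable(iem, tsv)
    got <- utils::read.delim(tsv, check.names = FALSE, row.names = 1)
    expect_equal(as.matrix(got), energyMatrix(iem, "total"),
                 tolerance = 1e-5, ignore_attr = TRUE)

    js <- tempfile(fileext = ".json")
    writeMatrixJSON(iem, js)
    parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
    expect_equal(parsed$kind, "interaction_energy_matrix")
    expect_equal(parsed$total, unname(signif(energyMatrix(iem, "total"), 6)),
                 tolerance = 1e-6)
    expect_equal(parsed$total_ie, signif(totalEnergies(iem)$total, 6),
                 tolerance = 1e-6)
})
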