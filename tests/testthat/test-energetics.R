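test_that("Lennard-Jones pair energy has its analytic landmarks", {
    expect_equal(ljPairEnergy(3.4, 0.1, 3.4), 0)
    expect_equal(ljPairEnergy(3.4, 0.1, 2^(1 / 6) * 3.4), -0.1)
    expect_equal(ljPairEnergy(3.4, 0.1, 3.8), -0.09993173,
                 tolerance = 1e-7)
    expect_error(ljPairEnergy(3.4, 0.1, 0), class = "iemInputError")
    ## repulsive wall rises steeply inside sigma
    expect_gt(ljPairEnergy(3.4, 0.1, 2.0), 100)
})

test_that("vacuum and DDDC electrostatics follow Coulomb's law", {
    vac <- solventModel("vacuum")
    ddd <- solventModel("dddc")
    expect_equal(electrostaticPairEnergy(0, 0.5, 2.0, vac), 0)
    expect_equal(electrostaticPairEnergy(1, 1, 3.320636, vac), 100,
                 tolerance = 1e-9)
    expect_equal(electrostaticPairEnergy(1, 1, 3.320636, ddd),
                 332.0636 / 3.320636^2, tolerance = 1e-12)
    expect_equal(electrostaticPairEnergy(1, 1, 3.320636, ddd), 30.11,
                 tolerance = 1e-3)
    ## eps_in scaling
    vac4 <- solventModel("vacuum", epsIn = 4)
    expect_equal(electrostaticPairEnergy(1, 1, 2, vac4),
                 electrostaticPairEnergy(1, 1, 2, vac) / 4)
    ## dddc at r = 1 with slope 1 coincides with vacuum
    expect_equal(electrostaticPairEnergy(0.3, -0.2, 1, ddd),
                 electrostaticPairEnergy(0.3, -0.2, 1, vac))
    expect_error(electrostaticPairEnergy(1, 1, 2, solventModel("gb")),
                 class = "iemUsageError")
})

test_that("HCT descreening term behaves across its piecewise cases", {
    ## vanishing at large separation
    expect_lt(hctDescreenTerm(1.41, 1.5, 0.8, 1e6), 1e-15)
    ## engulfed neighbor contributes nothing
    expect_equal(hctDescreenTerm(1.41, 1.5, 0.8, 0.2), 0)
    ## monotone decrease with distance in the non-overlap regime
    d <- seq(3, 10, by = 0.5)
    v <- hctDescreenTerm(1.41, 1.5, 0.8, d)
    expect_true(all(diff(v) < 0))
    expect_error(hctDescreenTerm(-1, 1.5, 0.8, 3), class = "iemInputError")
    ## spot check against the Monte-Carlo volume oracle
    expect_equal(hctDescreenTerm(1.41, 1.5, 0.8, 4.0),
                 mcDescreen(1.41, 1.5, 0.8, 4.0), tolerance = 0.01)
})

test_that("OBC-II Born radii: isolated limit, monotonicity, oracle", {
    ## single isolated atom: R equals rho - offset exactly
    df <- data.frame(chain = "A", resno = 1, resid = "DUA", elety = "Q1",
                     element = "C", x = 0, y = 0, z = 0)
    tab <- data.frame(residue = "DUA", atom = "Q1", charge = 0,
                      sigma = 3.4, epsilon = 0.1, gb_rho = 1.5,
                      gb_scale = 0.8)
    ps1 <- assignParameters(structureFromDf(df),
                            loadParameterSet(writeParamFixture(tab)))
    expect_equal(effectiveRadii(bornRadii(ps1)), 1.41)

    ## two spheres: radii match an independent recomputation (MC
    ## integral pushed through the OBC closed form)
    fx <- makeToyStructure("two_sphere", dir = tempdir())
    ps2 <- assignParameters(readPDB(fx$pdb), loadParameterSet(fx$params))
    br <- bornRadii(ps2)
    I <- mcDescreen(1.41, 1.5, 0.8, 3.0)
    psi <- I * 1.41
    Rexp <- 1 / (1 / 1.41 - tanh(psi - 0.8 * psi^2 + 4.85 * psi^3) / 1.5)
    expect_equal(effectiveRadii(br), c(Rexp, Rexp), tolerance = 1e-3)
    expect_equal(br@integrals, c(I, I), tolerance = 0.01)
    ## neighbors only ever grow the radii beyond the isolated value
    expect_true(all(effectiveRadii(br) >= 1.41))

    ## adding a third atom increases (never decreases) both radii
    df3 <- rbind(atoms(ps2@structure)[, c("chain", "resno", "resid",
                                          "elety", "element", "x", "y",
                                          "z")],
                 data.frame(chain = "A", resno = 3, resid = "DUA",
                            elety = "Q1", element = "C", x = 1.5,
                            y = 2.5, z = 0))
    tab3 <- data.frame(residue = c("DUA", "DUB"), atom = "Q1",
                       charge = c(0.5, -0.5), sigma = 3.4, epsilon = 0.1,
                       gb_rho = 1.5, gb_scale = 0.8)
    ps3 <- assignParameters(structureFromDf(df3),
                            loadParameterSet(writeParamFixture(tab3)))
    br3 <- bornRadii(ps3)
    expect_true(all(effectiveRadii(br3)[1:2] >= effectiveRadii(br) - 1e-12))
})

test_that("GB pair energy: worked value, vacuum limit, screened limit", {
    gb <- solventModel("gb")
    expect_equal(gbPairEnergy(1, -1, 3.0, 1.5, 1.5, gb), -6.11314,
                 tolerance = 1e-4)
    ## eps_out = eps_in collapses to vacuum Coulomb exactly
    gb0 <- solventModel("gb", epsOut = 1)
    expect_equal(gbPairEnergy(0.4, 0.3, 2.7, 1.2, 1.4, gb0),
                 electrostaticPairEnergy(0.4, 0.3, 2.7,
                                         solventModel("vacuum")))
    ## large separation tends to Coulomb in the solvent dielectric
    r <- 40
    expect_equal(gbPairEnergy(1, -1, r, 1.5, 1.5, gb),
                 332.0636 * (-1) / (78.5 * r), tolerance = 0.01)
    expect_error(gbPairEnergy(1, 1, 2, 1.5, 1.5, solventModel("vacuum")),
                 class = "iemUsageError")
    expect_error(gbPairEnergy(1, 1, 0, 1.5, 1.5, gb),
                 class = "iemInputError")
})

test_that("residue pair energy equals the naive double loop", {
    fx <- makeToyStructure("dipeptide", dir = tempdir())
    ps <- assignParameters(readPDB(fx$pdb), loadParameterSet(fx$params))
    for (kind in c("vacuum", "dddc")) {
        m <- solventModel(kind)
        got <- residuePairEnergy(ps, 1, 2, m)
        expect_equal(got, bruteForcePairEnergy(ps, 1, 2, m),
                     tolerance = 1e-12)
        ## symmetry under residue swap
        expect_equal(got, residuePairEnergy(ps, 2, 1, m))
    }
    expect_error(residuePairEnergy(ps, 1, 1, solventModel("vacuum")),
                 class = "iemUsageError")
    expect_error(residuePairEnergy(ps, 1, 2, solventModel("gb")),
                 class = "iemUsageError")
})

test_that("zero charges and epsilons give exactly zero pair energy", {
    df <- data.frame(chain = "A", resno = 1:2, resid = c("DUA", "DUB"),
                     elety = "Q1", element = "C", x = c(0, 4), y = 0,
                     z = 0)
    tab <- data.frame(residue = c("DUA", "DUB"), atom = "Q1", charge = 0,
                      sigma = 3.4, epsilon = 0, gb_rho = 1.5,
                      gb_scale = 0.8)
    ps <- assignParameters(structureFromDf(df),
                           loadParameterSet(writeParamFixture(tab)))
    pe <- residuePairEnergy(ps, 1, 2, solventModel("vacuum"))
    expect_identical(unname(pe), c(0, 0, 0))
})

test_that("unparameterized atoms in scope are refused by name", {
    lines <- c(pdbLine(serial = 1, name = "CA", resname = "ALA", resno = 1),
               pdbLine(serial = 2, name = "XQ1", resname = "ALA", resno = 1,
                       x = 2, element = "C"),
               pdbLine(serial = 3, name = "CA", resname = "GLY", resno = 2,
                       x = 6))
    ps <- assignParameters(readPDB(writePdbFixture(lines)),
                           defaultParameterSet())
    expect_error(buildIEM(ps, solventModel("vacuum")), "XQ1",
                 class = "iemParameterizationError")
})

test_that("IEM is symmetric, zero-diagonal and consistent with pairs", {
    fx <- makeToyStructure("helix", dir = tempdir(), n = 5)
    ps <- assignParameters(readPDB(fx$pdb), loadParameterSet(fx$params))
    for (kind in c("vacuum", "dddc", "gb")) {
        iem <- buildIEM(ps, solventModel(kind))
        M <- energyMatrix(iem, "total")
        expect_equal(M, t(M))
        expect_equal(diag(M), setNames(rep(0, 5), rownames(M)))
        expect_equal(energyMatrix(iem, "total"),
                     energyMatrix(iem, "coulomb") + energyMatrix(iem, "lj"))
    }
    iem <- buildIEM(ps, solventModel("vacuum"))
    pe <- residuePairEnergy(ps, 2, 4, solventModel("vacuum"))
    expect_equal(energyMatrix(iem, "coulomb")[2, 4],
                 unname(pe["electrostatic"]))
    expect_equal(energyMatrix(iem, "lj")[2, 4], unname(pe["lennardJones"]))
})

test_that("total IEs are row sums and obey the double-counting identity", {
    fx <- makeToyStructure("helix", dir = tempdir(), n = 5)
    ps <- assignParameters(readPDB(fx$pdb), loadParameterSet(fx$params))
    iem <- buildIEM(ps, solventModel("vacuum"))
    tot <- totalEnergies(iem)
    M <- energyMatrix(iem, "total")
    expect_equal(tot$total, unname(rowSums(M)))
    expect_equal(sum(tot$total), 2 * sum(M[upper.tri(M)]))
    ## a 2-residue structure: both totals equal the single pair total
    fx2 <- makeToyStructure("dipeptide", dir = tempdir())
    ps2 <- assignParameters(readPDB(fx2$pdb), loadParameterSet(fx2$params))
    iem2 <- buildIEM(ps2, solventModel("vacuum"))
    pe <- residuePairEnergy(ps2, 1, 2, solventModel("vacuum"))
    expect_equal(totalEnergies(iem2)$total, rep(unname(pe["total"]), 2))
})

test_that("GB energies see global geometry; vacuum energies do not", {
    fx <- makeToyStructure("helix", dir = tempdir(), n = 3)
    s3 <- readPDB(fx$pdb)
    pset <- loadParameterSet(fx$params)
    ps3 <- assignParameters(s3, pset)
    a <- atoms(s3)
    cols <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z")
    ps2 <- assignParameters(structureFromDf(a[a$resIndex <= 2, cols]), pset)

    vac3 <- buildIEM(ps3, solventModel("vacuum"))
    vac2 <- buildIEM(ps2, solventModel("vacuum"))
    expect_equal(energyMatrix(vac3, "total")[1, 2],
                 energyMatrix(vac2, "total")[1, 2], tolerance = 1e-12,
                 ignore_attr = TRUE)

    gb3 <- buildIEM(ps3, solventModel("gb"))
    gb2 <- buildIEM(ps2, solventModel("gb"))
    expect_gt(abs(energyMatrix(gb3, "coulomb")[1, 2] -
                  energyMatrix(gb2, "coulomb")[1, 2]), 1e-6)
})

test_that("energies are invariant under rigid motion", {
    fx <- makeToyStructure("helix", dir = tempdir(), n = 4)
    s <- readPDB(fx$pdb)
    pset <- loadParameterSet(fx$params)
    ps <- assignParameters(s, pset)
    psT <- assignParameters(rigidTransform(s), pset)
    for (kind in c("vacuum", "gb")) {
        M1 <- energyMatrix(buildIEM(ps, solventModel(kind)), "total")
        M2 <- energyMatrix(buildIEM(psT, solventModel(kind)), "total")
        expect_equal(M1, M2, tolerance = 1e-8)
    }
})

test_that("permuting residues conjugates the IEM", {
    fx <- makeToyStructure("helix", dir = tempdir(), n = 5)
    s <- readPDB(fx$pdb)
    pset <- loadParameterSet(fx$params)
    perm <- c(3, 1, 5, 2, 4)
    iem1 <- buildIEM(assignParameters(s, pset), solventModel("vacuum"))
    iem2 <- buildIEM(assignParameters(permuteResidues(s, perm), pset),
                     solventModel("vacuum"))
    expect_equal(unname(energyMatrix(iem1, "total")[perm, perm]),
                 unname(energyMatrix(iem2, "total")), tolerance = 1e-12)
})

test_that("FF exclusion policy removes and scales bonded-neighbor pairs", {
    ## two consecutive alanines share a peptide bond by numbering
    fx <- makeToyStructure("dipeptide", dir = tempdir())
    ps <- assignParameters(readPDB(fx$pdb), loadParameterSet(fx$params))
    m <- solventModel("vacuum")
    peNone <- residuePairEnergy(ps, 1, 2, m)
    peFF <- residuePairEnergy(ps, 1, 2, m, exclusions = "ff")
    expect_false(isTRUE(all.equal(peNone["total"], peFF["total"])))
    ## manually remove 1-2/1-3 and scale 1-4 contributions
    at <- atoms(ps); p <- ps@parameters
    excl <- list(c("C", "N"), c("CA", "N"), c("O", "N"), c("C", "CA"),
                 c("C", "H"))
    s14 <- list(c("N", "N"), c("CB", "N"), c("HA", "N"), c("CA", "H"),
                c("CA", "CA"), c("O", "H"), c("O", "CA"), c("C", "HA"),
                c("C", "CB"), c("C", "C"))
    delta <- 0
    for (pr in c(excl, s14)) {
        i <- which(at$resIndex == 1 & at$elety == pr[1])
        j <- which(at$resIndex == 2 & at$elety == pr[2])
        r <- sqrt(sum((unlist(at[i, c("x", "y", "z")]) -
                       unlist(at[j, c("x", "y", "z")]))^2))
        e <- 332.0636 * p$charge[i] * p$charge[j] / r
        l <- ljPairEnergy((p$sigma[i] + p$sigma[j]) / 2,
                          sqrt(p$epsilon[i] * p$epsilon[j]), r)
        f <- if (list(pr) %in% excl ||
                 any(vapply(excl, identical, TRUE, y = pr)))
            c(1, 1) else c(1 - 1 / 1.2, 0.5)
        delta <- delta + f[1] * e + f[2] * l
    }
    expect_equal(unname(peNone["total"] - peFF["total"]), delta,
                 tolerance = 1e-10)
})
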