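## Independent oracles and small construction helpers shared by the
## test files. Oracles deliberately avoid the package's vectorized
## code paths.

## Monte-Carlo volume integration of (1/4pi) r'^-4 over the
## descreening sphere (radius scale*rho at distance d), excluding the
## region within rhoTilde of the descreened atom's center.
mcDescreen <- function(rhoTilde, rho, scale, d, n = 2e6, seed = 42) {
    set.seed(seed)
    s <- scale * rho
    u <- matrix(stats::rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- u * (s * stats::runif(n)^(1 / 3))
    pts[, 1] <- pts[, 1] + d
    t2 <- rowSums(pts^2)
    f <- ifelse(t2 >= rhoTilde^2, 1 / t2^2, 0)
    (4 / 3 * pi * s^3) * mean(f) / (4 * pi)
}

## one fixed-width PDB ATOM/HETATM line
pdbLine <- function(type = "ATOM", serial = 1, name = "CA", alt = "",
                    resname = "ALA", chain = "A", resno = 1, icode = "",
                    x = 0, y = 0, z = 0, occ = 1, element = NULL) {
    if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
    nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
    sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            type, serial, nm, alt, resname, chain, resno, icode,
            x, y, z, occ, 0, element)
}

writePdbFixture <- function(lines, dir = tempdir()) {
    path <- tempfile("fixture_", tmpdir = dir, fileext = ".pdb")
    writeLines(c(lines, "END"), path)
    path
}

## build a Structure directly from an atom table (chain, resno, resid,
## elety, element, x, y, z)
structureFromDf <- function(df)
    ResidueIEM:::.structureFromAtoms(df)

## reorder the residues of a structure (atoms stay grouped per residue)
permuteResidues <- function(s, perm) {
    a <- atoms(s)
    blocks <- split(seq_len(nrow(a)), a$resIndex)
    idx <- unlist(blocks[perm], use.names = FALSE)
    structureFromDf(a[idx, c("chain", "resno", "resid", "elety",
                             "element", "x", "y", "z")])
}

## apply a rigid rotation + translation to all coordinates
rigidTransform <- function(s, seed = 7) {
    set.seed(seed)
    M <- matrix(stats::rnorm(9), 3, 3)
    Q <- qr.Q(qr(M))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    shift <- stats::rnorm(3, sd = 20)
    a <- atoms(s)
    xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(Q)
    a$x <- xyz[, 1] + shift[1]
    a$y <- xyz[, 2] + shift[2]
    a$z <- xyz[, 3] + shift[3]
    structureFromDf(a[, c("chain", "resno", "resid", "elety", "element",
                          "x", "y", "z")])
}

## naive scalar double-loop residue pair energy (vacuum/dddc), kept
## separate from the package's vectorized kernel
bruteForcePairEnergy <- function(ps, a, b, model) {
    at <- atoms(ps)
    p <- ps@parameters
    ia <- which(at$resIndex == a)
    ib <- which(at$resIndex == b)
    elec <- 0; lj <- 0
    for (i in ia) for (j in ib) {
        r <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                  (at$z[i] - at$z[j])^2)
        sig <- (p$sigma[i] + p$sigma[j]) / 2
        eps <- sqrt(p$epsilon[i] * p$epsilon[j])
        lj <- lj + 4 * eps * ((sig / r)^12 - (sig / r)^6)
        elec <- elec + if (model@kind == "vacuum")
            332.0636 * p$charge[i] * p$charge[j] / (model@epsIn * r)
        else 332.0636 * p$charge[i] * p$charge[j] / (model@dddcSlope * r^2)
    }
    c(electrostatic = elec, lennardJones = lj, total = elec + lj)
}

## a tiny all-covering parameter table written to disk
writeParamFixture <- function(tab, dir = tempdir()) {
    path <- tempfile("params_", tmpdir = dir, fileext = ".tsv")
    writeLines(c(paste(names(tab), collapse = "\t"),
                 do.call(paste, c(unname(tab), sep = "\t"))), path)
    path
}
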