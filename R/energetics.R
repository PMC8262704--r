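#' @include forcefield.R
NULL

#' Construct a solvent / electrostatics model
#'
#' Three treatments of the environment are available for the
#' point-charge electrostatic term: `"vacuum"` (plain Coulomb with
#' dielectric `epsIn`), `"dddc"` (legacy distance-dependent dielectric,
#' `eps(r) = dddcSlope * r`, a heuristic damping without physical
#' grounding) and `"gb"` (generalized Born continuum solvent with
#' OBC-II effective radii, the recommended model for aqueous media).
#'
#' @param kind model kind.
#' @param epsIn internal dielectric constant (>= 1).
#' @param epsOut solvent dielectric constant (>= epsIn); only used by
#'   the GB model.
#' @param dddcSlope slope of the distance-dependent dielectric.
#' @return a [SolventModel-class].
#' @export
solventModel <- function(kind = c("gb", "vacuum", "dddc"), epsIn = 1.0,
                         epsOut = 78.5, dddcSlope = 1.0) {
    kind <- match.arg(kind)
    new("SolventModel", kind = kind, epsIn = epsIn, epsOut = epsOut,
        dddcSlope = dddcSlope)
}

#' Construct OBC model-II constants
#'
#' @param alpha,beta,gamma tanh-polynomial coefficients (model-II
#'   defaults 1.0, 0.8, 4.85).
#' @param offset dielectric offset, Angstrom (default 0.09).
#' @return an [ObcParameters-class].
#' @export
obcParameters <- function(alpha = 1.0, beta = 0.8, gamma = 4.85,
                          offset = 0.09) {
    new("ObcParameters", alpha = alpha, beta = beta, gamma = gamma,
        offset = offset)
}

#' Lennard-Jones pair energy
#'
#' `E = 4 eps [ (sigma/r)^12 - (sigma/r)^6 ]`, vectorized.
#'
#' @param sigma combined sigma, Angstrom.
#' @param epsilon combined epsilon (well depth), kcal/mol.
#' @param r interatomic distance, Angstrom (> 0).
#' @return energy, kcal/mol.
#' @export
ljPairEnergy <- function(sigma, epsilon, r) {
    if (any(r <= 0))
        iemInputError("zero or negative interatomic distance (clash)")
    sr6 <- (sigma / r)^6
    4 * epsilon * (sr6 * sr6 - sr6)
}

#' Point-charge electrostatic pair energy (vacuum or DDDC)
#'
#' Vacuum: `E = k q_i q_j / (epsIn r)`. DDDC: `E = k q_i q_j /
#' (eps(r) r)` with `eps(r) = dddcSlope * r`. The Coulomb constant k is
#' [COULOMB_CONSTANT]. For the GB model use [gbPairEnergy()], which
#' needs effective Born radii.
#'
#' @param qi,qj partial charges, elementary charges.
#' @param r distance, Angstrom (> 0).
#' @param model a [SolventModel-class] of kind `"vacuum"` or `"dddc"`.
#' @return energy, kcal/mol.
#' @export
electrostaticPairEnergy <- function(qi, qj, r, model) {
    stopifnot(is(model, "SolventModel"))
    if (model@kind == "gb")
        iemUsageError("GB electrostatics require Born radii; use gbPairEnergy()")
    if (any(r <= 0))
        iemInputError("zero or negative interatomic distance (clash)")
    if (model@kind == "vacuum")
        COULOMB_CONSTANT * qi * qj / (model@epsIn * r)
    else
        COULOMB_CONSTANT * qi * qj / (model@dddcSlope * r * r)
}

#' HCT pairwise descreening term
#'
#' Analytic Hawkins-Cramer-Truhlar approximation to
#' `(1/4pi) * integral r'^-4 dV` over the descreening sphere of a
#' neighbor atom j (radius `s_j = scale * rho`, centered at distance
#' `r`), excluding the region within the descreened atom's reduced
#' radius `rhoTilde` of its center. Piecewise: zero when the neighbor
#' sphere is engulfed within `rhoTilde`; closed forms for the
#' non-overlapping, partially overlapping and atom-inside-neighbor
#' arrangements. Vectorized; recycles arguments.
#'
#' @param rhoTilde reduced intrinsic radius of the descreened atom
#'   (`rho_i - offset`), Angstrom (> 0).
#' @param rho intrinsic radius of the descreening neighbor, Angstrom.
#' @param scale dimensionless HCT scale of the neighbor.
#' @param r center-center distance, Angstrom (>= 0).
#' @return descreening contribution, 1/Angstrom.
#' @export
hctDescreenTerm <- function(rhoTilde, rho, scale, r) {
    if (any(rhoTilde <= 0) || any(rho <= 0) || any(scale <= 0) ||
        any(r < 0))
        iemInputError("hctDescreenTerm: negative or zero radius/distance")
    n <- max(length(rhoTilde), length(rho), length(scale), length(r))
    rt <- rep_len(rhoTilde, n); s <- rep_len(scale * rho, n)
    d <- rep_len(r, n)
    out <- numeric(n)

    live <- d + s > rt                     # else sphere j engulfed -> 0
    conc <- live & d < 1e-12               # concentric: exact shell integral
    out[conc] <- 1 / rt[conc] - 1 / s[conc]
    w <- live & !conc
    if (any(w)) {
        dw <- d[w]; sw <- s[w]; rw <- rt[w]
        U <- dw + sw
        L <- pmax(rw, abs(dw - sw))
        val <- 0.5 * (1 / L - 1 / U +
                      (dw^2 - sw^2) / (4 * dw) * (1 / U^2 - 1 / L^2) -
                      log(U / L) / (2 * dw))
        ## shells entirely inside the neighbor sphere (atom i deeply
        ## buried in sphere j) contribute their full surface
        inner <- sw - dw > rw
        val[inner] <- val[inner] + 1 / rw[inner] - 1 / (sw[inner] - dw[inner])
        out[w] <- val
    }
    out
}

#' Effective Born radii by the OBC model II
#'
#' For each atom i: the HCT descreening integrals of all neighbors are
#' summed, `I_i = sum_j hct(rhoTilde_i, rho_j, S_j, r_ij)`, scaled to
#' `Psi_i = I_i * rhoTilde_i`, and rescaled through the OBC tanh form
#' `1/R_i = 1/rhoTilde_i - tanh(alpha Psi - beta Psi^2 + gamma Psi^3) /
#' rho_i` with `rhoTilde_i = rho_i - offset`. Radii are computed from
#' the full structure: they depend on the global geometry, not only on
#' any one residue pair. Over-descreened atoms (non-positive inverse
#' radius) are clamped to 100 Angstrom with a warning.
#'
#' @param ps a [ParameterizedStructure-class] with GB parameters
#'   assigned to every atom.
#' @param obc an [ObcParameters-class].
#' @return a [BornRadii-class] (one entry per atom, structure order).
#' @export
bornRadii <- function(ps, obc = obcParameters()) {
    stopifnot(is(ps, "ParameterizedStructure"), is(obc, "ObcParameters"))
    p <- ps@parameters
    if (anyNA(p$gb_rho) || anyNA(p$gb_scale)) {
        a <- ps@structure@atoms[is.na(p$gb_rho) | is.na(p$gb_scale), ]
        iemParamError(paste0("GB parameters missing for atom(s): ",
                             paste(utils::head(paste0(a$resid, a$resno, "/",
                                                      a$elety), 5),
                                   collapse = ", ")))
    }
    if (any(p$gb_rho <= obc@offset))
        iemParamError("gb_rho must exceed the dielectric offset")
    n <- nrow(p)
    rt <- p$gb_rho - obc@offset
    D <- as.matrix(stats::dist(as.matrix(ps@structure@atoms[, c("x", "y", "z")])))
    RT <- matrix(rt, n, n)                       # [i,j] = rhoTilde_i
    RHO <- matrix(p$gb_rho, n, n, byrow = TRUE)  # [i,j] = rho_j
    SC <- matrix(p$gb_scale, n, n, byrow = TRUE)
    H <- matrix(hctDescreenTerm(RT, RHO, SC, D), n, n)
    diag(H) <- 0
    I <- rowSums(H)
    psi <- I * rt
    invR <- 1 / rt - tanh(obc@alpha * psi - obc@beta * psi^2 +
                          obc@gamma * psi^3) / p$gb_rho
    bad <- invR <= 1 / 100
    if (any(invR <= 0))
        warning(sum(invR <= 0), " over-descreened atom(s); Born radii ",
                "clamped to 100 Angstrom")
    R <- ifelse(bad, 100, 1 / invR)
    new("BornRadii", radii = R, psi = psi, integrals = I)
}

#' @export
setMethod("effectiveRadii", "BornRadii", function(x) x@radii)

setMethod("show", "BornRadii", function(object) {
    cat("BornRadii for", length(object@radii), "atoms; range",
        sprintf("%.3f - %.3f", min(object@radii), max(object@radii)),
        "Angstrom\n")
})

#' Generalized-Born screened electrostatic pair energy
#'
#' `E = k q_i q_j / (epsIn r) - k (1/epsIn - 1/epsOut) q_i q_j / f_GB`
#' with the canonical smoothing function
#' `f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / (4 R_i R_j)))`. With
#' `epsOut = epsIn` the screening term vanishes and the vacuum Coulomb
#' energy is recovered; at large separation the energy tends to the
#' Coulomb interaction in the solvent dielectric.
#'
#' @param qi,qj partial charges, elementary charges.
#' @param r distance, Angstrom (> 0 between distinct atoms).
#' @param Ri,Rj effective Born radii, Angstrom.
#' @param model a [SolventModel-class] of kind `"gb"`.
#' @return energy, kcal/mol.
#' @export
gbPairEnergy <- function(qi, qj, r, Ri, Rj, model = solventModel("gb")) {
    stopifnot(is(model, "SolventModel"))
    if (model@kind != "gb")
        iemUsageError("gbPairEnergy requires a model of kind 'gb'")
    if (any(r <= 0))
        iemInputError("zero or negative interatomic distance (clash)")
    if (any(Ri <= 0) || any(Rj <= 0))
        iemInputError("Born radii must be positive")
    RR <- Ri * Rj
    fgb <- sqrt(r * r + RR * exp(-r * r / (4 * RR)))
    tau <- 1 / model@epsIn - 1 / model@epsOut
    COULOMB_CONSTANT * qi * qj / (model@epsIn * r) -
        COULOMB_CONSTANT * tau * qi * qj / fgb
}

## ---- bonded exclusions across the peptide bond (name-based) -------------
## pair name lists (first = residue i, second = residue i+1) derived from
## the backbone connectivity N-CA-C(=O)-N'-CA' with H on N' and CD on a
## following proline standing in for H
PEPTIDE_12 <- list(c("C", "N"))
PEPTIDE_13 <- list(c("CA", "N"), c("O", "N"), c("C", "CA"), c("C", "H"),
                   c("C", "CD"))
PEPTIDE_14 <- list(c("N", "N"), c("CB", "N"), c("HA", "N"), c("HA2", "N"),
                   c("HA3", "N"), c("CA", "H"), c("CA", "CA"), c("O", "H"),
                   c("O", "CA"), c("C", "HA"), c("C", "HA2"), c("C", "HA3"),
                   c("C", "CB"), c("C", "C"), c("CA", "CD"), c("O", "CD"),
                   c("C", "HD2"), c("C", "HD3"))
SCALE14_ELEC <- 1 / 1.2
SCALE14_LJ <- 0.5

## elec/LJ scale matrices for the atom pairs (rows idxA, cols idxB);
## 1 everywhere except 1-2/1-3 (0) and 1-4 (FF factors) across a
## peptide bond when exclusions == "ff"
.exclusionScales <- function(atoms, idxA, idxB, exclusions) {
    nA <- length(idxA); nB <- length(idxB)
    elec <- matrix(1, nA, nB)
    lj <- matrix(1, nA, nB)
    if (exclusions != "ff") return(list(elec = elec, lj = lj))
    aA <- atoms[idxA, ]; aB <- atoms[idxB, ]
    ## adjacency: same chain, consecutive residue index and numbering;
    ## `first` says whether the row-side residue is the earlier one
    applyPairs <- function(first, pairs, e, l) {
        adj <- outer(aA$resIndex, aB$resIndex,
                     if (first) function(i, j) j - i == 1 else
                                function(i, j) i - j == 1) &
               outer(aA$chain, aB$chain, "==") &
               outer(aA$resno, aB$resno,
                     if (first) function(i, j) j - i == 1 else
                                function(i, j) i - j == 1)
        for (p in pairs) {
            hit <- adj &
                outer(aA$elety == p[[if (first) 1 else 2]],
                      aB$elety == p[[if (first) 2 else 1]], "&")
            elec[hit] <<- e
            lj[hit] <<- l
        }
    }
    for (first in c(TRUE, FALSE)) {
        applyPairs(first, PEPTIDE_12, 0, 0)
        applyPairs(first, PEPTIDE_13, 0, 0)
        applyPairs(first, PEPTIDE_14, SCALE14_ELEC, SCALE14_LJ)
    }
    list(elec = elec, lj = lj)
}

## atom-pair component energies between index sets idxA x idxB; returns
## matrices (kcal/mol). Assumes parameters assigned; born is the
## full-structure BornRadii when model is gb.
.atomPairComponents <- function(ps, idxA, idxB, model, born, exclusions,
                                cutoff) {
    a <- ps@structure@atoms
    p <- ps@parameters
    xyz <- as.matrix(a[, c("x", "y", "z")])
    dx <- outer(xyz[idxA, 1], xyz[idxB, 1], "-")
    dy <- outer(xyz[idxA, 2], xyz[idxB, 2], "-")
    dz <- outer(xyz[idxA, 3], xyz[idxB, 3], "-")
    r <- sqrt(dx * dx + dy * dy + dz * dz)
    sameRes <- outer(a$resIndex[idxA], a$resIndex[idxB], "==")
    if (any(r <= 0 & !sameRes))
        iemInputError("coincident atoms across residues (degenerate geometry)")
    r[r <= 0] <- 1    # same-residue self pairs; caller zeroes these cells
    qq <- outer(p$charge[idxA], p$charge[idxB])
    comb <- ljCombine(
        matrix(p$sigma[idxA], length(idxA), length(idxB)),
        matrix(p$epsilon[idxA], length(idxA), length(idxB)),
        matrix(p$sigma[idxB], length(idxA), length(idxB), byrow = TRUE),
        matrix(p$epsilon[idxB], length(idxA), length(idxB), byrow = TRUE),
        rule = "lorentz_berthelot")
    sr6 <- (comb$sigma / r)^6
    lj <- 4 * comb$epsilon * (sr6 * sr6 - sr6)
    elec <- switch(model@kind,
        vacuum = COULOMB_CONSTANT * qq / (model@epsIn * r),
        dddc = COULOMB_CONSTANT * qq / (model@dddcSlope * r * r),
        gb = {
            R <- born@radii
            RR <- outer(R[idxA], R[idxB])
            fgb <- sqrt(r * r + RR * exp(-r * r / (4 * RR)))
            tau <- 1 / model@epsIn - 1 / model@epsOut
            COULOMB_CONSTANT * qq / (model@epsIn * r) -
                COULOMB_CONSTANT * tau * qq / fgb
        })
    sc <- .exclusionScales(a, idxA, idxB, exclusions)
    elec <- elec * sc$elec
    lj <- lj * sc$lj
    if (is.finite(cutoff)) {
        far <- r > cutoff
        elec[far] <- 0
        lj[far] <- 0
    }
    list(elec = elec, lj = lj)
}

.checkAssigned <- function(ps, idx) {
    bad <- idx[is.na(ps@parameters$charge[idx])]
    if (length(bad)) {
        a <- ps@structure@atoms[bad, ]
        iemParamError(paste0("unparameterized atom(s) in selection: ",
                             paste(utils::head(paste0(a$resid, a$resno, "/",
                                                      a$elety), 8),
                                   collapse = ", ")))
    }
}

#' Pairwise interaction energy of one residue pair
#'
#' Sums the Lennard-Jones and model electrostatic terms over all
#' cross-residue atom pairs within the selected subgroup. By default
#' every cross-residue atom pair contributes once; with
#' `exclusions = "ff"`, 1-2/1-3 pairs across the peptide bond are
#' removed and 1-4 pairs scaled by the standard force-field factors
#' (electrostatics 1/1.2, Lennard-Jones 1/2).
#'
#' @param ps a [ParameterizedStructure-class].
#' @param a,b residue indices (`resIndex`, 1-based file order), `a != b`.
#' @param model a [SolventModel-class].
#' @param subgroup atom subgroup restriction.
#' @param born a [BornRadii-class] computed from the full structure;
#'   required iff the model kind is `"gb"`.
#' @param exclusions `"none"` or `"ff"`.
#' @param cutoff atom-pair distance cutoff, Angstrom (default `Inf`).
#' @return named numeric vector `c(electrostatic, lennardJones, total)`,
#'   kcal/mol.
#' @export
residuePairEnergy <- function(ps, a, b, model = solventModel("vacuum"),
                              subgroup = "all", born = NULL,
                              exclusions = c("none", "ff"),
                              cutoff = Inf) {
    stopifnot(is(ps, "ParameterizedStructure"))
    exclusions <- match.arg(exclusions)
    if (a == b) iemUsageError("residuePairEnergy requires two distinct residues")
    if (model@kind == "gb" && is.null(born))
        iemUsageError("GB model requires Born radii (bornRadii on the full structure)")
    if (model@kind != "gb" && !is.null(born))
        iemUsageError("Born radii supplied for a non-GB model")
    mask <- subgroupMask(ps, subgroup)
    at <- ps@structure@atoms
    idxA <- which(at$resIndex == a & mask)
    idxB <- which(at$resIndex == b & mask)
    if (!length(idxA) || !length(idxB))
        iemUsageError("empty atom selection for a residue under this subgroup")
    .checkAssigned(ps, c(idxA, idxB))
    comp <- .atomPairComponents(ps, idxA, idxB, model, born, exclusions,
                                cutoff)
    e <- sum(comp$elec); l <- sum(comp$lj)
    c(electrostatic = e, lennardJones = l, total = e + l)
}

#' Build the residue interaction energy matrix
#'
#' Computes the full symmetric residue-by-residue matrix of pairwise
#' interaction energies under the chosen solvent model and atom
#' subgroup. For the GB model the effective Born radii are computed
#' once from the complete structure (all atoms, regardless of
#' subgroup), so pairwise GB energies reflect the global geometry.
#' The diagonal is zero by convention.
#'
#' @inheritParams residuePairEnergy
#' @param obc OBC constants used for the GB Born radii.
#' @return an [InteractionEnergyMatrix-class].
#' @examples
#' fx <- makeToyStructure("dipeptide", dir = tempdir())
#' ps <- assignParameters(readPDB(fx$pdb), loadParameterSet(fx$params))
#' iem <- buildIEM(ps, solventModel("vacuum"))
#' energyMatrix(iem, "total")
#' @export
buildIEM <- function(ps, model = solventModel("gb"), subgroup = "all",
                     exclusions = c("none", "ff"), cutoff = Inf,
                     obc = obcParameters()) {
    stopifnot(is(ps, "ParameterizedStructure"))
    exclusions <- match.arg(exclusions)
    mask <- subgroupMask(ps, subgroup)
    at <- ps@structure@atoms
    sel <- which(mask)
    .checkAssigned(ps, sel)
    born <- if (model@kind == "gb") bornRadii(ps, obc) else NULL
    keys <- residues(ps@structure)
    n <- nrow(keys)
    if (length(sel)) {
        comp <- .atomPairComponents(ps, sel, sel, model, born, exclusions,
                                    cutoff)
        ri <- at$resIndex[sel]
        ## same-residue atom pairs are not pairwise interactions
        same <- outer(ri, ri, "==")
        comp$elec[same] <- 0
        comp$lj[same] <- 0
        ## aggregate atom-pair energies into residue-pair cells; residues
        ## with no selected atoms (e.g. GLY sidechain) keep zero rows
        agg <- function(m) {
            collapse <- function(mm) {
                s <- rowsum(mm, ri)
                full <- matrix(0, n, ncol(mm))
                full[match(rownames(s), as.character(keys$resIndex)), ] <- s
                full
            }
            t(collapse(t(collapse(m))))
        }
        E <- agg(comp$elec); L <- agg(comp$lj)
        E <- (E + t(E)) / 2   # remove round-off asymmetry
        L <- (L + t(L)) / 2
    } else {
        E <- L <- matrix(0, n, n)
    }
    dimnames(E) <- dimnames(L) <-
        list(.residueKeyStrings(keys), .residueKeyStrings(keys))
    new("InteractionEnergyMatrix",
        residueKeys = keys[, c("chain", "resno", "insert", "resid")],
        electrostatic = E, lennardJones = L, model = model,
        subgroup = subgroup)
}

#' @export
setMethod("residueKeys", "InteractionEnergyMatrix",
          function(x) x@residueKeys)

#' @export
setMethod("energyMatrix", "InteractionEnergyMatrix",
    function(x, component = c("total", "coulomb", "lj")) {
    component <- match.arg(component)
    switch(component,
           total = x@electrostatic + x@lennardJones,
           coulomb = x@electrostatic,
           lj = x@lennardJones)
})

#' @export
setMethod("totalEnergies", "InteractionEnergyMatrix", function(x) {
    out <- x@residueKeys
    out$coulomb <- rowSums(x@electrostatic)
    out$lj <- rowSums(x@lennardJones)
    out$total <- out$coulomb + out$lj
    rownames(out) <- NULL
    out
})

setMethod("show", "InteractionEnergyMatrix", function(object) {
    n <- nrow(object@residueKeys)
    tot <- object@electrostatic + object@lennardJones
    cat("InteractionEnergyMatrix: ", n, " x ", n, " residues, model ",
        object@model@kind, ", subgroup ", object@subgroup, "\n", sep = "")
    if (n > 1) {
        ut <- tot[upper.tri(tot)]
        cat(sprintf("  pairwise total IE range %.3f to %.3f kcal/mol\n",
                    min(ut), max(ut)))
    }
})
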