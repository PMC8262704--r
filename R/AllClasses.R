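#' @import methods
NULL

#' Coulomb constant in kcal Angstrom mol^-1 e^-2
#'
#' Conversion constant for point-charge electrostatics with distances in
#' Angstrom, charges in elementary charges and energies in kcal/mol.
#' @export
COULOMB_CONSTANT <- 332.0636

#' Protein structure as a flat atom table
#'
#' Holds all atoms of (the first model of) a PDB structure in file order.
#' The `atoms` slot is a data.frame with one row per atom and columns
#' `chain`, `resno`, `insert`, `resid` (3-letter residue name), `elety`
#' (atom name), `eleno` (serial), `x`, `y`, `z` (Angstrom), `element`,
#' `mass` (Da), `het` (logical, HETATM record) and `resIndex` (dense
#' 1-based residue index in file order).
#'
#' @slot atoms data.frame of atoms, see description.
#' @slot title character, structure title (may be empty).
#' @export
setClass("Structure",
    representation(atoms = "data.frame", title = "character"))

setValidity("Structure", function(object) {
    a <- object@atoms
    need <- c("chain", "resno", "insert", "resid", "elety", "eleno",
              "x", "y", "z", "element", "mass", "het", "resIndex")
    if (!all(need %in% names(a)))
        return(paste("atoms missing columns:",
                     paste(setdiff(need, names(a)), collapse = ", ")))
    if (nrow(a) > 0) {
        if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
            return("non-finite atom coordinates")
        if (!all(a$mass > 0)) return("non-positive atomic mass")
        if (any(!nzchar(a$elety))) return("empty atom name")
    }
    TRUE
})

#' Force-field parameter set
#'
#' Residue templates of per-atom nonbonded parameters: partial charge
#' (elementary charges), Lennard-Jones sigma (Angstrom) and epsilon
#' (kcal/mol), intrinsic generalized-Born radius `gb_rho` (Angstrom) and
#' dimensionless HCT descreening scale `gb_scale`.
#'
#' @slot name character label of the set.
#' @slot templates data.frame with columns `residue`, `atom`, `charge`,
#'   `sigma`, `epsilon`, `gb_rho`, `gb_scale`.
#' @slot combiningRule `"lorentz_berthelot"` or `"geometric"`.
#' @export
setClass("ParameterSet",
    representation(name = "character", templates = "data.frame",
                   combiningRule = "character"))

setValidity("ParameterSet", function(object) {
    t <- object@templates
    need <- c("residue", "atom", "charge", "sigma", "epsilon",
              "gb_rho", "gb_scale")
    if (!all(need %in% names(t)))
        return(paste("templates missing columns:",
                     paste(setdiff(need, names(t)), collapse = ", ")))
    if (anyDuplicated(t[, c("residue", "atom")]))
        return("duplicate (residue, atom) row in templates")
    if (any(t$sigma <= 0)) return("sigma must be > 0")
    if (any(t$epsilon < 0)) return("epsilon must be >= 0")
    if (!object@combiningRule %in% c("lorentz_berthelot", "geometric"))
        return("combiningRule must be lorentz_berthelot or geometric")
    TRUE
})

#' Structure with assigned force-field parameters
#'
#' Pairs a [Structure-class] with per-atom nonbonded parameters looked up
#' from a [ParameterSet-class]. Atoms whose (residue, atom name) had no
#' template row are listed in `unassigned` (and carry NA parameters);
#' template atoms absent from the structure (e.g. missing hydrogens) are
#' listed in `missing`. Energetics refuse structures with unassigned
#' atoms inside the selected subgroup.
#'
#' @slot structure the underlying [Structure-class].
#' @slot parameters data.frame aligned row-by-row with the structure's
#'   atoms: `charge`, `sigma`, `epsilon`, `gb_rho`, `gb_scale`.
#' @slot unassigned data.frame (`chain`, `resno`, `insert`, `resid`,
#'   `elety`) of atoms without parameters.
#' @slot missing data.frame (`chain`, `resno`, `insert`, `resid`,
#'   `elety`) of template atoms not present in the structure.
#' @export
setClass("ParameterizedStructure",
    representation(structure = "Structure", parameters = "data.frame",
                   unassigned = "data.frame", missing = "data.frame"))

setValidity("ParameterizedStructure", function(object) {
    if (nrow(object@parameters) != nrow(object@structure@atoms))
        return("parameters not aligned with atoms")
    need <- c("charge", "sigma", "epsilon", "gb_rho", "gb_scale")
    if (!all(need %in% names(object@parameters)))
        return("parameters missing columns")
    TRUE
})

#' Electrostatics / solvent model description
#'
#' @slot kind `"vacuum"`, `"dddc"` or `"gb"`.
#' @slot epsIn internal (solute) dielectric constant, default 1.
#' @slot epsOut solvent dielectric constant, default 78.5 (water).
#' @slot dddcSlope slope of the distance-dependent dielectric
#'   `eps(r) = dddcSlope * r` (dimensionless, default 1).
#' @export
setClass("SolventModel",
    representation(kind = "character", epsIn = "numeric",
                   epsOut = "numeric", dddcSlope = "numeric"))

setValidity("SolventModel", function(object) {
    if (!object@kind %in% c("vacuum", "dddc", "gb"))
        return("kind must be vacuum, dddc or gb")
    if (object@epsIn < 1) return("epsIn must be >= 1")
    if (object@epsOut < object@epsIn) return("epsOut must be >= epsIn")
    if (object@dddcSlope <= 0) return("dddcSlope must be > 0")
    TRUE
})

#' OBC model-II constants
#'
#' Constants of the Onufriev-Bashford-Case tanh rescaling of HCT
#' descreening integrals (model II): `alpha` = 1.0, `beta` = 0.8,
#' `gamma` = 4.85, dielectric `offset` = 0.09 Angstrom.
#'
#' @slot alpha,beta,gamma dimensionless tanh-polynomial coefficients.
#' @slot offset dielectric offset subtracted from intrinsic radii, Angstrom.
#' @export
setClass("ObcParameters",
    representation(alpha = "numeric", beta = "numeric",
                   gamma = "numeric", offset = "numeric"))

#' Per-atom effective Born radii
#'
#' @slot radii effective Born radii R_i, Angstrom, one per atom.
#' @slot psi dimensionless Psi_i = I_i * rhoTilde_i.
#' @slot integrals HCT descreening sums I_i, 1/Angstrom.
#' @export
setClass("BornRadii",
    representation(radii = "numeric", psi = "numeric",
                   integrals = "numeric"))

setValidity("BornRadii", function(object) {
    if (length(object@radii) != length(object@psi) ||
        length(object@radii) != length(object@integrals))
        return("slot lengths differ")
    if (any(object@radii <= 0)) return("Born radii must be > 0")
    TRUE
})

#' Residue-residue interaction energy matrix
#'
#' Square symmetric matrix of pairwise residue interaction energies with
#' a component decomposition (Coulomb and Lennard-Jones); the complete
#' energy is their sum. The diagonal is zero by convention (self terms
#' are not pairwise interactions).
#'
#' @slot residueKeys data.frame (`chain`, `resno`, `insert`, `resid`)
#'   identifying the rows/columns in order.
#' @slot electrostatic n x n matrix, kcal/mol.
#' @slot lennardJones n x n matrix, kcal/mol.
#' @slot model the [SolventModel-class] used.
#' @slot subgroup atom subgroup used (`"all"`, `"backbone"`, `"sidechain"`).
#' @export
setClass("InteractionEnergyMatrix",
    representation(residueKeys = "data.frame", electrostatic = "matrix",
                   lennardJones = "matrix", model = "SolventModel",
                   subgroup = "character"))

setValidity("InteractionEnergyMatrix", function(object) {
    n <- nrow(object@residueKeys)
    for (nm in c("electrostatic", "lennardJones")) {
        m <- slot(object, nm)
        if (!all(dim(m) == c(n, n))) return(paste(nm, "has wrong dimensions"))
        if (n > 0) {
            if (max(abs(m - t(m))) > 1e-9 * max(1, max(abs(m))))
                return(paste(nm, "is not symmetric"))
            if (any(diag(m) != 0)) return(paste(nm, "has nonzero diagonal"))
        }
    }
    TRUE
})

#' Residue-residue distance matrix
#'
#' @slot residueKeys data.frame as in [InteractionEnergyMatrix-class].
#' @slot values n x n matrix of distances, Angstrom; NA marks residues
#'   with an empty atom selection under the chosen subgroup.
#' @slot metric `"closest"` (minimum cross atom-pair distance) or
#'   `"com"` (distance between mass-weighted centroids).
#' @slot subgroup atom subgroup the distances were computed over.
#' @export
setClass("DistanceMatrix",
    representation(residueKeys = "data.frame", values = "matrix",
                   metric = "character", subgroup = "character"))

setValidity("DistanceMatrix", function(object) {
    n <- nrow(object@residueKeys)
    if (!all(dim(object@values) == c(n, n))) return("wrong dimensions")
    if (!object@metric %in% c("closest", "com")) return("unknown metric")
    v <- object@values
    if (n > 0 && max(abs(v - t(v)), na.rm = TRUE) > 1e-9)
        return("not symmetric")
    TRUE
})

#' Combined energy/distance matrix
#'
#' Each off-diagonal cell carries the complete pairwise interaction
#' energy where the residue pair is closer than `threshold`, and the
#' distance otherwise; `isEnergy` says which.
#'
#' @slot residueKeys data.frame as in [InteractionEnergyMatrix-class].
#' @slot values n x n numeric matrix (kcal/mol or Angstrom per cell).
#' @slot isEnergy n x n logical matrix; TRUE where `values` is an energy.
#' @slot threshold distance threshold, Angstrom.
#' @export
setClass("CombinedMatrix",
    representation(residueKeys = "data.frame", values = "matrix",
                   isEnergy = "matrix", threshold = "numeric"))

#' Per-residue conservation profile
#'
#' Per-column information content of a weighted multiple sequence
#' alignment mapped onto the residues of one structure chain. IC is in
#' bits, between 0 (unconserved) and log2(20) ~ 4.32 (fully conserved);
#' NA marks residues not covered by the alignment (or all-gap columns).
#'
#' @slot chain chain identifier the profile refers to.
#' @slot sequence one-letter chain sequence the profile is aligned to.
#' @slot ic per-residue information content, bits (NA = undefined).
#' @slot gapFraction per-residue weighted gap fraction of the mapped
#'   alignment column (NA where unmapped).
#' @slot column 1-based alignment column index mapped to each residue
#'   (NA where unmapped).
#' @export
setClass("ConservationProfile",
    representation(chain = "character", sequence = "character",
                   ic = "numeric", gapFraction = "numeric",
                   column = "integer"))

setValidity("ConservationProfile", function(object) {
    n <- nchar(object@sequence)
    if (length(object@ic) != n || length(object@gapFraction) != n ||
        length(object@column) != n)
        return("profile length must equal chain length")
    ok <- !is.na(object@ic)
    if (any(object@ic[ok] < -1e-9 | object@ic[ok] > log2(20) + 1e-9))
        return("IC outside [0, log2(20)]")
    TRUE
})
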