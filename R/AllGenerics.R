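#' @include AllClasses.R
NULL

#' Residue keys of a matrix-like object
#'
#' @param x an object carrying residue identities.
#' @return data.frame with columns `chain`, `resno`, `insert`, `resid`,
#'   one row per matrix row/column, in order.
#' @export
setGeneric("residueKeys", function(x) standardGeneric("residueKeys"))

#' Numeric matrix values of a matrix-like object
#'
#' @param x a [DistanceMatrix-class] or [CombinedMatrix-class].
#' @return numeric matrix with residue-key dimnames.
#' @export
setGeneric("matrixValues", function(x) standardGeneric("matrixValues"))

#' Extract an energy component matrix
#'
#' @param x an [InteractionEnergyMatrix-class].
#' @param component `"total"` (Coulomb + Lennard-Jones), `"coulomb"` or
#'   `"lj"`.
#' @return numeric matrix, kcal/mol, with residue-key dimnames.
#' @export
setGeneric("energyMatrix",
    function(x, component = c("total", "coulomb", "lj"))
        standardGeneric("energyMatrix"))

#' Per-residue total (net) interaction energies
#'
#' The total IE of a residue is the sum of its pairwise IEs with all
#' other residues (its row sum in the interaction energy matrix).
#'
#' @param x an [InteractionEnergyMatrix-class].
#' @return data.frame with residue keys and columns `coulomb`, `lj`,
#'   `total`, kcal/mol.
#' @export
setGeneric("totalEnergies", function(x) standardGeneric("totalEnergies"))

#' One-letter sequences of the polypeptide chains of a structure
#'
#' @param x a [Structure-class] or [ParameterizedStructure-class].
#' @return named character vector, one sequence per polypeptide chain
#'   (a chain with at least one standard amino acid) in file order;
#'   non-standard residues appear as `"X"`. Chains with no standard
#'   amino acid (e.g. water or ligand chains) are omitted.
#' @export
setGeneric("chainSequences", function(x) standardGeneric("chainSequences"))

#' Effective Born radii
#'
#' @param x a [BornRadii-class].
#' @return numeric vector of per-atom effective radii, Angstrom.
#' @export
setGeneric("effectiveRadii", function(x) standardGeneric("effectiveRadii"))
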