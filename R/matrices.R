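#' @include energetics.R
NULL

#' Distance between two residue atom sets
#'
#' `"closest"` is the minimum Euclidean distance over all cross atom
#' pairs; `"com"` is the distance between the mass-weighted centroids.
#'
#' @param xyzA,xyzB numeric matrices (atoms x 3), Angstrom.
#' @param metric `"closest"` or `"com"`.
#' @param massA,massB atomic masses (Da) for the COM metric; equal
#'   masses by default.
#' @return distance, Angstrom.
#' @export
residueDistance <- function(xyzA, xyzB, metric = c("closest", "com"),
                            massA = NULL, massB = NULL) {
    metric <- match.arg(metric)
    xyzA <- rbind(xyzA); xyzB <- rbind(xyzB)
    if (nrow(xyzA) == 0 || nrow(xyzB) == 0)
        iemUsageError("empty atom set in residueDistance")
    if (metric == "closest") {
        d2 <- outer(rowSums(xyzA^2), rowSums(xyzB^2), "+") -
            2 * xyzA %*% t(xyzB)
        sqrt(max(min(d2), 0))
    } else {
        if (is.null(massA)) massA <- rep(1, nrow(xyzA))
        if (is.null(massB)) massB <- rep(1, nrow(xyzB))
        ca <- colSums(xyzA * massA) / sum(massA)
        cb <- colSums(xyzB * massB) / sum(massB)
        sqrt(sum((ca - cb)^2))
    }
}

#' Build a residue-residue distance matrix
#'
#' Distances are computed under the chosen metric with the subgroup
#' restriction applied to both residues' atom sets (matching the
#' restriction used for the energies). Residues whose selection is
#' empty under the subgroup (e.g. glycine sidechain) get NA rows and
#' columns, with a warning.
#'
#' @param x a [Structure-class] or [ParameterizedStructure-class].
#' @param metric `"closest"` or `"com"`.
#' @param subgroup atom subgroup restriction.
#' @return a [DistanceMatrix-class].
#' @export
buildDistanceMatrix <- function(x, metric = c("closest", "com"),
                                subgroup = "all") {
    metric <- match.arg(metric)
    a <- atoms(x)
    mask <- subgroupMask(x, subgroup)
    keys <- residues(x)
    n <- nrow(keys)
    V <- matrix(NA_real_, n, n)
    diag(V) <- 0
    sets <- lapply(keys$resIndex, function(i) which(a$resIndex == i & mask))
    empty <- lengths(sets) == 0
    if (any(empty))
        warning(sum(empty), " residue(s) with empty '", subgroup,
                "' selection; distances undefined (NA)")
    xyz <- as.matrix(a[, c("x", "y", "z")])
    for (i in seq_len(n)) {
        if (empty[i]) { V[i, ] <- NA; V[, i] <- NA; next }
        for (j in seq_len(i - 1L)) {
            if (empty[j]) next
            V[i, j] <- V[j, i] <- residueDistance(
                xyz[sets[[i]], , drop = FALSE],
                xyz[sets[[j]], , drop = FALSE], metric,
                massA = a$mass[sets[[i]]], massB = a$mass[sets[[j]]])
        }
    }
    if (any(empty)) diag(V)[empty] <- NA
    ks <- .residueKeyStrings(keys)
    dimnames(V) <- list(ks, ks)
    new("DistanceMatrix",
        residueKeys = keys[, c("chain", "resno", "insert", "resid")],
        values = V, metric = metric, subgroup = subgroup)
}

#' @export
setMethod("residueKeys", "DistanceMatrix", function(x) x@residueKeys)

#' @export
setMethod("matrixValues", "DistanceMatrix", function(x) x@values)

setMethod("show", "DistanceMatrix", function(object) {
    n <- nrow(object@residueKeys)
    cat("DistanceMatrix: ", n, " x ", n, " residues, metric ",
        object@metric, ", subgroup ", object@subgroup, "\n", sep = "")
})

#' Combine an energy matrix with a distance matrix
#'
#' Residue pairs at or below the distance threshold carry their
#' complete pairwise interaction energy; pairs further apart carry
#' their distance (the masked part — distant pairs have IEs near zero
#' and would otherwise hide the informative contacts). Every
#' off-diagonal cell is exactly one of the two.
#'
#' @param iem an [InteractionEnergyMatrix-class].
#' @param dm a [DistanceMatrix-class] over the same residues and
#'   subgroup.
#' @param threshold distance threshold, Angstrom (default 5).
#' @return a [CombinedMatrix-class].
#' @export
combineMatrices <- function(iem, dm, threshold = 5.0) {
    stopifnot(is(iem, "InteractionEnergyMatrix"), is(dm, "DistanceMatrix"))
    if (!identical(iem@residueKeys, dm@residueKeys))
        iemUsageError("energy and distance matrices cover different residues")
    if (!identical(iem@subgroup, dm@subgroup))
        iemUsageError("energy and distance matrices use different subgroups")
    E <- energyMatrix(iem, "total")
    D <- dm@values
    isE <- !is.na(D) & D <= threshold
    diag(isE) <- FALSE
    V <- ifelse(isE, E, D)
    diag(V) <- 0
    new("CombinedMatrix", residueKeys = iem@residueKeys, values = V,
        isEnergy = isE, threshold = threshold)
}

#' @export
setMethod("residueKeys", "CombinedMatrix", function(x) x@residueKeys)

#' @export
setMethod("matrixValues", "CombinedMatrix", function(x) x@values)

#' Which cells of a combined matrix are energy-valued
#'
#' @param x a [CombinedMatrix-class].
#' @return logical matrix; TRUE where the cell carries an energy.
#' @export
isEnergyCell <- function(x) {
    stopifnot(is(x, "CombinedMatrix"))
    x@isEnergy
}

setMethod("show", "CombinedMatrix", function(object) {
    n <- nrow(object@residueKeys)
    cat("CombinedMatrix: ", n, " x ", n, " residues, threshold ",
        object@threshold, " Angstrom; ",
        sum(object@isEnergy[upper.tri(object@isEnergy)]),
        " energy-valued pair(s)\n", sep = "")
})

## ---- tabular export -----------------------------------------------------

.formatNum <- function(x) {
    out <- ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g",
                                          digits = 6))
    out
}

.exportMatrix <- function(keys, values, path, sep) {
    ks <- .residueKeyStrings(keys)
    lines <- c(paste(c("residue", ks), collapse = sep),
               vapply(seq_len(nrow(values)), function(i)
                   paste(c(ks[i], .formatNum(values[i, ])), collapse = sep),
                   character(1)))
    writeLines(lines, path)
    invisible(path)
}

#' Export a matrix object to TSV/CSV
#'
#' Writes the numeric matrix with residue-key row and column headers
#' (`chain:resSeq:iCode:name`), values at 6 significant digits.
#'
#' @param x an [InteractionEnergyMatrix-class], [DistanceMatrix-class]
#'   or [CombinedMatrix-class].
#' @param path output file path.
#' @param format `"tsv"` or `"csv"`.
#' @param component energy component, for interaction energy matrices.
#' @return `path`, invisibly.
#' @export
writeMatrixTable <- function(x, path, format = c("tsv", "csv"),
                             component = "total") {
    format <- match.arg(format)
    sep <- if (format == "tsv") "\t" else ","
    values <- if (is(x, "InteractionEnergyMatrix"))
        energyMatrix(x, component) else matrixValues(x)
    .exportMatrix(residueKeys(x), values, path, sep)
}

#' Export a matrix object to JSON
#'
#' Carries the matrix, residue keys and metadata (model or metric,
#' subgroup, threshold where applicable) plus per-residue totals for
#' energy matrices.
#'
#' @inheritParams writeMatrixTable
#' @return `path`, invisibly.
#' @export
writeMatrixJSON <- function(x, path) {
    keys <- residueKeys(x)
    payload <- list(residues = .residueKeyStrings(keys))
    if (is(x, "InteractionEnergyMatrix")) {
        payload$kind <- "interaction_energy_matrix"
        payload$model <- list(kind = x@model@kind, eps_in = x@model@epsIn,
                              eps_out = x@model@epsOut,
                              dddc_slope = x@model@dddcSlope)
        payload$subgroup <- x@subgroup
        payload$coulomb <- signif(unname(energyMatrix(x, "coulomb")), 6)
        payload$lj <- signif(unname(energyMatrix(x, "lj")), 6)
        payload$total <- signif(unname(energyMatrix(x, "total")), 6)
        tot <- totalEnergies(x)
        payload$total_ie <- signif(tot$total, 6)
    } else if (is(x, "DistanceMatrix")) {
        payload$kind <- "distance_matrix"
        payload$metric <- x@metric
        payload$subgroup <- x@subgroup
        payload$values <- signif(unname(x@values), 6)
    } else if (is(x, "CombinedMatrix")) {
        payload$kind <- "combined_matrix"
        payload$threshold <- x@threshold
        payload$values <- signif(unname(x@values), 6)
        payload$is_energy <- unname(x@isEnergy)
    } else iemUsageError("unsupported object for JSON export")
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
    invisible(path)
}
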