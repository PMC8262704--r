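#' @include structure-io.R
NULL

PARAM_COLUMNS <- c("residue", "atom", "charge", "sigma", "epsilon",
                   "gb_rho", "gb_scale")
PARAM_MANDATORY <- c("residue", "atom", "charge", "sigma", "epsilon")

#' Load a force-field parameter table
#'
#' Reads a UTF-8 TSV with header
#' `residue atom charge sigma epsilon gb_rho gb_scale` (the two GB
#' columns may be absent for tables intended for vacuum/DDDC use only)
#' and one row per template atom; `#` starts a comment. Units: charges
#' in elementary charges, sigma and gb_rho in Angstrom, epsilon in
#' kcal/mol, gb_scale dimensionless.
#'
#' @param path path to the parameter TSV.
#' @param name label for the set (defaults to the file name).
#' @param combiningRule Lennard-Jones combining rule for the set.
#' @return a [ParameterSet-class].
#' @export
loadParameterSet <- function(path, name = basename(path),
                             combiningRule = c("lorentz_berthelot",
                                               "geometric")) {
    combiningRule <- match.arg(combiningRule)
    if (!is.character(path) || length(path) != 1 || !file.exists(path))
        iemInputError(paste("cannot read parameter table:", path))
    lines <- readLines(path, warn = FALSE)
    keep <- which(!grepl("^\\s*(#|$)", lines))
    if (length(keep) < 1)
        iemInputError("parameter table is empty")
    fields <- strsplit(trimws(lines[keep]), "\\s+")
    header <- fields[[1]]
    if (!all(PARAM_MANDATORY %in% header))
        iemInputError(paste("parameter table missing mandatory column(s):",
                            paste(setdiff(PARAM_MANDATORY, header),
                                  collapse = ", ")))
    unknown <- setdiff(header, PARAM_COLUMNS)
    if (length(unknown))
        iemInputError(paste("unknown parameter table column(s):",
                            paste(unknown, collapse = ", ")))
    ncol <- length(header)
    rows <- fields[-1]
    lineno <- keep[-1]
    bad <- which(lengths(rows) != ncol)
    if (length(bad))
        iemInputError(paste0("malformed parameter table line ",
                             lineno[bad[1]], ": expected ", ncol,
                             " fields, got ", lengths(rows)[bad[1]]))
    tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(tab) <- header
    for (cn in setdiff(header, c("residue", "atom"))) {
        v <- suppressWarnings(as.numeric(tab[[cn]]))
        if (anyNA(v))
            iemInputError(paste0("non-numeric value in column '", cn,
                                 "' at line ",
                                 lineno[which(is.na(v))[1]]))
        tab[[cn]] <- v
    }
    for (cn in setdiff(PARAM_COLUMNS, header)) tab[[cn]] <- NA_real_
    tab <- tab[, PARAM_COLUMNS]
    dup <- duplicated(tab[, c("residue", "atom")])
    if (any(dup))
        iemInputError(paste0("duplicate atom row in template: ",
                             tab$residue[dup][1], "/", tab$atom[dup][1]))
    new("ParameterSet", name = name, templates = tab,
        combiningRule = combiningRule)
}

#' Built-in minimal parameter set
#'
#' A minimal, internally consistent, illustrative nonbonded parameter
#' table covering all 20 standard amino acids with hydrogens:
#' Amber-99-like backbone charges with group-rule side-chain charges
#' balanced exactly to the residue formal charge, Amber-type
#' Lennard-Jones classes, mbondi2-like intrinsic GB radii and
#' element-based HCT descreening scales. Intended for testing and
#' method exploration; for production scoring supply a table derived
#' from a published force field via [loadParameterSet()].
#'
#' @return a [ParameterSet-class] with 20 residue templates.
#' @export
defaultParameterSet <- function() {
    path <- system.file("extdata", "minimal_ff.tsv",
                        package = "ResidueIEM", mustWork = TRUE)
    loadParameterSet(path, name = "minimal")
}

## name-based terminal patches: atoms present only in terminal residue
## variants are parameterized from a donor atom of the same template
TERMINAL_PATCHES <- c(OXT = "O", H1 = "H", H2 = "H", H3 = "H")

#' Assign force-field parameters to a structure
#'
#' Looks up each atom's nonbonded parameters by (residue name, atom
#' name) in the parameter set's templates. Terminal-variant atom names
#' (OXT, H1-H3) are resolved by a name-based patch to the corresponding
#' mid-chain atom (O, H). Atoms without a template row are recorded in
#' `unassigned`; template atoms absent from a residue (e.g. missing
#' hydrogens) are recorded in `missing`. Nothing is dropped silently;
#' energetics later refuse selections containing unassigned atoms.
#'
#' @param x a [Structure-class].
#' @param ps a [ParameterSet-class].
#' @return a [ParameterizedStructure-class].
#' @export
assignParameters <- function(x, ps) {
    stopifnot(is(x, "Structure"), is(ps, "ParameterSet"))
    a <- x@atoms
    t <- ps@templates
    tkey <- paste(t$residue, t$atom, sep = "\r")
    akey <- paste(a$resid, a$elety, sep = "\r")
    idx <- match(akey, tkey)
    ## terminal patch: retry unmatched OXT/H1/H2/H3 via their donors
    patch <- which(is.na(idx) & a$elety %in% names(TERMINAL_PATCHES))
    if (length(patch)) {
        donor <- TERMINAL_PATCHES[a$elety[patch]]
        idx[patch] <- match(paste(a$resid[patch], donor, sep = "\r"), tkey)
    }
    pcols <- c("charge", "sigma", "epsilon", "gb_rho", "gb_scale")
    params <- t[idx, pcols, drop = FALSE]
    rownames(params) <- NULL
    keycols <- c("chain", "resno", "insert", "resid", "elety")
    unassigned <- a[is.na(idx), keycols, drop = FALSE]
    rownames(unassigned) <- NULL

    ## missing template atoms per residue (N-terminal H1-H3 satisfy H)
    miss <- list()
    r <- residues(x)
    for (i in seq_len(nrow(r))) {
        if (!r$resid[i] %in% t$residue) next
        have <- a$elety[a$resIndex == r$resIndex[i]]
        want <- t$atom[t$residue == r$resid[i]]
        m <- setdiff(want, have)
        if ("H" %in% m && any(c("H1", "H2", "H3") %in% have))
            m <- setdiff(m, "H")
        if (length(m))
            miss[[length(miss) + 1]] <- data.frame(
                chain = r$chain[i], resno = r$resno[i],
                insert = r$insert[i], resid = r$resid[i], elety = m,
                stringsAsFactors = FALSE)
    }
    missing <- if (length(miss)) do.call(rbind, miss) else
        data.frame(chain = character(0), resno = integer(0),
                   insert = character(0), resid = character(0),
                   elety = character(0), stringsAsFactors = FALSE)
    new("ParameterizedStructure", structure = x, parameters = params,
        unassigned = unassigned, missing = missing)
}

#' Unassigned and missing atoms of a parameterized structure
#'
#' @param x a [ParameterizedStructure-class].
#' @return data.frame of atoms present in the structure but absent from
#'   the parameter templates (`unassignedAtoms`), or template atoms
#'   absent from the structure (`missingAtoms`).
#' @export
unassignedAtoms <- function(x) {
    stopifnot(is(x, "ParameterizedStructure"))
    x@unassigned
}

#' @rdname unassignedAtoms
#' @export
missingAtoms <- function(x) {
    stopifnot(is(x, "ParameterizedStructure"))
    x@missing
}

#' Combine Lennard-Jones parameters for an atom pair
#'
#' Lorentz-Berthelot: `sigma_ij = (sigma_i + sigma_j)/2`,
#' `eps_ij = sqrt(eps_i * eps_j)`; geometric: geometric means of both.
#' Vectorized over atom pairs.
#'
#' @param sigma1,sigma2 per-atom sigma, Angstrom.
#' @param eps1,eps2 per-atom epsilon, kcal/mol.
#' @param rule combining rule.
#' @return list with components `sigma` and `epsilon`.
#' @export
ljCombine <- function(sigma1, eps1, sigma2, eps2,
                      rule = c("lorentz_berthelot", "geometric")) {
    rule <- match.arg(rule)
    sigma <- if (rule == "lorentz_berthelot") (sigma1 + sigma2) / 2
             else sqrt(sigma1 * sigma2)
    list(sigma = sigma, epsilon = sqrt(eps1 * eps2))
}

setMethod("show", "ParameterSet", function(object) {
    cat("ParameterSet '", object@name, "': ",
        length(unique(object@templates$residue)), " residue templates, ",
        nrow(object@templates), " atom rows, ",
        object@combiningRule, " combining rule\n", sep = "")
})

setMethod("show", "ParameterizedStructure", function(object) {
    cat("ParameterizedStructure:", nrow(object@structure@atoms), "atoms;",
        nrow(object@unassigned), "unassigned,",
        nrow(object@missing), "missing template atoms\n")
})
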