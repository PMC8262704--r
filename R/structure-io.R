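#' @include AllClasses.R AllGenerics.R
NULL

## classed conditions used across the package; the CLI wrapper maps them
## to exit codes (input 1, parameterization 2, environment 3)
iemStop <- function(class, message, call = sys.call(-1)) {
    stop(structure(class = c(class, "iemError", "error", "condition"),
                   list(message = message, call = call)))
}

iemInputError <- function(message) iemStop("iemInputError", message)
iemUsageError <- function(message) iemStop("iemUsageError", message)
iemParamError <- function(message) iemStop("iemParameterizationError", message)
iemEnvError <- function(message) iemStop("iemEnvironmentError", message)

## three-letter -> one-letter code for the 20 standard amino acids
AA_THREE_TO_ONE <- c(
    ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
    GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
    LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
    SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

STANDARD_RESIDUES <- names(AA_THREE_TO_ONE)

## atomic masses (Da) for elements commonly seen in PDB files
ELEMENT_MASSES <- c(
    H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
    S = 32.06, P = 30.974, SE = 78.971, F = 18.998, CL = 35.45,
    BR = 79.904, I = 126.904, `NA` = 22.990, K = 39.098, MG = 24.305,
    CA = 40.078, MN = 54.938, FE = 55.845, CO = 58.933, NI = 58.693,
    CU = 63.546, ZN = 65.38)

## backbone atom names: N, CA, C, O plus their bonded hydrogens and the
## terminal backbone atoms (OXT and the N-terminal ammonium H1-H3)
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "H", "HA", "HA2", "HA3",
                    "OXT", "H1", "H2", "H3")

.elementFromName <- function(elety) {
    nm <- toupper(gsub("[0-9']", "", elety))
    two <- substr(nm, 1, 2)
    one <- substr(nm, 1, 1)
    ## single-letter organic elements win over two-letter metals: a
    ## protein "HG" atom is a gamma hydrogen, not mercury
    ifelse(one %in% c("H", "C", "N", "O", "S", "P"), one,
           ifelse(two %in% names(ELEMENT_MASSES), two, one))
}

.massForElement <- function(element) {
    m <- ELEMENT_MASSES[element]
    if (anyNA(m)) {
        warning("unknown element(s) ",
                paste(unique(element[is.na(m)]), collapse = ", "),
                "; using carbon mass")
        m[is.na(m)] <- ELEMENT_MASSES[["C"]]
    }
    unname(m)
}

#' Read a PDB file into a Structure
#'
#' Parses the ATOM/HETATM records of the first model. Alternate
#' locations are resolved to a single atom by keeping the record with
#' the highest occupancy (ties: first encountered). HETATM records are
#' retained and flagged (`het = TRUE`); they are reported as
#' unparameterizable downstream unless a template covers them.
#'
#' @param path path to a PDB file.
#' @return a [Structure-class].
#' @examples
#' pdb <- makeToyStructure("dipeptide", dir = tempdir())
#' s <- readPDB(pdb$pdb)
#' nrow(atoms(s))
#' @export
readPDB <- function(path) {
    if (!is.character(path) || length(path) != 1 || !file.exists(path))
        iemInputError(paste("cannot read PDB file:", path))
    pdb <- tryCatch(
        suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                         rm.alt = FALSE,
                                         rm.insert = FALSE,
                                         verbose = FALSE)),
        error = function(e)
            iemInputError(paste("failed to parse PDB file:",
                                conditionMessage(e))))
    a <- pdb$atom
    if (is.null(a) || nrow(a) == 0 || !any(a$type == "ATOM"))
        iemInputError("no ATOM records found (empty structure)")

    a$insert[is.na(a$insert)] <- ""
    a$chain[is.na(a$chain)] <- " "
    a$alt[is.na(a$alt)] <- ""
    a$o[is.na(a$o)] <- 1.0

    ## altloc resolution: highest occupancy per (chain, resno, insert,
    ## atom name); ties broken by file order
    key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
    ord <- order(key, -a$o, seq_len(nrow(a)))
    a <- a[ord[!duplicated(key[ord])], , drop = FALSE]
    a <- a[order(as.integer(rownames(a))), , drop = FALSE]

    element <- a$elesy
    bad <- is.na(element) | !nzchar(trimws(element))
    element[!bad] <- toupper(trimws(element[!bad]))
    element[bad] <- .elementFromName(a$elety[bad])

    atoms <- data.frame(
        chain = a$chain, resno = a$resno, insert = a$insert,
        resid = a$resid, elety = a$elety, eleno = a$eleno,
        x = a$x, y = a$y, z = a$z,
        element = element, mass = .massForElement(element),
        het = a$type == "HETATM",
        stringsAsFactors = FALSE)
    rk <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
    atoms$resIndex <- match(rk, unique(rk))
    rownames(atoms) <- NULL
    new("Structure", atoms = atoms, title = "")
}

#' Write a Structure back to a PDB file
#'
#' @param x a [Structure-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePDB <- function(x, path) {
    stopifnot(is(x, "Structure"))
    a <- x@atoms
    bio3d::write.pdb(file = path,
                     type = ifelse(a$het, "HETATM", "ATOM"),
                     eleno = a$eleno, elety = a$elety, resid = a$resid,
                     chain = ifelse(a$chain == " ", "", a$chain),
                     resno = a$resno, insert = a$insert,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                     elesy = a$element)
    invisible(path)
}

#' Atom table of a Structure
#'
#' @param x a [Structure-class] or [ParameterizedStructure-class].
#' @return the atom data.frame (see [Structure-class]).
#' @export
atoms <- function(x) {
    if (is(x, "ParameterizedStructure")) x <- x@structure
    stopifnot(is(x, "Structure"))
    x@atoms
}

#' Residue table of a Structure
#'
#' @param x a [Structure-class] or [ParameterizedStructure-class].
#' @return data.frame with one row per residue (`resIndex`, `chain`,
#'   `resno`, `insert`, `resid`) in file order.
#' @export
residues <- function(x) {
    a <- atoms(x)
    r <- a[!duplicated(a$resIndex),
           c("resIndex", "chain", "resno", "insert", "resid")]
    rownames(r) <- NULL
    r
}

.residueKeyStrings <- function(keys) {
    paste(keys$chain, keys$resno, keys$insert, keys$resid, sep = ":")
}

#' @describeIn chainSequences sequences of the chains of a parsed
#'   structure.
#' @export
setMethod("chainSequences", "Structure", function(x) {
    r <- residues(x)
    out <- character(0)
    for (ch in unique(r$chain)) {
        rc <- r[r$chain == ch, , drop = FALSE]
        if (!any(rc$resid %in% STANDARD_RESIDUES)) next
        code <- AA_THREE_TO_ONE[rc$resid]
        code[is.na(code)] <- "X"
        out[ch] <- paste(code, collapse = "")
    }
    out
})

#' @export
setMethod("chainSequences", "ParameterizedStructure",
          function(x) chainSequences(x@structure))

#' Atom subgroup selection mask
#'
#' Selects atoms by structural role: `"backbone"` keeps N, CA, C, O,
#' their bonded hydrogens (H, HA, HA2, HA3) and the terminal backbone
#' atoms (OXT, H1-H3); `"sidechain"` is the complement within each
#' residue; `"all"` keeps everything. For every residue the backbone
#' and sidechain masks are disjoint and their union is the full atom
#' set.
#'
#' @param x a [Structure-class] or [ParameterizedStructure-class].
#' @param subgroup one of `"all"`, `"backbone"`, `"sidechain"`.
#' @return logical vector over the structure's atoms.
#' @export
subgroupMask <- function(x, subgroup = c("all", "backbone", "sidechain")) {
    if (!is.character(subgroup) || length(subgroup) != 1 ||
        !subgroup %in% c("all", "backbone", "sidechain"))
        iemUsageError("subgroup must be one of: all, backbone, sidechain")
    a <- atoms(x)
    switch(subgroup,
           all = rep(TRUE, nrow(a)),
           backbone = a$elety %in% BACKBONE_ATOMS,
           sidechain = !(a$elety %in% BACKBONE_ATOMS))
}

setMethod("show", "Structure", function(object) {
    r <- residues(object)
    cat("Structure with", nrow(object@atoms), "atoms,", nrow(r),
        "residues,", length(unique(r$chain)), "chain(s)\n")
    sq <- chainSequences(object)
    for (ch in names(sq))
        cat("  chain ", ch, ": ", substr(sq[ch], 1, 60),
            if (nchar(sq[ch]) > 60) "..." else "", "\n", sep = "")
})
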