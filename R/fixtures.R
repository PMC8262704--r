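#' @include conservation.R
NULL

## idealized alanine geometry (Angstrom, local frame); bond lengths
## follow standard values, all interatomic distances >= 1.0
ALA_TEMPLATE <- data.frame(
    elety = c("N", "H", "CA", "HA", "CB", "HB1", "HB2", "HB3", "C", "O"),
    element = c("N", "H", "C", "H", "C", "H", "H", "H", "C", "O"),
    x = c(0.000, -0.960, 1.458, 1.800, 1.990, 3.080, 1.640, 1.640,
          2.000, 1.250),
    y = c(0.000, 0.310, 0.000, -0.500, 1.420, 1.400, 1.960, 1.960,
          -0.770, -1.590),
    z = c(0.000, 0.000, 0.000, -0.880, 0.000, 0.000, 0.880, -0.880,
          1.200, 1.730),
    stringsAsFactors = FALSE)

## Amber-94-style alanine charges (sum exactly 0) with Amber-type LJ,
## mbondi2-like GB radii and element HCT scales
ALA_PARAMS <- data.frame(
    residue = "ALA",
    atom = c("N", "H", "CA", "HA", "CB", "HB1", "HB2", "HB3", "C", "O"),
    charge = c(-0.4157, 0.2719, 0.0337, 0.0823, -0.1825, 0.0603,
               0.0603, 0.0603, 0.5973, -0.5679),
    sigma = c(3.2500, 1.0691, 3.3997, 2.6495, 3.3997, 2.6495, 2.6495,
              2.6495, 3.3997, 2.9599),
    epsilon = c(0.1700, 0.0157, 0.1094, 0.0157, 0.1094, 0.0157, 0.0157,
                0.0157, 0.0860, 0.2100),
    gb_rho = c(1.55, 1.30, 1.70, 1.20, 1.70, 1.20, 1.20, 1.20, 1.70, 1.50),
    gb_scale = c(0.79, 0.85, 0.72, 0.85, 0.72, 0.85, 0.85, 0.85, 0.72,
                 0.85),
    stringsAsFactors = FALSE)

.writeParamTable <- function(tab, path) {
    lines <- c("# fixture parameter table",
               paste(PARAM_COLUMNS, collapse = "\t"),
               paste(tab$residue, tab$atom,
                     formatC(tab$charge, format = "f", digits = 4),
                     formatC(tab$sigma, format = "f", digits = 4),
                     formatC(tab$epsilon, format = "f", digits = 4),
                     formatC(tab$gb_rho, format = "f", digits = 2),
                     formatC(tab$gb_scale, format = "f", digits = 2),
                     sep = "\t"))
    writeLines(lines, path)
    path
}

.structureFromAtoms <- function(df) {
    df$mass <- .massForElement(df$element)
    df$het <- FALSE
    df$eleno <- seq_len(nrow(df))
    df$insert <- ""
    rk <- paste(df$chain, df$resno, df$insert, sep = "\r")
    df$resIndex <- match(rk, unique(rk))
    new("Structure",
        atoms = df[, c("chain", "resno", "insert", "resid", "elety",
                       "eleno", "x", "y", "z", "element", "mass", "het",
                       "resIndex")],
        title = "")
}

.rotZ <- function(theta)
    matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0,
             0, 0, 1), 3, 3)

#' Generate a deterministic toy structure fixture
#'
#' Writes a well-formed PDB and a matching parameter table (covering
#' every atom, so tests never depend on the shipped force-field
#' table). Available kinds:
#' \describe{
#'   \item{two_atom}{two single-atom residues, charges `charges`,
#'     separated by `r` Angstrom along x (Coulomb worked examples).}
#'   \item{two_sphere}{two single-atom residues with GB radii 1.5 and
#'     HCT scale 0.8 at `r = 3` Angstrom (Born-radius fixtures).}
#'   \item{dipeptide}{two fully protonated alanine residues, 6
#'     Angstrom apart, completely parameterized.}
#'   \item{helix}{`n` alanine residues on a helical arrangement (100
#'     degree twist, 3 Angstrom rise, 2 Angstrom radial offset per
#'     residue), packed near van-der-Waals contact without clashes.}
#' }
#' Identical arguments (including `seed`) give byte-identical files.
#'
#' @param kind fixture kind, see description.
#' @param dir output directory (created if needed).
#' @param seed integer seed (fixtures are deterministic; the seed is
#'   part of the file names so callers can keep variants apart).
#' @param n number of residues for `"helix"`.
#' @param r separation in Angstrom for the two-atom kinds.
#' @param charges length-2 charges for `"two_atom"`/`"two_sphere"`.
#' @return list with elements `pdb` and `params` (file paths).
#' @export
makeToyStructure <- function(kind = c("dipeptide", "two_atom",
                                      "two_sphere", "helix"),
                             dir = tempdir(), seed = 1L, n = 10L,
                             r = NULL, charges = c(1, -1)) {
    kind <- match.arg(kind)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    stem <- file.path(dir, paste0("fixture_", kind, "_", seed))
    pdbPath <- paste0(stem, ".pdb")
    parPath <- paste0(stem, "_ff.tsv")

    if (kind %in% c("two_atom", "two_sphere")) {
        if (is.null(r)) r <- if (kind == "two_atom") 3.320636 else 3.0
        df <- data.frame(
            chain = "A", resno = 1:2, resid = c("DUA", "DUB"),
            elety = "Q1", element = "C",
            x = c(0, r), y = 0, z = 0, stringsAsFactors = FALSE)
        gb <- if (kind == "two_sphere") c(1.5, 0.8) else c(1.5, 0.8)
        tab <- data.frame(residue = c("DUA", "DUB"), atom = "Q1",
                          charge = charges, sigma = 3.4,
                          epsilon = if (kind == "two_atom") 0 else 0.1,
                          gb_rho = gb[1], gb_scale = gb[2],
                          stringsAsFactors = FALSE)
    } else if (kind == "dipeptide") {
        t1 <- ALA_TEMPLATE; t2 <- ALA_TEMPLATE
        t2$x <- t2$x + 6.0
        df <- rbind(cbind(t1, resno = 1), cbind(t2, resno = 2))
        df$chain <- "A"; df$resid <- "ALA"
        tab <- ALA_PARAMS
    } else {                                   # helix
        set.seed(seed)
        parts <- lapply(seq_len(n), function(k) {
            R <- .rotZ((k - 1) * 100 * pi / 180)
            xyz <- as.matrix(ALA_TEMPLATE[, c("x", "y", "z")])
            xyz[, 1] <- xyz[, 1] + 2.0
            xyz <- xyz %*% t(R)
            xyz[, 3] <- xyz[, 3] + (k - 1) * 3.0
            out <- ALA_TEMPLATE
            out$x <- round(xyz[, 1], 3); out$y <- round(xyz[, 2], 3)
            out$z <- round(xyz[, 3], 3)
            out$resno <- k
            out
        })
        df <- do.call(rbind, parts)
        df$chain <- "A"; df$resid <- "ALA"
        tab <- ALA_PARAMS
    }
    df$x <- round(df$x, 3); df$y <- round(df$y, 3); df$z <- round(df$z, 3)
    s <- .structureFromAtoms(df)
    writePDB(s, pdbPath)
    .writeParamTable(tab, parPath)
    list(pdb = pdbPath, params = parPath)
}

#' Generate a deterministic toy alignment fixture
#'
#' Writes an aligned FASTA with a known conservation pattern per
#' column: `"conserved"` columns contain one amino-acid type in every
#' row (IC = log2(20) by construction), `"uniform20"` columns cycle
#' through the 20 standard amino acids (IC = 0 when `nRows = 20` and
#' weights are equal) and `"random"` columns are drawn uniformly from
#' the 20 amino acids under the seed. Identical arguments give
#' byte-identical files.
#'
#' @param nRows number of sequences (>= 1).
#' @param pattern character vector, one of `"conserved"`,
#'   `"uniform20"`, `"random"` per column.
#' @param seed integer seed for the random columns.
#' @param dir output directory.
#' @return list with `path` (FASTA file) and `rows` (named character
#'   vector of the aligned rows).
#' @export
makeToyMSA <- function(nRows = 20L,
                       pattern = c("conserved", "uniform20", "random"),
                       seed = 1L, dir = tempdir()) {
    if (nRows < 1) iemUsageError("nRows must be >= 1")
    bad <- setdiff(pattern, c("conserved", "uniform20", "random"))
    if (length(bad))
        iemUsageError(paste("unknown column pattern:", bad[1]))
    set.seed(seed)
    cols <- lapply(pattern, function(p) switch(p,
        conserved = rep("W", nRows),
        uniform20 = AA20[((seq_len(nRows) - 1) %% 20) + 1],
        random = sample(AA20, nRows, replace = TRUE)))
    m <- do.call(cbind, cols)
    rows <- apply(m, 1, paste, collapse = "")
    names(rows) <- sprintf("row%02d", seq_len(nRows))
    path <- file.path(dir, sprintf("fixture_msa_%d_%d.fasta", nRows, seed))
    writeLines(rbind(paste0(">", names(rows)), rows), path)
    list(path = path, rows = rows)
}
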