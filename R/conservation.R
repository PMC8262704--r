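#' @include matrices.R
NULL

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read a multiple sequence alignment
#'
#' Reads aligned FASTA or Stockholm into a Biostrings
#' `AAMultipleAlignment`. Sequences are normalized to upper case and
#' `.` gap characters to `-`; ragged alignments are rejected.
#'
#' @param path alignment file path.
#' @param format `"fasta"` or `"stockholm"`.
#' @return an `AAMultipleAlignment`.
#' @export
readMSA <- function(path, format = c("fasta", "stockholm")) {
    format <- match.arg(format)
    if (!is.character(path) || length(path) != 1 || !file.exists(path))
        iemInputError(paste("cannot read alignment file:", path))
    aln <- tryCatch(
        Biostrings::readAAMultipleAlignment(path, format = format),
        error = function(e)
            iemInputError(paste0("failed to parse alignment (", format,
                                 "): ", conditionMessage(e))))
    rows <- as.character(Biostrings::unmasked(aln))
    if (length(rows) == 0 || all(nchar(rows) == 0))
        iemInputError("empty alignment")
    rows <- chartr(".", "-", toupper(rows))
    if (length(unique(nchar(rows))) != 1)
        iemInputError("ragged alignment: rows differ in length")
    Biostrings::AAMultipleAlignment(rows)
}

## normalized character matrix (rows x columns) from an alignment in
## any accepted representation
.msaMatrix <- function(msa) {
    if (is.matrix(msa) && is.character(msa)) return(msa)
    rows <- if (methods::is(msa, "AAMultipleAlignment"))
        as.character(Biostrings::unmasked(msa))
    else if (is.character(msa)) msa
    else iemUsageError("msa must be an AAMultipleAlignment or character vector")
    if (length(rows) < 1) iemInputError("alignment has no rows")
    rows <- chartr(".", "-", toupper(rows))
    if (length(unique(nchar(rows))) != 1)
        iemInputError("ragged alignment: rows differ in length")
    m <- do.call(rbind, strsplit(rows, ""))
    rownames(m) <- if (!is.null(names(rows))) names(rows) else
        paste0("seq", seq_along(rows))
    m
}

#' Gerstein/Sonnhammer/Chothia sequence weights
#'
#' Tree-based weights that damp the contribution of redundant
#' sequences. Pairwise distances are one minus fractional identity
#' (computed over columns where neither row has a gap); a UPGMA guide
#' tree is built on them, and each branch's length is divided among
#' the leaves below it in proportion to their accumulated weights
#' (equal split where all are still zero), moving from the leaves
#' toward the root. Weights are rescaled to mean one.
#'
#' @param msa an `AAMultipleAlignment` or character vector of aligned
#'   rows.
#' @return numeric vector of weights (mean 1), named by row.
#' @export
gscWeights <- function(msa) {
    m <- .msaMatrix(msa)
    n <- nrow(m)
    if (n == 1) return(stats::setNames(1, rownames(m)))
    gap <- m == "-"
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        ok <- !gap[i, ] & !gap[j, ]
        D[i, j] <- D[j, i] <- if (!any(ok)) 1 else
            1 - sum(m[i, ok] == m[j, ok]) / sum(ok)
    }
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    w <- numeric(n)
    leaves <- vector("list", n - 1)
    heights <- numeric(n - 1)
    childHeight <- function(c) if (c < 0) 0 else heights[c]
    childLeaves <- function(c) if (c < 0) -c else leaves[[c]]
    for (k in seq_len(n - 1)) {
        hk <- hc$height[k]
        for (side in 1:2) {
            ch <- hc$merge[k, side]
            b <- hk - childHeight(ch)
            L <- childLeaves(ch)
            cw <- w[L]
            share <- if (sum(cw) <= 1e-12) rep(1 / length(L), length(L))
                     else cw / sum(cw)
            w[L] <- w[L] + b * share
        }
        leaves[[k]] <- c(childLeaves(hc$merge[k, 1]),
                         childLeaves(hc$merge[k, 2]))
        heights[k] <- hk
    }
    if (sum(w) <= 1e-12) w <- rep(1, n)   # all rows identical
    stats::setNames(w / mean(w), rownames(m))
}

#' Weighted per-column information content
#'
#' Weighted amino-acid frequencies are formed over the 20 standard
#' residues (gaps and ambiguity codes B/Z/X are excluded and the
#' remaining weight mass renormalized); the information content is
#' `log2(20) - H` with `H` the weighted Shannon entropy, in bits.
#' Columns with no standard residue are undefined (NA).
#'
#' @param msa an `AAMultipleAlignment` or character vector.
#' @param weights sequence weights (defaults to [gscWeights()]).
#' @param columns 1-based column indices (default: all columns).
#' @return numeric vector of IC values in bits, `[0, log2(20)]` or NA.
#' @export
columnIC <- function(msa, weights = NULL, columns = NULL) {
    m <- .msaMatrix(msa)
    if (is.null(weights)) weights <- gscWeights(m)
    if (length(weights) != nrow(m))
        iemUsageError("one weight per alignment row required")
    if (is.null(columns)) columns <- seq_len(ncol(m))
    if (any(columns < 1 | columns > ncol(m)))
        iemUsageError("column index out of range")
    vapply(columns, function(j) {
        col <- m[, j]
        keep <- col %in% AA20
        if (!any(keep)) return(NA_real_)
        wk <- weights[keep]
        p <- vapply(AA20, function(a) sum(wk[col[keep] == a]), numeric(1))
        p <- p / sum(p)
        p <- p[p > 0]
        log2(20) + sum(p * log2(p))
    }, numeric(1))
}

#' Weighted per-column gap frequency
#'
#' Weighted fraction of gap characters per column; useful for flagging
#' artifactual high-IC terminal columns where most sequences are
#' simply unmatched.
#'
#' @inheritParams columnIC
#' @return numeric vector in `[0, 1]`, one value per column.
#' @export
gapFrequency <- function(msa, weights = NULL, columns = NULL) {
    m <- .msaMatrix(msa)
    if (is.null(weights)) weights <- gscWeights(m)
    if (is.null(columns)) columns <- seq_len(ncol(m))
    if (any(columns < 1 | columns > ncol(m)))
        iemUsageError("column index out of range")
    vapply(columns, function(j)
        sum(weights[m[, j] == "-"]) / sum(weights), numeric(1))
}

#' Map alignment conservation onto a structure chain
#'
#' The query row of the alignment is ungapped and compared with the
#' chain sequence (`X` tolerated as a wildcard on either side); the
#' k-th non-gap query position then carries its column's weighted IC
#' to the k-th chain residue. Chain residues beyond the alignment get
#' NA.
#'
#' @param chainSequence one-letter chain sequence (as from
#'   [chainSequences()]).
#' @param msa an `AAMultipleAlignment` or character vector.
#' @param query row id (name) or 1-based row index of the query
#'   sequence in the alignment.
#' @param weights sequence weights (defaults to [gscWeights()]).
#' @param chainId chain identifier stored in the profile.
#' @return a [ConservationProfile-class].
#' @export
conservationProfile <- function(chainSequence, msa, query = 1,
                                weights = NULL, chainId = "A") {
    m <- .msaMatrix(msa)
    qi <- if (is.character(query)) match(query, rownames(m)) else
        as.integer(query)
    if (is.na(qi) || qi < 1 || qi > nrow(m))
        iemUsageError(paste("query row not found in alignment:", query))
    if (is.null(weights)) weights <- gscWeights(m)
    qrow <- m[qi, ]
    cols <- which(qrow != "-")
    qseq <- qrow[cols]
    chain <- strsplit(toupper(chainSequence), "")[[1]]
    if (length(qseq) > length(chain))
        iemInputError(sprintf(
            "ungapped query (%d residues) longer than chain (%d)",
            length(qseq), length(chain)))
    cmp <- seq_along(qseq)
    mismatch <- cmp[qseq != chain[cmp] & qseq != "X" & chain[cmp] != "X"]
    if (length(mismatch))
        iemInputError(sprintf(
            "query/chain sequence mismatch at chain position %d (%s vs %s)",
            mismatch[1], chain[mismatch[1]], qseq[mismatch[1]]))
    ic <- columnIC(m, weights)
    gf <- gapFrequency(m, weights)
    n <- length(chain)
    icOut <- rep(NA_real_, n); gfOut <- rep(NA_real_, n)
    colOut <- rep(NA_integer_, n)
    icOut[cmp] <- ic[cols]
    gfOut[cmp] <- gf[cols]
    colOut[cmp] <- as.integer(cols)
    new("ConservationProfile", chain = chainId,
        sequence = paste(chain, collapse = ""), ic = icOut,
        gapFraction = gfOut, column = colOut)
}

#' Information content values of a profile
#'
#' @param x a [ConservationProfile-class].
#' @return numeric vector of per-residue IC in bits (NA = undefined).
#' @export
icValues <- function(x) {
    stopifnot(is(x, "ConservationProfile"))
    x@ic
}

setMethod("show", "ConservationProfile", function(object) {
    ok <- !is.na(object@ic)
    cat("ConservationProfile for chain ", object@chain, ": ",
        nchar(object@sequence), " residues, ", sum(ok), " mapped",
        sep = "")
    if (any(ok))
        cat(sprintf("; IC %.2f - %.2f bits", min(object@ic[ok]),
                    max(object@ic[ok])))
    cat("\n")
})

#' Write a per-residue conservation table
#'
#' TSV/CSV with columns `chain resSeq iCode resname IC gap_fraction`,
#' one row per residue of the profile's chain in the structure.
#'
#' @param profile a [ConservationProfile-class].
#' @param structure the [Structure-class] the profile maps onto.
#' @param path output file path.
#' @param format `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
writeConservationTable <- function(profile, structure, path,
                                   format = c("tsv", "csv")) {
    format <- match.arg(format)
    sep <- if (format == "tsv") "\t" else ","
    r <- residues(structure)
    r <- r[r$chain == profile@chain, , drop = FALSE]
    if (nrow(r) != nchar(profile@sequence))
        iemUsageError("profile length does not match the structure chain")
    lines <- c(paste(c("chain", "resSeq", "iCode", "resname", "IC",
                       "gap_fraction"), collapse = sep),
               paste(r$chain, r$resno, r$insert, r$resid,
                     .formatNum(profile@ic), .formatNum(profile@gapFraction),
                     sep = sep))
    writeLines(lines, path)
    invisible(path)
}

#' Build a query-anchored alignment with an external homology search
#'
#' Optional adapter around the `phmmer` search tool: searches
#' `databasePath` (a FASTA protein database such as UniProtKB/
#' Swiss-Prot) with the chain sequence under default parameters and
#' stacks the hit alignment query-anchored, first row the query. The
#' rest of the package works without this adapter; conservation can be
#' computed from any user-supplied alignment.
#'
#' @param chainSequence one-letter query sequence.
#' @param databasePath FASTA database to search.
#' @param phmmer name/path of the phmmer executable.
#' @return character vector of aligned rows, first row the ungapped
#'   query, suitable for [gscWeights()] / [columnIC()].
#' @export
runHomologySearch <- function(chainSequence, databasePath,
                              phmmer = "phmmer") {
    exe <- Sys.which(phmmer)
    if (!nzchar(exe))
        iemEnvError(paste("homology search tool not found on PATH:", phmmer))
    if (!file.exists(databasePath))
        iemEnvError(paste("sequence database not found:", databasePath))
    qf <- tempfile(fileext = ".fasta")
    af <- tempfile(fileext = ".sto")
    on.exit(unlink(c(qf, af)), add = TRUE)
    writeLines(c(">query", chainSequence), qf)
    status <- system2(exe, c("-A", af, "--noali", qf, databasePath),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0)
        iemEnvError(paste("phmmer exited with status", status))
    if (!file.exists(af) || file.size(af) == 0)
        return(stats::setNames(chainSequence, "query"))
    hits <- .msaMatrix(readMSA(af, "stockholm"))
    ## anchor on query coordinates: phmmer match columns are the query
    ## positions; columns that are insertions relative to the query
    ## (all-gap against it in the stacked pairwise alignments) are
    ## lower-case/'.' in Stockholm and were normalized to '-' -> drop
    ## columns where every hit has a gap
    keep <- colSums(hits != "-") > 0
    hits <- hits[, keep, drop = FALSE]
    if (ncol(hits) != nchar(chainSequence))
        return(stats::setNames(chainSequence, "query"))
    rows <- apply(hits, 1, paste, collapse = "")
    c(stats::setNames(chainSequence, "query"), rows)
}
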