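#' @include fixtures.R
NULL

#' Run the full interaction-energy / conservation pipeline
#'
#' Ties the package together the way the command-line front-end does:
#' parse the structure, assign force-field parameters (refusing
#' structures with missing or unparameterizable atoms), build the
#' interaction energy matrix under the chosen solvent model and
#' subgroup, build the residue distance and combined matrices, and —
#' when an alignment is supplied — compute the conservation profile of
#' one chain and a joined per-residue table of total IE and IC.
#'
#' Output files (TSV, 6 significant digits, no timestamps; re-running
#' an identical configuration reproduces them byte for byte):
#' `iem_total.tsv`, `iem_coulomb.tsv`, `iem_lj.tsv`, `total_ie.tsv`,
#' `distances.tsv`, `combined.tsv`, `run.json`, plus
#' `conservation.tsv` and `residue_summary.tsv` when an alignment is
#' given.
#'
#' @param pdb path to the input PDB file (protonated standard
#'   residues).
#' @param params path to the force-field parameter table; `NULL` uses
#'   the built-in minimal set.
#' @param outputDir directory for the output files.
#' @param model solvent model kind (`"gb"`, `"vacuum"`, `"dddc"`).
#' @param epsIn,epsOut,dddcSlope dielectric settings, see
#'   [solventModel()].
#' @param subgroup atom subgroup (`"all"`, `"backbone"`,
#'   `"sidechain"`).
#' @param exclusions peptide-bond exclusion policy (`"none"` or
#'   `"ff"`).
#' @param cutoff atom-pair distance cutoff in Angstrom (default none).
#' @param metric residue distance metric (`"closest"` or `"com"`).
#' @param threshold combined-matrix distance threshold, Angstrom.
#' @param msa optional alignment file for the conservation profile.
#' @param msaFormat `"fasta"` or `"stockholm"`.
#' @param query query row (id or index) in the alignment.
#' @param chain chain id to map conservation onto (default: first
#'   polypeptide chain).
#' @return invisibly, a list with `status` (0) and `files` (paths
#'   written). Failures raise classed conditions (`iemInputError`,
#'   `iemParameterizationError`, `iemEnvironmentError`) which the CLI
#'   front-end maps to exit codes 1, 2 and 3.
#' @export
runPipeline <- function(pdb, params = NULL, outputDir = ".",
                        model = c("gb", "vacuum", "dddc"), epsIn = 1.0,
                        epsOut = 78.5, dddcSlope = 1.0,
                        subgroup = "all",
                        exclusions = c("none", "ff"), cutoff = Inf,
                        metric = c("closest", "com"), threshold = 5.0,
                        msa = NULL, msaFormat = c("fasta", "stockholm"),
                        query = 1, chain = NULL) {
    model <- match.arg(model)
    exclusions <- match.arg(exclusions)
    metric <- match.arg(metric)
    msaFormat <- match.arg(msaFormat)
    if (!dir.exists(outputDir))
        dir.create(outputDir, recursive = TRUE)

    s <- readPDB(pdb)
    pset <- if (is.null(params)) defaultParameterSet() else
        loadParameterSet(params)
    ps <- assignParameters(s, pset)
    if (nrow(ps@missing) > 0) {
        m <- ps@missing
        iemParamError(paste0(
            "structure is missing template atoms (add hydrogens or fix ",
            "the model): ",
            paste(utils::head(paste0(m$resid, m$resno, "/", m$elety), 8),
                  collapse = ", ")))
    }
    mask <- subgroupMask(ps, subgroup)
    bad <- which(is.na(ps@parameters$charge) & mask)
    if (length(bad)) {
        a <- atoms(ps)[bad, ]
        iemParamError(paste0("unparameterizable atom(s) in scope: ",
                             paste(utils::head(paste0(a$resid, a$resno,
                                                      "/", a$elety), 8),
                                   collapse = ", ")))
    }
    sm <- solventModel(model, epsIn = epsIn, epsOut = epsOut,
                       dddcSlope = dddcSlope)
    if (model == "gb" && anyNA(ps@parameters$gb_rho[mask]))
        iemInputError(paste("parameter table lacks GB columns",
                            "(gb_rho/gb_scale) required by the GB model"))

    iem <- buildIEM(ps, sm, subgroup = subgroup, exclusions = exclusions,
                    cutoff = cutoff)
    dm <- buildDistanceMatrix(ps, metric = metric, subgroup = subgroup)
    cm <- combineMatrices(iem, dm, threshold = threshold)

    files <- character(0)
    out <- function(name) file.path(outputDir, name)
    for (comp in c("total", "coulomb", "lj"))
        files <- c(files, writeMatrixTable(iem, out(paste0("iem_", comp,
                                                           ".tsv")),
                                           component = comp))
    tot <- totalEnergies(iem)
    totPath <- out("total_ie.tsv")
    writeLines(c(paste(c("chain", "resSeq", "iCode", "resname", "coulomb",
                         "lj", "total"), collapse = "\t"),
                 paste(tot$chain, tot$resno, tot$insert, tot$resid,
                       .formatNum(tot$coulomb), .formatNum(tot$lj),
                       .formatNum(tot$total), sep = "\t")), totPath)
    files <- c(files, totPath)
    files <- c(files, writeMatrixTable(dm, out("distances.tsv")))
    files <- c(files, writeMatrixTable(cm, out("combined.tsv")))

    profile <- NULL
    if (!is.null(msa)) {
        aln <- readMSA(msa, msaFormat)
        seqs <- chainSequences(s)
        if (length(seqs) == 0)
            iemInputError("no polypeptide chain for the conservation profile")
        if (is.null(chain)) chain <- names(seqs)[1]
        if (!chain %in% names(seqs))
            iemInputError(paste("no polypeptide chain with id:", chain))
        w <- gscWeights(aln)
        profile <- conservationProfile(seqs[[chain]], aln, query = query,
                                       weights = w, chainId = chain)
        files <- c(files,
                   writeConservationTable(profile, s, out("conservation.tsv")))
        ## joined per-residue view (total IE + IC) of the profiled chain
        rch <- tot[tot$chain == chain, , drop = FALSE]
        sumPath <- out("residue_summary.tsv")
        writeLines(c(paste(c("chain", "resSeq", "iCode", "resname",
                             "total_ie", "IC"), collapse = "\t"),
                     paste(rch$chain, rch$resno, rch$insert, rch$resid,
                           .formatNum(rch$total),
                           .formatNum(profile@ic), sep = "\t")), sumPath)
        files <- c(files, sumPath)
    }

    meta <- list(model = list(kind = model, eps_in = epsIn,
                              eps_out = epsOut, dddc_slope = dddcSlope),
                 subgroup = subgroup, exclusions = exclusions,
                 cutoff = if (is.finite(cutoff)) cutoff else "none",
                 metric = metric, threshold = threshold,
                 n_residues = nrow(residueKeys(iem)),
                 n_atoms = nrow(atoms(s)),
                 conservation = !is.null(msa))
    metaPath <- out("run.json")
    jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, digits = NA)
    files <- c(files, metaPath)

    invisible(list(status = 0L, files = files, iem = iem, distances = dm,
                   combined = cm, conservation = profile))
}
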