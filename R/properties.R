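# Drug-likeness descriptors and the reference-blocker comparison filter.
#
# Descriptors are computed with RDKit (Crippen atom-contribution logP, the
# Ertl-Schuffenhauer synthetic accessibility score, Bickerton's QED
# desirability product) through the bundled helper script; descriptor values
# depend on the RDKit version, which is recorded on the result. Structures
# are used as given (neutral form): no pH-dependent protonation step is
# applied, a documented deviation from protonating at pH 7.35.

.pythonBinary <- function() {
    p <- getOption("tccselect.python", Sys.which("python"))
    if (!nzchar(p)) p <- Sys.which("python3")
    if (!nzchar(p))
        stop("no 'python' interpreter with RDKit found on the PATH; ",
             "set options(tccselect.python = ...)")
    p
}

#' Is the RDKit descriptor backend available?
#'
#' @return TRUE if a Python interpreter with RDKit (including the SA-score
#'   contribution) can be invoked.
#' @export
rdkitAvailable <- function() {
    p <- tryCatch(.pythonBinary(), error = function(e) NULL)
    if (is.null(p)) return(FALSE)
    code <- paste0("import os,sys;from rdkit.Chem import RDConfig;",
                   "sys.path.append(os.path.join(RDConfig.RDContribDir,'SA_Score'));",
                   "import sascorer")
    identical(suppressWarnings(system2(p, c("-c", shQuote(code)),
                                       stdout = FALSE, stderr = FALSE)), 0L)
}

#' Compute drug-likeness descriptors from structures
#'
#' Computes the octanol-water partition estimate (Crippen logP), the
#' synthetic accessibility score (Ertl-Schuffenhauer, 1 = easy to 10 =
#' hard) and the quantitative estimate of drug-likeness (QED, 0-1) for each
#' input SMILES.
#'
#' @param smiles character vector of SMILES strings.
#' @param id compound identifiers; defaults to the SMILES themselves.
#' @return data.frame with columns id, smiles, logp, sas, qed, carrying the
#'   RDKit version as attribute `"rdkit_version"`. An unparseable SMILES
#'   raises an error naming the offending input.
#' @examples
#' \dontrun{computeProperties("CC(=O)Oc1ccccc1C(=O)O", id = "aspirin")}
#' @export
computeProperties <- function(smiles, id = smiles) {
    stopifnot(length(smiles) == length(id))
    if (!length(smiles))
        return(data.frame(id = character(), smiles = character(),
                          logp = numeric(), sas = numeric(), qed = numeric(),
                          stringsAsFactors = FALSE))
    script <- system.file("python", "descriptors.py", package = "tccselect",
                          mustWork = TRUE)
    infile <- tempfile(fileext = ".smi")
    on.exit(unlink(infile))
    writeLines(paste(smiles, id, sep = "\t"), infile)
    out <- suppressWarnings(system2(.pythonBinary(), c(script, infile),
                                    stdout = TRUE, stderr = FALSE))
    status <- attr(out, "status")
    payload <- tryCatch(jsonlite::fromJSON(paste(out, collapse = "\n")),
                        error = function(e)
                            stop("descriptor backend failed: ",
                                 paste(out, collapse = " ")))
    if (!is.null(status) && status != 0L) {
        if (identical(payload$error, "unparseable SMILES"))
            stop("unparseable SMILES: ", payload$input)
        stop("descriptor backend failed (exit status ", status, ")")
    }
    rec <- as.data.frame(payload$records, stringsAsFactors = FALSE)
    structure(rec[, c("id", "smiles", "logp", "sas", "qed")],
              rdkit_version = payload$rdkit_version)
}

#' Load a compound property table
#'
#' Reads a CSV with columns id, logp, sas, qed and role (either "reference"
#' for known blockers or "candidate" for screened compounds). Values
#' outside the descriptor ranges (QED in (0, 1], SAS in [1, 10]) raise a
#' validation error.
#'
#' @param file path to the CSV. See [table3Fixture()] for the bundled
#'   blocker/candidate table.
#' @return data.frame of compound records (possibly empty).
#' @export
loadPropertyTable <- function(file) {
    tab <- utils::read.csv(file, stringsAsFactors = FALSE)
    need <- c("id", "logp", "sas", "qed")
    if (!all(need %in% names(tab)))
        stop("property table must have columns: ", paste(need, collapse = ", "))
    if (!"role" %in% names(tab)) tab$role <- "candidate"
    if (nrow(tab) == 0L) return(tab)
    for (col in c("logp", "sas", "qed")) tab[[col]] <- as.numeric(tab[[col]])
    if (any(!is.finite(tab$logp)))
        stop("non-finite logp in row(s): ", paste(which(!is.finite(tab$logp)), collapse = ", "))
    badQed <- tab$qed <= 0 | tab$qed > 1
    if (any(badQed))
        stop("qed outside (0, 1] in row(s): ", paste(which(badQed), collapse = ", "))
    badSas <- tab$sas < 1 | tab$sas > 10
    if (any(badSas))
        stop("sas outside [1, 10] in row(s): ", paste(which(badSas), collapse = ", "))
    if (!all(tab$role %in% c("reference", "candidate")))
        stop("role must be 'reference' or 'candidate'")
    tab
}

#' Compare candidates against reference blockers on drug-likeness
#'
#' A candidate passes when it is strictly better than every reference
#' blocker on the enforced criteria: lower logP and higher QED by default.
#' The synthetic accessibility comparison (lower SAS than every reference)
#' is always reported but only enforced in the strict three-criterion mode,
#' because computer-designed candidates are routinely harder to synthesize
#' than marketed blockers and a hard SAS cut would discard the entire
#' candidate class. Ties fail (comparisons are strict).
#'
#' @param candidates data.frame of candidate records (columns id, logp,
#'   sas, qed).
#' @param references non-empty data.frame of reference records (same
#'   columns).
#' @param enforceSas also require SAS lower than every reference.
#' @return data.frame with one row per candidate: per-criterion booleans
#'   logp_pass, qed_pass, sas_pass and the overall `pass`.
#' @examples
#' tab <- table3Fixture()
#' flt <- referenceFilter(tab[tab$role == "candidate", ],
#'                        tab[tab$role == "reference", ])
#' flt[flt$id == "TC 7", ]
#' @export
referenceFilter <- function(candidates, references, enforceSas = FALSE) {
    stopifnot(is.data.frame(references), nrow(references) > 0L)
    need <- c("id", "logp", "sas", "qed")
    stopifnot(all(need %in% names(candidates)), all(need %in% names(references)))
    out <- data.frame(id = candidates$id,
                      logp = candidates$logp, sas = candidates$sas,
                      qed = candidates$qed, stringsAsFactors = FALSE)
    out$logp_pass <- candidates$logp < min(references$logp)
    out$qed_pass <- candidates$qed > max(references$qed)
    out$sas_pass <- candidates$sas < min(references$sas)
    out$pass <- out$logp_pass & out$qed_pass & (!enforceSas | out$sas_pass)
    out
}
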