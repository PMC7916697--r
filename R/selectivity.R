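# Docking-table triage: free-energy to dissociation-constant conversion and
# the domain-based T-type vs L-type selectivity rule.

.RECEPTORS <- c("a1C", "a1G", "a1H", "a1I")
.TCC_RECEPTORS <- c("a1G", "a1H", "a1I")
.LCC_RECEPTOR <- "a1C"
.CATEGORIES <- c("TCC_selective", "dual_blocker", "LCC_selective", "non_binder")

.ROMAN <- c(I = 1L, II = 2L, III = 3L, IV = 4L)

.parseDomain <- function(x) {
    x <- toupper(trimws(as.character(x)))
    out <- rep(NA_integer_, length(x))
    miss <- is.na(x) | x %in% c("", "N/A", "NA")
    roman <- !miss & x %in% names(.ROMAN)
    out[roman] <- .ROMAN[x[roman]]
    numeric_ <- !miss & !roman & grepl("^[1-4]$", x)
    out[numeric_] <- as.integer(x[numeric_])
    bad <- !miss & !roman & !numeric_
    if (any(bad))
        stop("unparseable binding domain: ", paste(unique(x[bad]), collapse = ", "))
    out
}

#' Convert docking free energies to dissociation constants
#'
#' Kd is obtained from the binding free energy at body temperature,
#' Kd = exp(dG / (R T)) with R = 0.001986 kcal mol^-1 K^-1 and T = 310 K by
#' default, so that a more negative dG gives a smaller (tighter) Kd and
#' dG = 0 gives Kd = 1. This is the `"thermodynamic"` convention. The
#' `"printed"` convention evaluates exp(-dG / (R T)) instead — the
#' literal sign sometimes seen in screening write-ups, whose output is the
#' reciprocal (association-like) quantity; it is exposed so either reading
#' can be reproduced, and the output records which one was used.
#'
#' @param deltaG numeric vector of binding free energies, kcal/mol; NA
#'   propagates.
#' @param temperature absolute temperature, K.
#' @param gasConstant gas constant, kcal mol^-1 K^-1.
#' @param convention "thermodynamic" (default) or "printed".
#' @return data.frame with columns delta_g_kcal_mol, kd_molar,
#'   temperature_K, gas_constant and convention.
#' @examples
#' deltaGToKd(-6.8)$kd_molar  # ~1.6e-5 M
#' @export
deltaGToKd <- function(deltaG, temperature = 310, gasConstant = 0.001986,
                       convention = c("thermodynamic", "printed")) {
    convention <- match.arg(convention)
    stopifnot(temperature > 0, gasConstant > 0)
    sign_ <- if (convention == "thermodynamic") 1 else -1
    kd <- exp(sign_ * deltaG / (gasConstant * temperature))
    data.frame(delta_g_kcal_mol = deltaG, kd_molar = kd,
               temperature_K = temperature, gas_constant = gasConstant,
               convention = convention, stringsAsFactors = FALSE)
}

#' Load a docking results table
#'
#' Reads a comma-separated docking table with columns compound, receptor,
#' delta_g_kcal_mol, binding_domain, binding_residue and bond_type, using
#' "N/A" as the missing-value token. Receptor names are normalized; binding
#' domains may be Roman or Arabic numerals. A missing free energy means "no
#' predicted binding" (never zero), and dominates any domain annotation
#' printed alongside it. Unknown receptors and unexpectedly positive free
#' energies produce warnings; structurally malformed rows raise.
#'
#' @param file path to the CSV. See [table2Fixture()] for the bundled
#'   phenylalkylamine table.
#' @return data.frame of docking records (possibly empty).
#' @export
loadDockingTable <- function(file) {
    tab <- utils::read.csv(file, stringsAsFactors = FALSE,
                           na.strings = c("N/A", "NA", ""),
                           colClasses = "character")
    need <- c("compound", "receptor", "delta_g_kcal_mol", "binding_domain")
    if (!all(need %in% names(tab)))
        stop("docking table must have columns: ", paste(need, collapse = ", "))
    if (!"binding_residue" %in% names(tab)) tab$binding_residue <- NA_character_
    if (!"bond_type" %in% names(tab)) tab$bond_type <- NA_character_
    if (nrow(tab) == 0L)
        return(data.frame(compound = character(), receptor = character(),
                          delta_g_kcal_mol = numeric(),
                          binding_domain = integer(),
                          binding_residue = character(),
                          bond_type = character(), stringsAsFactors = FALSE))
    receptor <- vapply(tab$receptor, function(r)
        tryCatch(normalizeChannel(r), error = function(e) NA_character_), "")
    if (anyNA(receptor)) {
        warning("unknown receptor name(s) kept unnormalized: ",
                paste(unique(tab$receptor[is.na(receptor)]), collapse = ", "))
        receptor[is.na(receptor)] <- tab$receptor[is.na(receptor)]
    }
    dg <- suppressWarnings(as.numeric(tab$delta_g_kcal_mol))
    malformed <- !is.na(tab$delta_g_kcal_mol) & is.na(dg)
    if (any(malformed))
        stop("unparseable free energy in row(s): ",
             paste(which(malformed), collapse = ", "))
    if (any(dg > 0, na.rm = TRUE))
        warning("positive binding free energies in row(s): ",
                paste(which(!is.na(dg) & dg > 0), collapse = ", "))
    data.frame(compound = tab$compound, receptor = unname(receptor),
               delta_g_kcal_mol = dg,
               binding_domain = .parseDomain(tab$binding_domain),
               binding_residue = tab$binding_residue,
               bond_type = tab$bond_type, stringsAsFactors = FALSE)
}

.classifyOne <- function(rec, tccDomains, lccDomains, bindingThreshold) {
    present <- !is.na(rec$delta_g_kcal_mol)
    if (!is.null(bindingThreshold))
        present <- present & rec$delta_g_kcal_mol <= bindingThreshold
    tccHit <- present & rec$receptor %in% .TCC_RECEPTORS &
        !is.na(rec$binding_domain) & rec$binding_domain %in% tccDomains
    lccHit <- present & rec$receptor == .LCC_RECEPTOR &
        !is.na(rec$binding_domain) & rec$binding_domain %in% lccDomains
    bindsTcc <- any(tccHit); bindsLcc <- any(lccHit)
    category <- if (bindsTcc && bindsLcc) "dual_blocker"
                else if (bindsTcc) "TCC_selective"
                else if (bindsLcc) "LCC_selective"
                else "non_binder"
    bestTcc <- NA_real_; bestTccReceptor <- NA_character_
    if (any(tccHit)) {
        # ties on dG break on receptor name so row order never matters
        i <- which(tccHit)[order(rec$delta_g_kcal_mol[tccHit],
                                 rec$receptor[tccHit])[1L]]
        bestTcc <- rec$delta_g_kcal_mol[i]
        bestTccReceptor <- rec$receptor[i]
    }
    a1c <- rec$delta_g_kcal_mol[rec$receptor == .LCC_RECEPTOR]
    a1c <- a1c[!is.na(a1c)]
    domStr <- function(recs) {
        d <- sort(unique(recs$binding_domain[!is.na(recs$delta_g_kcal_mol) &
                                             !is.na(recs$binding_domain)]))
        if (length(d)) paste(names(.ROMAN)[d], collapse = "+") else NA_character_
    }
    doms <- vapply(.RECEPTORS, function(rc)
        domStr(rec[rec$receptor == rc, , drop = FALSE]), "")
    data.frame(category = category, binds_tcc = bindsTcc, binds_lcc = bindsLcc,
               best_tcc_dg = bestTcc, best_tcc_receptor = bestTccReceptor,
               a1c_dg = if (length(a1c)) min(a1c) else NA_real_,
               domains_a1C = doms[["a1C"]], domains_a1G = doms[["a1G"]],
               domains_a1H = doms[["a1H"]], domains_a1I = doms[["a1I"]],
               stringsAsFactors = FALSE)
}

#' Classify compounds as T-type-selective, L-type-selective, dual or inert
#'
#' Applies the domain-based selectivity rule to a docking table: a compound
#' "binds TCC" when any T-type receptor (a1G/a1H/a1I) records a present
#' free energy with binding domain among `tccDomains` (I and IV by default,
#' the preferred Ca2+/phenylalkylamine region of T-type channels), and
#' "binds LCC" when the L-type receptor a1C records a present free energy
#' with binding domain among `lccDomains` (III and IV by default). The four
#' categories partition every input: compounds binding only T-type are the
#' selective candidates, those binding both are dual blockers.
#'
#' @param records docking data.frame as returned by [loadDockingTable()]
#'   (one or many compounds).
#' @param tccDomains integer domains counted as T-type binding.
#' @param lccDomains integer domains counted as L-type binding.
#' @param bindingThreshold optional free-energy cutoff (kcal/mol); when set,
#'   only dG <= threshold counts as binding. Default NULL: any reported dG
#'   counts.
#' @return data.frame with one row per compound (sorted by compound id):
#'   category, binds_tcc, binds_lcc, best_tcc_dg, best_tcc_receptor,
#'   a1c_dg and per-receptor bound domains.
#' @examples
#' rep <- classifySelectivity(table2Fixture())
#' rep[rep$compound == "NNC 55-0396", "category"]  # TCC_selective
#' @export
classifySelectivity <- function(records, tccDomains = c(1L, 4L),
                                lccDomains = c(3L, 4L),
                                bindingThreshold = NULL) {
    if (nrow(records) == 0L)
        return(data.frame(compound = character(), category = character(),
                          stringsAsFactors = FALSE))
    ids <- sort(unique(records$compound))
    rows <- lapply(ids, function(id)
        cbind(data.frame(compound = id, stringsAsFactors = FALSE),
              .classifyOne(records[records$compound == id, , drop = FALSE],
                           tccDomains, lccDomains, bindingThreshold)))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Rank selective-blocker candidates
#'
#' Orders a selectivity report for triage: TCC-selective compounds first,
#' sorted by best T-type free energy ascending (more negative = stronger),
#' with ties broken by higher QED then lower logP; the remaining categories
#' follow in the order dual blocker, LCC-selective, non-binder under the
#' same sort keys. Each compound is additionally compared against a set of
#' reference blockers: the `beats_ref_*` flags state whether it is strictly
#' better than every reference on affinity (more negative best T-type dG),
#' logP (lower) and QED (higher); with no references the flags are
#' vacuously TRUE. Compounds without a property row are ranked but flagged
#' `unfiltered`.
#'
#' @param report selectivity report from [classifySelectivity()].
#' @param properties data.frame with columns id, logp, sas, qed (see
#'   [loadPropertyTable()]).
#' @param referenceCompounds character vector of compound ids to use as
#'   references; their affinities are taken from `report` and their
#'   properties from `properties`.
#' @return The report with property columns, reference-comparison flags and
#'   a `rank` column, ordered by rank.
#' @export
rankCandidates <- function(report, properties = NULL,
                           referenceCompounds = character()) {
    stopifnot(is.data.frame(report), "compound" %in% names(report))
    if (!is.null(properties)) {
        stopifnot(all(c("id", "logp", "sas", "qed") %in% names(properties)))
        m <- match(report$compound, properties$id)
        report$logp <- properties$logp[m]
        report$sas <- properties$sas[m]
        report$qed <- properties$qed[m]
    } else {
        report$logp <- report$sas <- report$qed <- NA_real_
    }
    report$unfiltered <- is.na(report$logp) & is.na(report$qed)
    refs <- report[report$compound %in% referenceCompounds, , drop = FALSE]
    refDg <- refs$best_tcc_dg[!is.na(refs$best_tcc_dg)]
    refLogp <- refs$logp[!is.na(refs$logp)]
    refQed <- refs$qed[!is.na(refs$qed)]
    cmpAll <- function(x, ref, better) {
        if (!length(ref)) return(rep(TRUE, length(x)))
        vapply(x, function(v) !is.na(v) && all(better(v, ref)), logical(1))
    }
    report$beats_ref_affinity <- cmpAll(report$best_tcc_dg, refDg, `<`)
    report$beats_ref_logp <- cmpAll(report$logp, refLogp, `<`)
    report$beats_ref_qed <- cmpAll(report$qed, refQed, `>`)
    catOrder <- match(report$category, .CATEGORIES)
    ord <- order(catOrder, report$best_tcc_dg, -xtfrm(report$qed),
                 report$logp, report$compound, na.last = TRUE)
    out <- report[ord, , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
}
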