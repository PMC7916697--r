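# Synthetic screening cohorts with known ground truth.
#
# The generator emulates the shape of a real screening campaign's outputs:
# a docking table (one row per compound x receptor, with the missing-value
# pattern of genuinely unbound compounds) and a property table, together
# with the true class of every compound. Free energies are draws, not
# physics: no docking scoring function is emulated.

#' Create a cohort specification
#'
#' Defaults describe a plausible screening cohort: TCC-selective compounds
#' bind the three T-type receptors at -7.5 +/- 0.5 kcal/mol in domains I or
#' IV with no L-type binding; dual blockers additionally bind the L-type
#' receptor in domains III or IV near -6.1 +/- 0.4 kcal/mol (the range
#' reported for dual-acting phenylalkylamines); non-binders report nothing.
#' Properties are uniform over the envelope of observed blocker/candidate
#' values. All draws derive from the single `seed`.
#'
#' @param nCompounds number of compounds.
#' @param fractionTcc fraction of truly TCC-selective compounds.
#' @param fractionNonBinder fraction of non-binders (remainder: dual).
#' @param dgTccMean,dgTccSd T-type free-energy distribution of selective
#'   compounds, kcal/mol.
#' @param dgDualTccMean,dgDualTccSd,dgDualLccMean,dgDualLccSd free-energy
#'   distributions of dual blockers on T-type / L-type receptors.
#' @param missingness probability that each present free energy is dropped.
#' @param logpRange,sasRange,qedRange uniform property ranges.
#' @param plantDominant force compound 1 to be TCC-selective and strictly
#'   dominant on affinity, logP and QED (requires fractionTcc > 0).
#' @param seed integer seed.
#' @return A [CohortSpec-class] object.
#' @examples
#' cohortSpec(nCompounds = 50, seed = 7)
#' @export
cohortSpec <- function(nCompounds = 200, fractionTcc = 0.3,
                       fractionNonBinder = 0.1,
                       dgTccMean = -7.5, dgTccSd = 0.5,
                       dgDualTccMean = -7.0, dgDualTccSd = 0.5,
                       dgDualLccMean = -6.1, dgDualLccSd = 0.4,
                       missingness = 0,
                       logpRange = c(3.5, 7.0), sasRange = c(3.0, 5.3),
                       qedRange = c(0.24, 0.64),
                       plantDominant = FALSE, seed = 1L) {
    spec <- new("CohortSpec", nCompounds = as.integer(nCompounds),
                fractionTcc = fractionTcc,
                fractionNonBinder = fractionNonBinder,
                dgTccMean = dgTccMean, dgTccSd = dgTccSd,
                dgDualTccMean = dgDualTccMean, dgDualTccSd = dgDualTccSd,
                dgDualLccMean = dgDualLccMean, dgDualLccSd = dgDualLccSd,
                missingness = missingness, logpRange = as.numeric(logpRange),
                sasRange = as.numeric(sasRange), qedRange = as.numeric(qedRange),
                plantDominant = plantDominant, seed = as.integer(seed))
    if (spec@plantDominant && (spec@nCompounds < 1L || spec@fractionTcc <= 0))
        stop("plantDominant requires at least one TCC-selective compound")
    spec
}

# negative-truncated Gaussian draw (no positive binding energies emitted)
.rnormNeg <- function(n, mean, sd) {
    x <- stats::rnorm(n, mean, sd)
    while (any(x >= 0)) {
        i <- x >= 0
        x[i] <- stats::rnorm(sum(i), mean, sd)
    }
    x
}

#' Generate a synthetic screening cohort
#'
#' Draws a docking table (one row per compound x receptor over
#' a1C/a1G/a1H/a1I), a property table and the ground-truth class labels
#' from a [CohortSpec-class]. The same spec always yields identical output;
#' the caller's RNG state is left untouched.
#'
#' @param spec a [CohortSpec-class] object.
#' @return List with elements `docking` (data.frame in the
#'   [loadDockingTable()] layout), `properties` (id, logp, sas, qed, role)
#'   and `truth` (id, class in TCC_selective / dual_blocker / non_binder).
#' @examples
#' cohort <- generateCohort(cohortSpec(nCompounds = 10, seed = 7))
#' table(cohort$truth$class)
#' @export
generateCohort <- function(spec) {
    stopifnot(is(spec, "CohortSpec"))
    validObject(spec)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec@seed)
    n <- spec@nCompounds
    emptyDock <- data.frame(compound = character(), receptor = character(),
                            delta_g_kcal_mol = numeric(),
                            binding_domain = integer(),
                            binding_residue = character(),
                            bond_type = character(), stringsAsFactors = FALSE)
    if (n == 0L)
        return(list(docking = emptyDock,
                    properties = data.frame(id = character(), logp = numeric(),
                                            sas = numeric(), qed = numeric(),
                                            role = character(),
                                            stringsAsFactors = FALSE),
                    truth = data.frame(id = character(), class = character(),
                                       stringsAsFactors = FALSE)))
    nTcc <- round(n * spec@fractionTcc)
    nNon <- round(n * spec@fractionNonBinder)
    nDual <- n - nTcc - nNon
    ids <- sprintf("SC-%04d", seq_len(n))
    class <- rep(c("TCC_selective", "dual_blocker", "non_binder"),
                 c(nTcc, nDual, nNon))
    rows <- vector("list", n)
    for (i in seq_len(n)) {
        dg <- rep(NA_real_, 4L)  # a1C, a1G, a1H, a1I
        dom <- rep(NA_integer_, 4L)
        if (class[i] == "TCC_selective") {
            dg[2:4] <- .rnormNeg(3L, spec@dgTccMean, spec@dgTccSd)
            dom[2:4] <- sample(c(1L, 4L), 3L, replace = TRUE)
        } else if (class[i] == "dual_blocker") {
            dg[1L] <- .rnormNeg(1L, spec@dgDualLccMean, spec@dgDualLccSd)
            dom[1L] <- sample(c(3L, 4L), 1L)
            dg[2:4] <- .rnormNeg(3L, spec@dgDualTccMean, spec@dgDualTccSd)
            dom[2:4] <- sample(c(1L, 4L), 3L, replace = TRUE)
        }
        if (spec@missingness > 0) {
            drop <- !is.na(dg) & stats::runif(4L) < spec@missingness
            dg[drop] <- NA_real_
        }
        rows[[i]] <- data.frame(compound = ids[i], receptor = .RECEPTORS,
                                delta_g_kcal_mol = dg, binding_domain = dom,
                                binding_residue = NA_character_,
                                bond_type = NA_character_,
                                stringsAsFactors = FALSE)
    }
    docking <- do.call(rbind, rows)
    rownames(docking) <- NULL
    properties <- data.frame(
        id = ids,
        logp = stats::runif(n, spec@logpRange[1L], spec@logpRange[2L]),
        sas = stats::runif(n, spec@sasRange[1L], spec@sasRange[2L]),
        qed = stats::runif(n, spec@qedRange[1L], spec@qedRange[2L]),
        role = "candidate", stringsAsFactors = FALSE)
    if (spec@plantDominant) {
        tccRows <- docking$compound == ids[1L] & docking$receptor == "a1G"
        docking$delta_g_kcal_mol[tccRows] <-
            min(docking$delta_g_kcal_mol, na.rm = TRUE) - 0.5
        docking$binding_domain[tccRows] <- 1L
        properties$logp[1L] <- min(properties$logp[-1L]) - 0.1
        properties$qed[1L] <- min(0.99, max(properties$qed[-1L]) + 0.01)
    }
    list(docking = docking, properties = properties,
         truth = data.frame(id = ids, class = class, stringsAsFactors = FALSE))
}
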