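#' @import methods
NULL

#' Point charge in elementary-charge units
#'
#' A labelled formal point charge. The interference model uses formal charges
#' only: Ca2+ carries +2, the filter aspartate side chain -1, the adjacent
#' lysine +1 at physiological pH.
#'
#' @slot label single non-empty character string naming the charge carrier.
#' @slot charge signed charge in units of the elementary charge e.
#' @export
setClass("PointCharge", representation(label = "character", charge = "numeric"))

setValidity("PointCharge", function(object) {
    msg <- character()
    if (length(object@label) != 1L || is.na(object@label) || !nzchar(object@label))
        msg <- c(msg, "'label' must be a single non-empty string")
    if (length(object@charge) != 1L || !is.finite(object@charge))
        msg <- c(msg, "'charge' must be a single finite number")
    if (length(msg)) msg else TRUE
})

#' Create a point charge
#'
#' @param label name of the charge carrier (e.g. "Ca2+").
#' @param charge signed charge in elementary-charge units.
#' @return A [PointCharge-class] object.
#' @examples
#' pointCharge("Ca2+", +2)
#' @export
pointCharge <- function(label, charge) {
    new("PointCharge", label = as.character(label), charge = as.numeric(charge))
}

#' Physical constants for the Coulomb model
#'
#' Coulomb's constant and the elementary charge used to convert formal
#' charges and Angstrom distances into SI forces. The default elementary
#' charge is the two-significant-figure 1.60e-19 C, which reproduces the
#' model's reference forces exactly; the CODATA value can be supplied
#' instead (it shifts the forces by about 0.3 percent).
#'
#' @slot ke Coulomb constant, N m^2 C^-2.
#' @slot e elementary charge, C.
#' @export
setClass("CoulombConstants", representation(ke = "numeric", e = "numeric"))

setValidity("CoulombConstants", function(object) {
    msg <- character()
    if (length(object@ke) != 1L || !is.finite(object@ke) || object@ke <= 0)
        msg <- c(msg, "'ke' must be a single positive number")
    if (length(object@e) != 1L || !is.finite(object@e) || object@e <= 0)
        msg <- c(msg, "'e' must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' Create the constants object
#'
#' @param ke Coulomb constant in N m^2 C^-2.
#' @param e elementary charge in C.
#' @return A [CoulombConstants-class] object.
#' @examples
#' coulombConstants()
#' coulombConstants(e = 1.602176634e-19)  # CODATA
#' @export
coulombConstants <- function(ke = 8.99e9, e = 1.60e-19) {
    new("CoulombConstants", ke = as.numeric(ke), e = as.numeric(e))
}

#' Geometry of the Ca2+ / aspartate / lysine interference triangle
#'
#' Describes the relative placement of the permeating calcium ion, the
#' domain-III selectivity-filter aspartate (D3p50) and the adjacent lysine
#' (K3p49).
#'
#' @slot a Ca2+--aspartate distance, Angstrom.
#' @slot b aspartate--lysine distance, Angstrom.
#' @slot theta angle at the Ca2+ vertex between the Ca->Asp and Ca->Lys
#'   directions, degrees; restricted to [0, 90) so the axial projection
#'   cos(theta) stays positive.
#' @slot phi angle at the lysine vertex between the Lys->Ca and Lys->Asp
#'   directions, degrees, in [0, 180]. It selects between the two lysine
#'   placements compatible with (a, b, theta): phi < 90 gives the far
#'   intersection, phi > 90 the near one, and phi = 90 is the tangent case
#'   where both coincide. See [lysineDistance()].
#' @export
setClass("InterferenceGeometry",
         representation(a = "numeric", b = "numeric",
                        theta = "numeric", phi = "numeric"))

setValidity("InterferenceGeometry", function(object) {
    msg <- character()
    num1 <- function(x) length(x) == 1L && is.finite(x)
    if (!num1(object@a) || object@a <= 0) msg <- c(msg, "'a' must be a single positive distance")
    if (!num1(object@b) || object@b <= 0) msg <- c(msg, "'b' must be a single positive distance")
    if (!num1(object@theta) || object@theta < 0 || object@theta >= 90)
        msg <- c(msg, "'theta' must lie in [0, 90) degrees")
    if (!num1(object@phi) || object@phi < 0 || object@phi > 180)
        msg <- c(msg, "'phi' must lie in [0, 180] degrees")
    if (!length(msg)) {
        asin_ <- object@a * sin(object@theta * pi / 180)
        if (object@b < asin_ - 1e-12)
            msg <- c(msg, sprintf(
                "infeasible geometry: b (%.4g) < a*sin(theta) (%.4g); no such triangle exists",
                object@b, asin_))
    }
    if (length(msg)) msg else TRUE
})

#' Create an interference geometry
#'
#' @param a Ca2+--aspartate distance, Angstrom.
#' @param b aspartate--lysine distance, Angstrom.
#' @param theta angle at Ca2+ between the Ca->Asp and Ca->Lys rays, degrees.
#' @param phi angle at the lysine between the Lys->Ca and Lys->Asp rays,
#'   degrees; branch selector for [lysineDistance()]. Default 0 (lysine on
#'   the far side of the aspartate, the minimal-interference placement).
#' @return An [InterferenceGeometry-class] object.
#' @examples
#' interferenceGeometry(a = 4.3, b = 3.8)
#' @export
interferenceGeometry <- function(a, b, theta = 0, phi = 0) {
    new("InterferenceGeometry", a = as.numeric(a), b = as.numeric(b),
        theta = as.numeric(theta), phi = as.numeric(phi))
}

setMethod("show", "InterferenceGeometry", function(object) {
    cat(sprintf(
        "InterferenceGeometry: a = %.3g A (Ca-Asp), b = %.3g A (Asp-Lys), theta = %.3g deg, phi = %.3g deg\n",
        object@a, object@b, object@theta, object@phi))
})

#' Pore-domain segment alignment of calcium channel alpha1 subunits
#'
#' Stores one row per (channel, domain, segment) of an S5/P-loop/S6
#' alignment, with each segment's numbering origin. Residues are held as a
#' Biostrings [Biostrings::AAStringSet] restricted to the 20 standard
#' one-letter codes.
#'
#' @slot table data.frame with columns channel, domain (1-4), segment
#'   ("o" = S5 outer helix, "p" = P-loop, "i" = S6 inner helix) and start
#'   (alignment position of the first residue: 1 for helices, 33 for
#'   P-loops).
#' @slot residues AAStringSet, one entry per table row.
#' @slot uncertain data.frame of residue positions flagged uncertain when a
#'   channel was derived by patching (may have zero rows).
#' @export
setClass("ChannelAlignment",
         representation(table = "data.frame", residues = "ANY",
                        uncertain = "data.frame"))

setValidity("ChannelAlignment", function(object) {
    msg <- character()
    tab <- object@table
    need <- c("channel", "domain", "segment", "start")
    if (!all(need %in% names(tab)))
        msg <- c(msg, paste("table must have columns", paste(need, collapse = ", ")))
    else {
        if (length(object@residues) != nrow(tab))
            msg <- c(msg, "one residue sequence required per table row")
        if (!all(tab$segment %in% c("o", "p", "i")))
            msg <- c(msg, "segment must be one of 'o', 'p', 'i'")
        if (!all(tab$domain %in% 1:4))
            msg <- c(msg, "domain must be an integer in 1..4")
        key <- paste(tab$channel, tab$domain, tab$segment)
        if (anyDuplicated(key))
            msg <- c(msg, paste("duplicate (channel, domain, segment) row:",
                                key[duplicated(key)][1L]))
        bad_start <- (tab$segment == "p" & tab$start != 33L) |
            (tab$segment != "p" & tab$start != 1L)
        if (any(bad_start))
            msg <- c(msg, paste("wrong start position in row", which(bad_start)[1L],
                                "(P-loops start at 33, helices at 1)"))
        if (length(object@residues) == nrow(tab)) {
            freq <- Biostrings::alphabetFrequency(object@residues)
            std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
            extra <- rowSums(freq[, setdiff(colnames(freq), std), drop = FALSE])
            if (any(extra > 0))
                msg <- c(msg, paste("non-standard residue letter in row",
                                    which(extra > 0)[1L]))
        }
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "ChannelAlignment", function(object) {
    cat(sprintf("ChannelAlignment: %d segment rows, channels: %s\n",
                nrow(object@table),
                paste(unique(object@table$channel), collapse = ", ")))
    if (nrow(object@uncertain))
        cat(sprintf("  %d residue position(s) flagged uncertain\n",
                    nrow(object@uncertain)))
})

#' @describeIn ChannelAlignment number of segment rows.
#' @param x a ChannelAlignment.
#' @export
setMethod("length", "ChannelAlignment", function(x) nrow(x@table))

#' Channel-family classification by the domain-III lysine signature
#'
#' @slot channel canonical channel id.
#' @slot family "TCC" (T-type) or "LCC" (L-type).
#' @slot residue3p49 residue at position 3p49.
#' @slot residue3p50 residue at position 3p50.
#' @slot filterMotif 4-character string of the p50 residues of domains I-IV
#'   (the selectivity-filter locus: EEEE in L-type, EEDD in T-type).
#' @export
setClass("ChannelClassification",
         representation(channel = "character", family = "character",
                        residue3p49 = "character", residue3p50 = "character",
                        filterMotif = "character"))

setValidity("ChannelClassification", function(object) {
    msg <- character()
    if (!object@family %in% c("TCC", "LCC"))
        msg <- c(msg, "family must be 'TCC' or 'LCC'")
    is_tcc <- identical(object@residue3p49, "K") &&
        object@residue3p50 %in% c("D", "E")
    if (is_tcc != identical(object@family, "TCC"))
        msg <- c(msg, "family must be TCC iff residue 3p49 is K and 3p50 is D or E")
    if (nchar(object@filterMotif) != 4L)
        msg <- c(msg, "filterMotif must have one residue per domain (4 characters)")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ChannelClassification", function(object) {
    cat(sprintf("%s: %s (3p49 = %s, 3p50 = %s, filter motif %s)\n",
                object@channel, object@family, object@residue3p49,
                object@residue3p50, object@filterMotif))
})

#' Specification of a synthetic screening cohort
#'
#' Defines the composition and distributions of a simulated docking /
#' property cohort with known ground truth. See [generateCohort()].
#'
#' @slot nCompounds number of compounds.
#' @slot fractionTcc fraction of truly TCC-selective compounds.
#' @slot fractionNonBinder fraction of non-binders; the remainder are dual
#'   blockers.
#' @slot dgTccMean,dgTccSd Gaussian parameters (kcal/mol) for binding free
#'   energies of TCC-selective compounds on T-type receptors.
#' @slot dgDualTccMean,dgDualTccSd,dgDualLccMean,dgDualLccSd Gaussian
#'   parameters for dual blockers on T-type and on the L-type receptor.
#' @slot missingness probability that any present free energy is dropped
#'   (recorded as missing) as observation noise.
#' @slot logpRange,sasRange,qedRange uniform ranges for compound properties.
#' @slot plantDominant if TRUE, compound 1 is forced TCC-selective and
#'   strictly dominant (best affinity, lowest logP, highest QED).
#' @slot seed integer seed; a fixed seed makes the output byte-stable.
#' @export
setClass("CohortSpec",
         representation(nCompounds = "integer", fractionTcc = "numeric",
                        fractionNonBinder = "numeric",
                        dgTccMean = "numeric", dgTccSd = "numeric",
                        dgDualTccMean = "numeric", dgDualTccSd = "numeric",
                        dgDualLccMean = "numeric", dgDualLccSd = "numeric",
                        missingness = "numeric",
                        logpRange = "numeric", sasRange = "numeric",
                        qedRange = "numeric", plantDominant = "logical",
                        seed = "integer"))

setValidity("CohortSpec", function(object) {
    msg <- character()
    if (object@nCompounds < 0L) msg <- c(msg, "nCompounds must be >= 0")
    fr <- c(object@fractionTcc, object@fractionNonBinder)
    if (any(fr < 0) || sum(fr) > 1)
        msg <- c(msg, "class fractions must be non-negative and sum to <= 1")
    if (object@dgTccSd <= 0 || object@dgDualTccSd <= 0 || object@dgDualLccSd <= 0)
        msg <- c(msg, "free-energy standard deviations must be positive")
    if (object@missingness < 0 || object@missingness > 1)
        msg <- c(msg, "missingness must lie in [0, 1]")
    for (nm in c("logpRange", "sasRange", "qedRange")) {
        r <- slot(object, nm)
        if (length(r) != 2L || r[1L] > r[2L])
            msg <- c(msg, paste(nm, "must be an increasing length-2 range"))
    }
    if (object@qedRange[1L] <= 0 || object@qedRange[2L] > 1)
        msg <- c(msg, "qedRange must lie inside (0, 1]")
    if (object@sasRange[1L] < 1 || object@sasRange[2L] > 10)
        msg <- c(msg, "sasRange must lie inside [1, 10]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "CohortSpec", function(object) {
    cat(sprintf(
        "CohortSpec: %d compounds (%.0f%% TCC-selective, %.0f%% non-binder, rest dual), missingness %.2f, seed %d\n",
        object@nCompounds, 100 * object@fractionTcc,
        100 * object@fractionNonBinder, object@missingness, object@seed))
})
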