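# Bundled example datasets, shipped as plain text under inst/extdata and
# integrity-checked on load.
#
# The three tables describe the in-silico screening study the package's
# methods operate on: an S5/P-loop/S6 pore-domain alignment of the Cav1.2
# (a1C, L-type) and Cav3.1 (a1G, T-type) alpha1 subunits; an AutoDock-Vina
# style docking summary of six phenylalkylamine blockers against homology
# models of a1C/a1G/a1H/a1I; and a descriptor table (logP, SAS, QED) for
# four reference blockers and thirteen computer-designed candidates.
# Note: the property table keeps the spelling "NNC 55-0365" used in its
# source; elsewhere the same blocker is written "NNC 55-0395".

.FIXTURE_MD5 <- c(
    "table2_docking.csv"   = "ed40160aa3d63bc4fde1b049e73bead6",
    "table3_properties.csv" = "acf92d1176d1b7b405bc8a7a574908fc",
    "table4_alignment.tsv" = "aa6f611f9f44d7fcfdb9a51ebb434396")

.fixturePath <- function(name) {
    path <- system.file("extdata", name, package = "tccselect", mustWork = TRUE)
    got <- unname(tools::md5sum(path))
    if (!identical(got, unname(.FIXTURE_MD5[[name]])))
        stop("integrity error: bundled dataset ", name,
             " does not match its recorded checksum")
    path
}

#' Bundled phenylalkylamine docking table
#'
#' Predicted binding free energies (kcal/mol) and binding domains for six
#' phenylalkylamine blockers docked against the a1C L-type and a1G/a1H/a1I
#' T-type channel models; missing entries mean no predicted binding. Where
#' the source reports them, the contacted residue (KcsA-aligned label) and
#' bond type are included.
#'
#' @return data.frame of 24 docking records (see [loadDockingTable()]).
#' @examples
#' table2Fixture()
#' @export
table2Fixture <- function() {
    loadDockingTable(.fixturePath("table2_docking.csv"))
}

#' Bundled compound property table
#'
#' logP, synthetic accessibility and QED for four reference T-type blockers
#' and thirteen computer-designed candidate compounds.
#'
#' @return data.frame of 17 compound records (see [loadPropertyTable()]).
#' @examples
#' table3Fixture()
#' @export
table3Fixture <- function() {
    loadPropertyTable(.fixturePath("table3_properties.csv"))
}

#' Bundled pore-domain segment alignment
#'
#' S5, P-loop and S6 segments of all four domains of the a1C (Cav1.2) and
#' a1G (Cav3.1) alpha1 subunits, KcsA-aligned (helices numbered from 1,
#' P-loops from 33). Use [extendedAlignment()] for the derived a1H/a1I
#' rows.
#'
#' @return A [ChannelAlignment-class] object with 24 segment rows.
#' @examples
#' table4Fixture()
#' @export
table4Fixture <- function() {
    loadAlignment(.fixturePath("table4_alignment.tsv"))
}
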