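# Residue-label nomenclature and channel-family classification over
# S5/P-loop/S6 pore-domain alignments.
#
# Labels follow the KcsA-aligned scheme "<domain><segment><position>":
# segment o = S5 outer helix (positions from 1), p = P-loop (positions from
# 33), i = S6 inner helix (positions from 1). Example: 3p49 = domain III,
# P-loop, aligned position 49.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
.P_START <- 33L
.P_MAX <- 57L

#' Normalize a calcium-channel identifier
#'
#' Accepts the common spellings of the four alpha1 subunits handled here
#' (e.g. "a1G", "alpha1G", "α1G", "Cav3.1") and returns the canonical
#' ASCII id.
#'
#' @param x character vector of channel names.
#' @return Character vector with entries in c("a1C", "a1G", "a1H", "a1I").
#' @examples
#' normalizeChannel(c("alpha1C", "Cav3.1"))
#' @export
normalizeChannel <- function(x) {
    key <- tolower(gsub("[^0-9a-zA-Z.]", "", as.character(x)))
    map <- c(a1c = "a1C", alpha1c = "a1C", cav1.2 = "a1C",
             a1g = "a1G", alpha1g = "a1G", cav3.1 = "a1G",
             a1h = "a1H", alpha1h = "a1H", cav3.2 = "a1H",
             a1i = "a1I", alpha1i = "a1I", cav3.3 = "a1I",
             `1c` = "a1C", `1g` = "a1G", `1h` = "a1H", `1i` = "a1I")
    out <- unname(map[key])
    if (anyNA(out))
        stop("unknown channel identifier: ",
             paste(unique(x[is.na(out)]), collapse = ", "))
    out
}

#' Parse a residue label
#'
#' @param label character vector of labels such as "3p49".
#' @return data.frame with columns domain (integer 1-4), segment ("o", "p"
#'   or "i") and position (integer). Invalid labels raise an error.
#' @examples
#' parseResidueLabel("3p49")
#' @export
parseResidueLabel <- function(label) {
    label <- as.character(label)
    m <- regmatches(label, regexec("^([1-4])([opi])([1-9][0-9]*)$", label))
    bad <- vapply(m, length, 1L) != 4L
    if (any(bad))
        stop("invalid residue label: ", paste(label[bad], collapse = ", "))
    domain <- as.integer(vapply(m, `[`, "", 2L))
    segment <- vapply(m, `[`, "", 3L)
    position <- as.integer(vapply(m, `[`, "", 4L))
    oob <- segment == "p" & (position < .P_START | position > .P_MAX)
    if (any(oob))
        stop("P-loop position out of the 33-57 alignment range: ",
             paste(label[oob], collapse = ", "))
    data.frame(domain = domain, segment = segment, position = position,
               stringsAsFactors = FALSE)
}

#' Render a residue label
#'
#' Inverse of [parseResidueLabel()].
#'
#' @param domain integer 1-4 (or a data.frame as returned by
#'   [parseResidueLabel()]).
#' @param segment "o", "p" or "i".
#' @param position integer alignment position.
#' @return Character vector of labels.
#' @examples
#' formatResidueLabel(3, "p", 49)
#' @export
formatResidueLabel <- function(domain, segment = NULL, position = NULL) {
    if (is.data.frame(domain)) {
        segment <- domain$segment; position <- domain$position
        domain <- domain$domain
    }
    paste0(domain, segment, position)
}

.checkResidues <- function(seqs, context = "sequence") {
    for (i in seq_along(seqs)) {
        letters_i <- strsplit(seqs[[i]], "")[[1L]]
        bad <- setdiff(letters_i, .AA20)
        if (length(bad))
            stop(sprintf("%s %d contains non-standard residue letter(s): %s",
                         context, i, paste(unique(bad), collapse = ", ")))
    }
    invisible(TRUE)
}

.newAlignment <- function(tab, seqs,
                          uncertain = data.frame(channel = character(),
                                                 label = character(),
                                                 reason = character())) {
    aa <- Biostrings::AAStringSet(seqs)
    names(aa) <- paste(tab$channel, tab$domain, tab$segment, sep = "|")
    new("ChannelAlignment", table = tab, residues = aa, uncertain = uncertain)
}

#' Load an S5/P-loop/S6 segment alignment
#'
#' Reads a tab-separated table with columns channel, domain, segment, start
#' and sequence (one row per channel x domain x segment). Whitespace inside
#' printed sequences is stripped; channel names are normalized. Malformed
#' rows (unknown residue letters, wrong numbering origin, duplicate keys)
#' raise an error naming the row.
#'
#' @param file path to the TSV file. See [table4Fixture()] for the bundled
#'   Cav1.2 / Cav3.1 alignment.
#' @return A [ChannelAlignment-class] object (empty for an empty file).
#' @export
loadAlignment <- function(file) {
    tab <- utils::read.delim(file, stringsAsFactors = FALSE,
                             colClasses = "character")
    need <- c("channel", "domain", "segment", "start", "sequence")
    if (!all(need %in% names(tab)))
        stop("alignment file must have columns: ", paste(need, collapse = ", "))
    if (nrow(tab) == 0L)
        return(.newAlignment(data.frame(channel = character(),
                                        domain = integer(),
                                        segment = character(),
                                        start = integer(),
                                        stringsAsFactors = FALSE),
                             character()))
    seqs <- gsub("[[:space:]]", "", tab$sequence)
    .checkResidues(seqs, context = "alignment row")
    out <- data.frame(channel = normalizeChannel(tab$channel),
                      domain = as.integer(tab$domain),
                      segment = tab$segment,
                      start = as.integer(tab$start),
                      stringsAsFactors = FALSE)
    aln <- .newAlignment(out, seqs)
    validObject(aln)
    aln
}

#' Write an alignment back to TSV
#'
#' Round-trip companion to [loadAlignment()].
#'
#' @param aln a [ChannelAlignment-class] object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeAlignment <- function(aln, file) {
    stopifnot(is(aln, "ChannelAlignment"))
    tab <- aln@table
    tab$sequence <- as.character(aln@residues)
    utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Export an alignment as FASTA
#'
#' Headers follow the pattern `channel|d<domain>|<segment>|<start>`.
#'
#' @param aln a [ChannelAlignment-class] object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
exportFasta <- function(aln, file) {
    stopifnot(is(aln, "ChannelAlignment"))
    aa <- aln@residues
    names(aa) <- sprintf("%s|d%d|%s|%d", aln@table$channel, aln@table$domain,
                         aln@table$segment, aln@table$start)
    Biostrings::writeXStringSet(aa, file)
    invisible(file)
}

.segmentRow <- function(aln, channel, domain, segment) {
    hit <- which(aln@table$channel == channel & aln@table$domain == domain &
                 aln@table$segment == segment)
    if (length(hit) != 1L)
        stop(sprintf("no %s segment stored for %s domain %d",
                     segment, channel, domain))
    hit
}

#' Look up the residue at an aligned position
#'
#' @param aln a [ChannelAlignment-class] object.
#' @param channel channel id (any accepted spelling).
#' @param label residue label string such as "3p49", or a parsed label
#'   data.frame.
#' @return Single one-letter residue code.
#' @examples
#' residueAt(table4Fixture(), "a1G", "3p49")  # "K"
#' @export
residueAt <- function(aln, channel, label) {
    stopifnot(is(aln, "ChannelAlignment"))
    channel <- normalizeChannel(channel)
    lab <- if (is.data.frame(label)) label else parseResidueLabel(label)
    stopifnot(nrow(lab) == 1L)
    i <- .segmentRow(aln, channel, lab$domain, lab$segment)
    offset <- lab$position - aln@table$start[i] + 1L
    len <- Biostrings::width(aln@residues)[i]
    if (offset < 1L || offset > len)
        stop(sprintf("position %s is outside the stored %s segment of %s (%d residues from %d)",
                     formatResidueLabel(lab), lab$segment, channel, len,
                     aln@table$start[i]))
    substr(as.character(aln@residues[[i]]), offset, offset)
}

#' Classify a channel as T-type or L-type by the domain-III lysine signature
#'
#' A channel is classified TCC when a lysine sits at 3p49 immediately
#' adjacent to an acidic residue (D or E) at the 3p50 selectivity-filter
#' locus; otherwise LCC. The filter motif is the string of p50 residues of
#' domains I-IV (EEEE for Cav1.2, EEDD for Cav3.x).
#'
#' @param aln a [ChannelAlignment-class] object.
#' @param channel channel id.
#' @return A [ChannelClassification-class] object.
#' @examples
#' classifyChannel(table4Fixture(), "a1G")
#' @export
classifyChannel <- function(aln, channel) {
    channel <- normalizeChannel(channel)
    if (!any(aln@table$channel == channel & aln@table$domain == 3L &
             aln@table$segment == "p"))
        stop("cannot classify ", channel, ": domain-III P-loop not stored")
    r49 <- residueAt(aln, channel, "3p49")
    r50 <- residueAt(aln, channel, "3p50")
    motif <- paste(vapply(1:4, function(d)
        residueAt(aln, channel, paste0(d, "p50")), ""), collapse = "")
    family <- if (identical(r49, "K") && r50 %in% c("D", "E")) "TCC" else "LCC"
    new("ChannelClassification", channel = channel, family = family,
        residue3p49 = r49, residue3p50 = r50, filterMotif = motif)
}

#' Net formal charge of a residue string
#'
#' Sums side-chain formal charges at pH ~7.35: D and E count -1, K and R +1,
#' histidine is counted neutral, all other standard residues 0. This is a
#' simple charge tally over reduced P-loop stretches, not an estimator of
#' solvation or continuum Coulomb energies.
#'
#' @param sequence one-letter residue string (vectorized).
#' @return Integer net charge per input string.
#' @examples
#' formalChargeTally("SKDGW")  # 0: one lysine, one aspartate
#' @export
formalChargeTally <- function(sequence) {
    vapply(as.character(sequence), function(s) {
        letters_i <- strsplit(gsub("[[:space:]]", "", s), "")[[1L]]
        bad <- setdiff(letters_i, .AA20)
        if (length(bad))
            stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "))
        sum((letters_i %in% c("K", "R")) - (letters_i %in% c("D", "E")))
    }, integer(1), USE.NAMES = FALSE)
}

#' Derive a channel's segments by patching another channel
#'
#' Adds rows for `channel` to an alignment by copying the segments of `from`
#' and applying single-residue substitutions given as
#' `"<residue><label>"` strings (e.g. "S3p47" places serine at 3p47).
#' Substitutions that cannot be applied (out-of-range or otherwise
#' uncertain) are recorded in the alignment's `uncertain` table instead of
#' being applied.
#'
#' @param aln a [ChannelAlignment-class] object containing `from`.
#' @param channel id of the channel to create.
#' @param from id of the scaffold channel.
#' @param substitutions character vector of residue-plus-label patches.
#' @param uncertain character vector of patch strings to record as
#'   uncertain without applying.
#' @return The extended [ChannelAlignment-class] object.
#' @export
deriveChannel <- function(aln, channel, from, substitutions,
                          uncertain = character()) {
    stopifnot(is(aln, "ChannelAlignment"))
    channel <- normalizeChannel(channel)
    from <- normalizeChannel(from)
    idx <- which(aln@table$channel == from)
    if (!length(idx)) stop("scaffold channel ", from, " not in alignment")
    tab <- aln@table[idx, , drop = FALSE]
    tab$channel <- channel
    seqs <- as.character(aln@residues[idx])
    unc <- aln@uncertain
    addUnc <- function(label, reason)
        rbind(unc, data.frame(channel = channel, label = label,
                              reason = reason, stringsAsFactors = FALSE))
    for (patch in substitutions) {
        res <- substr(patch, 1L, 1L)
        lab <- tryCatch(parseResidueLabel(substr(patch, 2L, nchar(patch))),
                        error = function(e) NULL)
        if (is.null(lab) || !res %in% .AA20) {
            unc <- addUnc(patch, "unparseable patch label")
            next
        }
        row <- which(tab$domain == lab$domain & tab$segment == lab$segment)
        offset <- lab$position - tab$start[row] + 1L
        if (length(row) != 1L || offset < 1L || offset > nchar(seqs[row])) {
            unc <- addUnc(patch, "position outside stored segment")
            next
        }
        substr(seqs[row], offset, offset) <- res
    }
    for (patch in uncertain)
        unc <- addUnc(patch, "typeset ambiguity in source annotation")
    newTab <- rbind(aln@table, tab)
    newSeqs <- c(as.character(aln@residues), seqs)
    out <- .newAlignment(newTab, newSeqs, uncertain = unc)
    validObject(out)
    out
}

# Curated single-residue differences of Cav3.2 (a1H) and Cav3.3 (a1I)
# relative to the Cav3.1 (a1G) scaffold. Annotations whose labels are
# garbled or out of segment range are kept as uncertain, not applied.
.A1H_PATCHES <- c("L3o7", "V2p54", "S3p47", "N3p54", "V2i8", "S3i15",
                  "A4i1", "L4i2", "V4i5", "T4i9", "V4i13", "V4i23")
.A1H_UNCERTAIN <- c("Y4o16", "R4o29")
.A1I_PATCHES <- c("I1o19", "V1p42", "E1p54", "V2p54", "P2i1", "S2i4",
                  "V2i8", "L3o7", "N3p54", "S3i15", "Y4o16", "Q4p45",
                  "F4i1", "V4i2", "I4i19", "V4i23")
.A1I_UNCERTAIN <- c("K4o29")

#' Alignment extended with the derived Cav3.2 and Cav3.3 segments
#'
#' Extends the bundled Cav1.2 / Cav3.1 alignment with a1H and a1I rows
#' derived from the a1G scaffold by the curated single-residue
#' substitutions; ambiguous annotations are retained as uncertain positions
#' and never asserted on.
#'
#' @param aln base alignment, default [table4Fixture()].
#' @return A [ChannelAlignment-class] object with 48 segment rows.
#' @examples
#' classifyChannel(extendedAlignment(), "a1H")  # TCC
#' @export
extendedAlignment <- function(aln = table4Fixture()) {
    aln <- deriveChannel(aln, "a1H", "a1G", .A1H_PATCHES, .A1H_UNCERTAIN)
    deriveChannel(aln, "a1I", "a1G", .A1I_PATCHES, .A1I_UNCERTAIN)
}
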