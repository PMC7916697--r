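# Residue-label nomenclature, alignment loading and the lysine signature.

test_that("bundled alignment loads with 24 segment rows and strips spacing", {
    aln <- table4Fixture()
    expect_s4_class(aln, "ChannelAlignment")
    expect_identical(length(aln), 24L)
    expect_setequal(unique(aln@table$channel), c("a1C", "a1G"))
    # printed sequences contain grouping spaces; storage must not
    expect_false(any(grepl(" ", as.character(aln@residues))))
    # every P-loop row starts at 33, every helix at 1
    expect_true(all(aln@table$start[aln@table$segment == "p"] == 33L))
    expect_true(all(aln@table$start[aln@table$segment != "p"] == 1L))
})

test_that("alignment round-trips through TSV serialization", {
    aln <- table4Fixture()
    tmp <- tempfile(fileext = ".tsv")
    on.exit(unlink(tmp))
    writeAlignment(aln, tmp)
    back <- loadAlignment(tmp)
    expect_identical(back@table, aln@table)
    expect_identical(as.character(back@residues), as.character(aln@residues))
})

test_that("malformed alignment input is rejected with a pointed error", {
    tmp <- tempfile(fileext = ".tsv")
    on.exit(unlink(tmp))
    # digit inside a sequence
    writeLines(c("channel\tdomain\tsegment\tstart\tsequence",
                 "a1G\t1\tp\t33\tFDN1GYAWIA"), tmp)
    expect_error(loadAlignment(tmp), "non-standard residue")
    # duplicate (channel, domain, segment) key
    writeLines(c("channel\tdomain\tsegment\tstart\tsequence",
                 "a1G\t1\tp\t33\tFDNIGYAWIA",
                 "a1G\t1\tp\t33\tFDNIGYAWIA"), tmp)
    expect_error(loadAlignment(tmp), "duplicate")
    # wrong numbering origin for a P-loop
    writeLines(c("channel\tdomain\tsegment\tstart\tsequence",
                 "a1G\t1\tp\t1\tFDNIGYAWIA"), tmp)
    expect_error(loadAlignment(tmp), "start position")
    # empty file gives an empty alignment
    writeLines("channel\tdomain\tsegment\tstart\tsequence", tmp)
    expect_identical(length(loadAlignment(tmp)), 0L)
})

test_that("residue-label grammar round-trips and rejects invalid labels", {
    set.seed(7)
    for (i in 1:50) {
        seg <- sample(c("o", "p", "i"), 1)
        pos <- if (seg == "p") sample(33:57, 1) else sample(1:30, 1)
        lab <- formatResidueLabel(sample(1:4, 1), seg, pos)
        expect_identical(formatResidueLabel(parseResidueLabel(lab)), lab)
    }
    expect_error(parseResidueLabel("5p50"), "invalid")
    expect_error(parseResidueLabel("3x49"), "invalid")
    expect_error(parseResidueLabel("3p0"), "invalid")
    expect_error(parseResidueLabel("3p58"), "33-57")
    expect_error(parseResidueLabel("3p21"), "33-57")
})

test_that("residue lookup reproduces every cited filter-region residue", {
    aln <- table4Fixture()
    expect_identical(residueAt(aln, "a1G", "3p49"), "K")
    expect_identical(residueAt(aln, "a1G", "3p50"), "D")
    expect_identical(residueAt(aln, "a1G", "1p50"), "E")
    expect_identical(residueAt(aln, "a1G", "2p50"), "E")
    expect_identical(residueAt(aln, "a1G", "4p50"), "D")
    expect_identical(residueAt(aln, "a1G", "1p51"), "G")
    expect_identical(residueAt(aln, "a1C", "3p50"), "E")
    # out-of-range lookup errors rather than returning a wrong letter
    expect_error(residueAt(aln, "a1G", "3o28"), "outside")
    # accepts alternative channel spellings
    expect_identical(residueAt(aln, "alpha1G", "3p49"), "K")
})

test_that("lysine signature separates T-type from L-type channels", {
    aln <- table4Fixture()
    g <- classifyChannel(aln, "a1G")
    expect_identical(g@family, "TCC")
    expect_identical(g@filterMotif, "EEDD")
    c_ <- classifyChannel(aln, "a1C")
    expect_identical(c_@family, "LCC")
    expect_identical(c_@filterMotif, "EEEE")
    # exactly the a1G rows classify TCC, exactly the a1C rows LCC
    fams <- vapply(c("a1C", "a1G"),
                   function(ch) classifyChannel(aln, ch)@family, "")
    expect_identical(unname(fams), c("LCC", "TCC"))
    # a channel lacking the domain-III P-loop cannot be classified
    sub <- aln@table$segment != "p" | aln@table$domain != 3L
    crippled <- new("ChannelAlignment", table = aln@table[sub, ],
                    residues = aln@residues[sub], uncertain = aln@uncertain)
    expect_error(classifyChannel(crippled, "a1G"), "domain-III")
})

test_that("replacing the 3p49 lysine flips the classification to LCC", {
    aln <- table4Fixture()
    mutant <- deriveChannel(aln, "a1H", "a1G", "G3p49")
    cl <- classifyChannel(mutant, "a1H")
    expect_identical(cl@residue3p49, "G")
    expect_identical(cl@family, "LCC")
})

test_that("derived a1H/a1I channels keep the signature; odd patches are quarantined", {
    ext <- extendedAlignment()
    expect_identical(length(ext), 48L)
    for (ch in c("a1H", "a1I")) {
        cl <- classifyChannel(ext, ch)
        expect_identical(cl@family, "TCC")
        expect_identical(cl@filterMotif, "EEDD")
    }
    # applied patch spot-checks: domain-III P-loop tail of a1H reads
    # S..SKDGWVN (3p47 A->S, 3p54 D->N)
    expect_identical(residueAt(ext, "a1H", "3p47"), "S")
    expect_identical(residueAt(ext, "a1H", "3p54"), "N")
    expect_identical(residueAt(ext, "a1I", "1p54"), "E")
    # garbled source annotations are recorded, not silently applied
    expect_setequal(ext@uncertain$label[ext@uncertain$channel == "a1H"],
                    c("Y4o16", "R4o29"))
    expect_true("K4o29" %in% ext@uncertain$label[ext@uncertain$channel == "a1I"])
})

test_that("FASTA export writes one labelled record per segment row", {
    aln <- table4Fixture()
    tmp <- tempfile(fileext = ".fasta")
    on.exit(unlink(tmp))
    exportFasta(aln, tmp)
    fa <- Biostrings::readAAStringSet(tmp)
    expect_identical(length(fa), 24L)
    expect_true("a1G|d3|p|33" %in% names(fa))
    expect_identical(as.character(fa[["a1G|d3|p|33"]]),
                     "FDNLGQALMSLFVLASKDGWVDIMY")
})

test_that("formal charge tally follows the pH-7 convention", {
    # reduced P-loop stretches of the four T-type domains
    expect_identical(formalChargeTally("TLEGWV"), -1L)
    expect_identical(formalChargeTally("TQEDW"), -2L)
    expect_identical(formalChargeTally("SKDGW"), 0L)
    expect_identical(formalChargeTally("TGDNW"), -1L)
    # histidine neutral, arginine positive; vectorized
    expect_identical(formalChargeTally(c("HH", "RKDE")), c(0L, 0L))
    expect_error(formalChargeTally("KDXB"), "unknown residue")
})
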