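# PLINK readers, family-unit construction and Mendelian screening.

writeLinesTo <- function(lines, name) {
    path <- file.path(withr::local_tempdir(.local_envir = parent.frame()),
                      name)
    writeLines(lines, path)
    path
}

test_that("ped text parsing recodes genotypes and handles missingness", {
    ped <- writeLinesTo(c("F1 I1 0 0 1 2 A A",
                          "F2 I2 0 0 2 1 A C",
                          "F3 I3 0 0 1 1 0 0",
                          "F4 I4 0 0 1 2 A 0"), "a.ped")
    map <- writeLinesTo("1 snp1 0 100", "a.map")
    st <- readPlinkText(ped, map)
    expect_equal(markerInfo(st)$allele1, "A")   # lexicographically smaller
    expect_equal(unname(genotypes(st)[1, ]), c(2L, 1L, NA, NA))
    expect_equal(individualInfo(st)$phenotype,
                 c("affected", "unaffected", "unaffected", "affected"))
})

test_that("malformed ped rows and multiallelic markers are reported", {
    map <- writeLinesTo(c("1 snp1 0 100", "1 snp2 0 200"), "b.map")
    bad <- writeLinesTo("F1 I1 0 0 1 2 A A", "b.ped")   # 1 marker only
    expect_error(readPlinkText(bad, map), "line 1")

    ped <- writeLinesTo(c("F1 I1 0 0 1 2 A A A G",
                          "F2 I2 0 0 1 1 A C G T",
                          "F3 I3 0 0 1 1 C C T T"), "c.ped")
    expect_warning(st <- readPlinkText(ped, map), "multiallelic")
    expect_true(markerInfo(st)$multiallelic[2])
    expect_false(markerInfo(st)$multiallelic[1])
    expect_true(all(is.na(genotypes(st)[2, ])))
    expect_equal(unname(genotypes(st)[1, ]), c(2L, 1L, 0L))
})

test_that("simgen round-trips through text and binary identically", {
    cfg <- simConfig(counts = data.frame(cases = 5, controls = 4, triads = 3,
                                         multiplex = 2),
                     nMarkers = 7, fst = 0, seed = 42)
    st <- simulateStudy(cfg)
    td <- withr::local_tempdir()
    writePlink(st, file.path(td, "t"), "text")
    back <- readPlinkText(file.path(td, "t.ped"), file.path(td, "t.map"))
    expect_identical(unname(genotypes(back)), unname(genotypes(st)))
    expect_equal(individualInfo(back)$phenotype,
                 individualInfo(st)$phenotype)

    writePlink(st, file.path(td, "b"), "binary")
    bin <- readPlinkBinary(file.path(td, "b.bed"), file.path(td, "b.bim"),
                           file.path(td, "b.fam"))
    expect_identical(unname(genotypes(bin)), unname(genotypes(back)))
    expect_identical(markerInfo(bin)$allele1, markerInfo(back)$allele1)
})

test_that("bed decoding rejects bad magic, mode and truncation", {
    td <- withr::local_tempdir()
    cfg <- simConfig(counts = data.frame(cases = 3, controls = 2, triads = 0,
                                         multiplex = 0),
                     nMarkers = 2, fst = 0, seed = 1)
    st <- simulateStudy(cfg)
    writePlink(st, file.path(td, "x"), "binary")
    bed <- readBin(file.path(td, "x.bed"), "raw", 100)

    writeBin(c(as.raw(c(0x6c, 0x1b, 0x00)), bed[-(1:3)]),
             file.path(td, "m.bed"))
    expect_error(readPlinkBinary(file.path(td, "m.bed"),
                                 file.path(td, "x.bim"),
                                 file.path(td, "x.fam")), "SNP-major")

    writeBin(bed[1:4], file.path(td, "t.bed"))
    expect_error(readPlinkBinary(file.path(td, "t.bed"),
                                 file.path(td, "x.bim"),
                                 file.path(td, "x.fam")), "truncation")

    writeBin(as.raw(c(0x00, 0x1b, 0x01)), file.path(td, "w.bed"))
    expect_error(readPlinkBinary(file.path(td, "w.bed"),
                                 file.path(td, "x.bim"),
                                 file.path(td, "x.fam")), "magic")

    # empty body with zero markers is fine
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), file.path(td, "e.bed"))
    file.create(file.path(td, "e.bim"))
    writeLines("F1 I1 0 0 1 2", file.path(td, "e.fam"))
    st0 <- readPlinkBinary(file.path(td, "e.bed"), file.path(td, "e.bim"),
                           file.path(td, "e.fam"))
    expect_equal(dim(genotypes(st0)), c(0L, 1L))
})

test_that("family units are built per sibship with singleton folding", {
    ind <- data.frame(
        familyId = c("F1", "F1", "F1", "F1", "U1", "U2", "U3"),
        individualId = c("dad", "mum", "kid2", "kid1", "case1", "ctrl1",
                         "nophen"),
        fatherId = c(NA, NA, "dad", "dad", NA, NA, NA),
        motherId = c(NA, NA, "mum", "mum", NA, NA, NA),
        sex = c("male", "female", "unknown", "unknown", "male", "female",
                "male"),
        phenotype = c("unaffected", "affected", "affected", "affected",
                      "affected", "unaffected", "missing"),
        stringsAsFactors = FALSE)
    expect_warning(bu <- buildFamilyUnits(ind), "excluded")
    tags <- vapply(bu$units, function(u) u@designTag, character(1))
    expect_setequal(tags, c("multiplex", "case_singleton",
                            "control_singleton"))
    fam <- bu$units[[which(tags == "multiplex")]]
    # affected sibs sorted by individual id; affected mother is a parent,
    # never a sibling
    expect_equal(fam@affectedSibs, c(4L, 3L))
    expect_equal(fam@father, 1L)
    # accounting: every individual is in exactly one unit or excluded
    inUnits <- sort(unlist(lapply(bu$units, unitMembers)))
    expect_equal(length(inUnits) + nrow(bu$exclusions), nrow(ind))
    expect_equal(anyDuplicated(inUnits), 0L)
    expect_equal(bu$exclusions$individualId, "nophen")
})

test_that("triad and half-sib sibships are tagged and split correctly", {
    ind <- data.frame(
        familyId = c("F1", "F1", "F1", "F2", "F2", "F2", "F2"),
        individualId = c("d", "m", "c", "d", "m1", "c1", "c2"),
        fatherId = c(NA, NA, "d", NA, NA, "d", "d"),
        motherId = c(NA, NA, "m", NA, NA, "m1", "other"),
        sex = "unknown",
        phenotype = c("unaffected", "unaffected", "affected",
                      "unaffected", "unaffected", "affected", "affected"),
        stringsAsFactors = FALSE)
    expect_warning(bu <- buildFamilyUnits(ind), "not in the data")
    tags <- vapply(bu$units, function(u) u@designTag, character(1))
    expect_true("triad" %in% tags)
    # half sibs (different mothers) never collapse into one unit
    expect_equal(sum(vapply(bu$units, function(u)
        any(c(6L, 7L) %in% u@affectedSibs), logical(1))), 2L)
})

test_that("pedigree cycles are detected", {
    ind <- data.frame(
        familyId = c("F1", "F1"), individualId = c("a", "b"),
        fatherId = c("b", "a"), motherId = c(NA, NA),
        sex = "unknown", phenotype = "affected", stringsAsFactors = FALSE)
    expect_error(buildFamilyUnits(ind), "cycle")
})

test_that("Mendelian screening matches transmission logic", {
    u <- FamilyUnit("F", father = 1L, mother = 2L, affectedSibs = 3L)
    expect_false(mendelConsistent(u, c(2L, 2L, 1L)))   # AA x AA -> Aa
    expect_true(mendelConsistent(u, c(1L, 1L, 0L)))    # het x het spans all
    expect_true(mendelConsistent(u, c(NA, NA, 2L)))    # missing never fails
    # father AA, mother missing: child 0 impossible whatever the mother
    expect_false(mendelConsistent(u, c(2L, NA, 0L)))
    expect_true(mendelConsistent(u, c(2L, NA, 1L)))
    # both-parent joint rule
    expect_false(mendelConsistent(u, c(0L, 2L, 0L)))   # must be het
    expect_true(mendelConsistent(u, c(0L, 2L, 1L)))
})
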