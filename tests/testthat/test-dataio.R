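test_that("spectrum files round-trip with the NMR axis conventions", {
    # headers written descending, stored ascending, values to print precision
    set.seed(42)
    x <- matrix(rexp(4 * 50), 4, 50)
    axis <- sort(runif(50, 0.5, 10))
    s <- toySet(x, axis)
    sp <- tempfile(fileext = ".csv"); mp <- tempfile(fileext = ".csv")
    writeSpectrumSet(s, sp, mp)
    hdr <- strsplit(readLines(sp, n = 1L), ",")[[1]]
    expect_identical(hdr[1], "sample_id")
    expect_true(all(diff(as.numeric(hdr[-1])) < 0))
    r <- readSpectrumSet(sp, mp)
    expect_true(all(diff(ppm(r)) > 0))
    expect_equal(ppm(r), ppm(s), tolerance = 1e-12)
    expect_equal(unname(intensityMatrix(r)), unname(intensityMatrix(s)),
                 tolerance = 1e-11)
    expect_identical(sampleInfo(r), sampleInfo(s))

    # explicit axis-order example: file columns 10, 5, 1
    f <- tempfile(fileext = ".csv")
    writeLines(c("sample_id,10.0,5.0,1.0", "a,3,2,1", "b,6,5,4"), f)
    m <- tempfile(fileext = ".csv")
    utils::write.csv(sampleMeta(2, prefix = ""), m, row.names = FALSE)
    writeLines(c("sample_id,genotype,replicate,compartment",
                 "a,WT,1,intracellular", "b,WT,2,intracellular"), m)
    r2 <- readSpectrumSet(f, m)
    expect_equal(ppm(r2), c(1, 5, 10))
    expect_equal(unname(intensityMatrix(r2)[, 1]), c(1, 4))
    expect_equal(unname(intensityMatrix(r2)[, 3]), c(3, 6))
})

test_that("spectrum reading enforces its contracts", {
    f <- tempfile(fileext = ".csv"); m <- tempfile(fileext = ".csv")
    writeLines(c("sample_id,1.0,2.0", "s1,1,2", "s2,3,4"), f)
    writeLines(c("sample_id,genotype,replicate,compartment",
                 "s1,WT,1,intracellular"), m)
    expect_error(readSpectrumSet(f, m), "s2")

    writeLines(c("sample_id,genotype,replicate,compartment",
                 "s1,WT,1,intracellular", "s2,WT,2,intracellular"), m)
    bad <- tempfile(fileext = ".csv")
    writeLines(c("sample_id,1.0,2.0", "s1,1,oops", "s2,3,4"), bad)
    expect_error(readSpectrumSet(bad, m), "row 1.*2\\.0")

    dup <- tempfile(fileext = ".csv")
    writeLines(c("sample_id,1.0,1.0", "s1,1,2", "s2,3,4"), dup)
    expect_error(readSpectrumSet(dup, m), "duplicate ppm")

    empty <- toySet(matrix(1, 1, 3))[, integer(0)]
    expect_error(writeSpectrumSet(empty, f, m), "no samples")
})

test_that("peak libraries round-trip through JSON and validate", {
    lib <- tinyLibrary()
    f <- tempfile(fileext = ".json")
    writePeakLibrary(lib, f)
    r <- readPeakLibrary(f)
    expect_equal(peakTable(r), peakTable(lib))

    # mixed-width HMDB accessions normalize to the padded form
    expect_identical(normalizeHmdb(c("HMDB00190", "HMDB0000190")),
                     rep("HMDB0000190", 2))
    pk <- peakTable(lib)
    pk$hmdb[pk$name == "MetA"] <- "HMDB1"
    expect_identical(unique(PeakLibrary(pk)@peaks$hmdb),
                     c("HMDB0000001", "HMDB0000002"))

    bad <- pk; bad$multiplicity[1] <- "x"
    expect_error(PeakLibrary(bad), "multiplicity")
    bad <- rbind(pk, data.frame(name = "MetA", hmdb = "HMDB0000009",
                                ppm = 2, multiplicity = "s", j_hz = 0,
                                rel_intensity = 1))
    expect_error(PeakLibrary(bad), "duplicate")
    zp <- tempfile(fileext = ".json")
    writeLines('{"metabolites":[{"name":"Z","hmdb":"HMDB0000003","peaks":[]}]}',
               zp)
    expect_error(readPeakLibrary(zp), "no peaks")
})

test_that("the packaged library carries the documented multiplets", {
    lib <- defaultPeakLibrary()
    lac <- peakTable(lib)[peakTable(lib)$name == "Lactate", ]
    expect_equal(sort(lac$ppm), c(1.331, 4.113))
    expect_identical(lac$multiplicity[order(lac$ppm)], c("d", "q"))
    expect_identical(unique(lac$hmdb), "HMDB0000190")
    expect_true(all(peakTable(lib)$ppm >= 0 & peakTable(lib)$ppm <= 12))
    expect_identical(anyDuplicated(hmdbIds(lib)), 0L)
})

test_that("pathway GMT files parse, validate and round-trip", {
    f <- tempfile(fileext = ".gmt")
    writeLines("AAbio\tdesc\tHMDB00687\tHMDB00172", f)
    p <- readPathwayLibrary(f)
    expect_identical(pathwayNames(p), "AAbio")
    expect_identical(pathwayMembers(p)$AAbio,
                     c("HMDB0000687", "HMDB0000172"))

    writeLines(c("A\td\tHMDB0000001", "B only"), f)
    expect_error(readPathwayLibrary(f), "line 2")
    writeLines(c("A\td\tHMDB0000001", "A\td\tHMDB0000002"), f)
    expect_error(readPathwayLibrary(f), "duplicate")

    sets <- list(P1 = c("HMDB0000001", "HMDB0000002"),
                 P2 = "HMDB0000003",
                 P3 = c("HMDB0000001", "HMDB0000004", "HMDB0000005"))
    lib <- PathwayLibrary(sets, c(P1 = "one", P2 = "two", P3 = "three"))
    writePathwayLibrary(lib, f)
    r <- readPathwayLibrary(f)
    expect_identical(pathwayMembers(r), pathwayMembers(lib))
    expect_identical(r@descriptions, lib@descriptions)
})
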