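ref <- fixtureReference()

test_that("printed variant sequences classify to their printed names", {
    r <- classifyRead("UUCACAGUGGCUAAGUUCUGC", ref)
    expect_true(r$assigned)
    expect_identical(r$category, "refseq")
    expect_identical(r$offset5, 0L)
    expect_identical(r$offset3, 0L)
    expect_identical(r$name, "miR-27b-3p")

    r <- classifyRead("UCACAGUGGCUAAGUUCUGC", ref)
    expect_identical(r$category, "iso5")
    expect_identical(r$offset5, 1L)
    expect_identical(r$offset3, 0L)
    expect_identical(r$name, "miR-27b-3p_t_+1_0")

    r <- classifyRead("CCAGUGUUCAGACUACCUGUUC", ref)
    expect_identical(r$offset5, 1L)
    expect_identical(r$name, "miR-199a-5p_t_+1_0")
})

test_that("non-templated tails are detected against non-matching flanks", {
    arm <- unname(armSequence(ref, "miR-27b-3p"))   # flanked by CGGC
    r <- classifyRead(paste0(arm, "AA"), ref)
    expect_identical(r$category, "nontemplate")
    expect_identical(r$offset5, 0L)
    expect_identical(r$offset3, 2L)
    expect_identical(r$tail, "AA")
    expect_identical(r$name, "miR-27b-3p_nont_0_+2_AA")

    # a tail matching the flank is templated instead (maximal prefix)
    r2 <- classifyRead(paste0(arm, "CG"), ref)
    expect_identical(r2$category, "iso3")
    expect_identical(r2$name, "miR-27b-3p_t_0_+2")

    r3 <- classifyRead(paste0(substr(arm, 1, 20), "AAAAAA"), ref)
    expect_false(r3$assigned)
    expect_identical(r3$reason, "tail_too_long")

    expect_error(classifyRead("UUCACAGNGGCUAAGUUCUGC", ref), "A,C,G,U")
    expect_false(classifyRead(strrep("ACGU", 8), ref)$assigned)  # 32 nt
})

test_that("canonical names format offsets with explicit signs", {
    expect_identical(
        nameCall(list(parent = "miR-449c-5p", offset5 = 0L, offset3 = -2L,
                      tail = "")),
        "miR-449c-5p_t_0_-2")
    expect_identical(
        nameCall(list(parent = "miR-127-3p", offset5 = 0L, offset3 = 2L,
                      tail = "AU")),
        "miR-127-3p_nont_0_+2_AU")
    expect_identical(
        nameCall(list(parent = "let-7g-5p", offset5 = 0L, offset3 = 0L,
                      tail = "")),
        "let-7g-5p")
})

test_that("parseName inverts nameCall and rejects malformed names", {
    p <- parseName("miR-30d-5p_t_+1_+2")
    expect_identical(p[c("parent", "category", "offset5", "offset3")],
                     list(parent = "miR-30d-5p", category = "iso5_3",
                          offset5 = 1L, offset3 = 2L))
    p <- parseName("miR-92a-3p_nont_0_+2_AA")
    expect_identical(p$category, "nontemplate")
    expect_identical(p$tail, "AA")
    expect_error(parseName("miR-92a-3p_x_0_0"), "malformed")
    expect_error(parseName("miR-92a-3p_t_+0_0"), "malformed")
    expect_error(parseName("miR-92a-3p_t_0_0"), "zero offsets")
})

test_that("naming is bijective over the valid field grid", {
    tails <- c("", "A", "AA", "AAA", "U", "AU", "UU")
    for (parent in c("miR-27b-3p", "let-7g-5p", "miR-9-5p")) {
        for (o5 in -5:5) for (o3 in -5:8) for (tail in tails) {
            call <- list(parent = parent, offset5 = as.integer(o5),
                         offset3 = as.integer(o3), tail = tail)
            nm <- nameCall(call)
            back <- parseName(nm)
            expect_identical(back$parent, parent)
            expect_identical(back$offset5, as.integer(o5))
            expect_identical(back$offset3, as.integer(o3))
            expect_identical(back$tail, tail)
        }
    }
})

test_that("classifier agrees with the brute-force oracle on random instances", {
    set.seed(42)
    cfg <- classifierConfig()
    n_mismatch <- 0
    for (rep in 1:60) {
        rs <- makeReference(nPrecursors = 2L, seed = 5000 + rep)
        reads <- replicate(20, randomReadFor(rs, cfg))
        got <- classifyReads(reads, rs, cfg)
        for (i in seq_along(reads)) {
            want <- oracleClassify(reads[i], rs, cfg)
            expect_identical(got$assigned[i], want$assigned)
            if (want$assigned)
                expect_identical(got$name[i], want$name)
        }
    }
})

test_that("emitted calls conserve length and reference reads stay refseq", {
    set.seed(7)
    cfg <- classifierConfig()
    for (rep in 1:10) {
        rs <- makeReference(nPrecursors = 3L, seed = 900 + rep)
        arms <- armSequence(rs)
        # reads equal to an arm are always refseq with zero offsets
        for (nm in names(arms)) {
            r <- classifyRead(arms[[nm]], rs, cfg)
            expect_identical(r$category, "refseq")
            expect_identical(r$name, nm)
        }
        reads <- replicate(30, randomReadFor(rs, cfg))
        got <- classifyReads(reads, rs, cfg)
        ok <- got$assigned
        reflen <- nchar(armSequence(rs))[got$parent[ok]]
        expect_equal(nchar(got$read[ok]),
                     unname(reflen) - got$offset5[ok] + got$offset3[ok])
    }
})

test_that("seed extraction and seed-shift detection follow the 2-8 rule", {
    expect_identical(seedOf("UUCACAGUGGCUAAGUUCUGC"), "UCACAGU")
    expect_error(seedOf("UUCACAG"), "8 nt")
    expect_true(isSeedShifted("miR-27b-3p_t_+1_0"))
    expect_false(isSeedShifted("miR-449c-5p_t_0_-2"))
    expect_false(isSeedShifted("miR-92a-3p_nont_0_+2_AA"))
    expect_true(isSeedShifted(classifyRead("UCACAGUGGCUAAGUUCUGC", ref)))
})
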