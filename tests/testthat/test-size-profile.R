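test_that("profiles tally exact 1-bp frequencies over the window", {
    p <- buildProfile(rep(166, 8), "s", "nuclear", "DSP")
    expect_equal(unname(profileFrequency(p)["166"]), 1)
    expect_equal(sum(profileFrequency(p)), 1)

    q <- buildProfile(c(100, 100, 200, 500), "s", "nuclear", "DSP")
    expect_equal(unname(profileFrequency(q)[c("100", "200", "500")]),
                 c(0.5, 0.25, 0.25))
    expect_equal(totalReads(q), 4)

    # out-of-window lengths leave numerator and denominator alike
    r <- buildProfile(c(20, 1500, 166), "s", "nuclear", "DSP")
    expect_equal(totalReads(r), 1)
    expect_equal(unname(profileFrequency(r)["166"]), 1)

    expect_error(buildProfile(c(10, 2000), "s", "nuclear", "DSP"),
                 "undefined")
})

test_that("mean profiles weight samples equally and renormalise", {
    p <- buildProfile(c(100, 150), "a", "nuclear", "DSP")
    expect_equal(profileFrequency(meanProfile(list(p))),
                 profileFrequency(p))

    one <- buildProfile(rep(100, 10), "a", "nuclear", "DSP")
    two <- buildProfile(rep(200, 90), "b", "nuclear", "DSP")
    m <- meanProfile(list(one, two))
    expect_equal(unname(profileFrequency(m)[c("100", "200")]), c(0.5, 0.5))
    expect_equal(totalReads(m), 100)

    seven <- replicate(7, p)
    expect_equal(profileFrequency(meanProfile(seven)), profileFrequency(p))

    ssp <- buildProfile(c(100, 150), "c", "nuclear", "SSP")
    expect_error(meanProfile(list(p, ssp)), "share")
})

test_that("band fractions sum correctly and reject inverted bounds", {
    p <- buildProfile(c(100, 100, 200, 500), "s", "nuclear", "DSP")
    expect_equal(bandFraction(p, 30, 1000), 1)
    expect_equal(bandFraction(p, 90, 260), 0.75)
    expect_error(bandFraction(p, 260, 90), "inverted")
    expect_error(bandFraction(p, 10, 90), "within")
    # additivity: disjoint bands covering the window sum to 1
    cuts <- c(30, 100, 200, 500, 1000)
    parts <- mapply(function(l, h) bandFraction(p, l, h),
                    c(30, 101, 201, 501), c(100, 200, 500, 1000))
    expect_equal(sum(parts), 1)
})

test_that("modal size picks the maximum and breaks ties to the smaller size", {
    expect_equal(modalSize(buildProfile(c(100, 100, 200), "s", "nuclear",
                                        "DSP")), 100)
    expect_equal(modalSize(buildProfile(c(100, 200), "s", "nuclear",
                                        "DSP")), 100)
})

test_that("short/long ratio uses strict thresholds and flags undefined", {
    p <- buildProfile(c(80, 80, 250, 300), "s", "mitochondrial", "DSP")
    expect_equal(shortLongRatio(p), 1)
    mid <- buildProfile(c(90, 150, 200), "s", "mitochondrial", "DSP")
    expect_true(is.na(shortLongRatio(mid)))
    # boundary sizes 90 and 200 belong to neither side
    expect_equal(shortLongRatio(buildProfile(c(89, 90, 200, 201), "s",
                                             "mitochondrial", "DSP")), 1)
    # printed double-strand means: 0.9% below 90, 38.1% above 200
    dsp <- buildProfile(c(rep(80, 9), rep(250, 381), rep(150, 610)),
                        "s", "mitochondrial", "DSP")
    expect_equal(round(shortLongRatio(dsp), 2), 0.02)
})

test_that("periodicity score is zero on flat profiles, plug-in positive on combs", {
    flat <- buildProfile(rep(30:1000, 2), "s", "nuclear", "DSP")
    expect_equal(periodicityScore(flat), 0)
    comb <- c(rep(seq(102, 152, 10), each = 2),  # 0.02 at each peak
              seq(97, 157, 10),                  # 0.01 at every +/-5 neighbour
              rep(500, 81))                      # filler mass, total 100
    p <- buildProfile(comb, "s", "nuclear", "DSP")
    expect_equal(periodicityScore(p), 0.01)
    expect_error(periodicityScore(p, positions = 32), "window")
})

test_that("synthetic nuclear combing is detected, mitochondrial is not", {
    n <- 200000
    nuc <- buildProfile(sampleFragmentLengths(
        defaultMixtureConfig("nuclear", "DSP"), n, seed = 21))
    mt <- buildProfile(sampleFragmentLengths(
        defaultMixtureConfig("mitochondrial", "DSP"), n, seed = 22))
    expect_gt(periodicityScore(nuc), 0)
    # null scale: resample a comb-free profile and take 3 SD of the score
    nullScores <- vapply(1:20, function(i) {
        periodicityScore(buildProfile(sampleFragmentLengths(
            defaultMixtureConfig("mitochondrial", "DSP"), n,
            seed = 100 + i)))
    }, 0)
    expect_lt(abs(periodicityScore(mt)), 3 * sd(nullScores) + 1e-12)
    expect_gt(periodicityScore(nuc), 10 * sd(nullScores))
})

test_that("library comparison folds behave and propagate undefined values", {
    lens <- c(rep(80, 10), rep(150, 70), rep(250, 20))
    dsp <- buildProfile(lens, "s", "mitochondrial", "DSP")
    ssp <- buildProfile(lens, "s", "mitochondrial", "SSP")
    cmp <- compareLibraries(dsp, ssp)
    expect_equal(cmp$foldBelow90, 1)
    expect_equal(cmp$foldAbove200, 1)
    expect_equal(cmp$ratioOfRatios, 1)

    # printed healthy-individual means: below-90 fractions 0.9% vs 33.5%
    dsp2 <- buildProfile(c(rep(80, 9), rep(150, 991)), "s",
                         "mitochondrial", "DSP")
    ssp2 <- buildProfile(c(rep(80, 335), rep(150, 665)), "s",
                         "mitochondrial", "SSP")
    cmp2 <- compareLibraries(dsp2, ssp2)
    expect_equal(round(cmp2$foldBelow90, 1), 37.2)
    expect_true(is.na(cmp2$foldAbove200))   # neither profile exceeds 200
    expect_error(compareLibraries(dsp,
        buildProfile(lens, "s", "nuclear", "SSP")), "same genome")
})

test_that("the overlay offset shifts SSP sizes before comparison", {
    p <- buildProfile(c(100, 200), "s", "nuclear", "SSP")
    shifted <- shiftProfile(p, 3)
    expect_equal(unname(profileFrequency(shifted)[c("103", "203")]),
                 c(0.5, 0.5))
    # an 88-nt SSP fragment crosses the <90 threshold under a +3 offset
    dsp <- buildProfile(c(88, 250), "s", "nuclear", "DSP")
    ssp <- buildProfile(c(88, 250), "s", "nuclear", "SSP")
    expect_equal(compareLibraries(dsp, ssp, offsetBp = 0)$foldBelow90, 1)
    expect_equal(compareLibraries(dsp, ssp, offsetBp = 3)$foldBelow90, 0)
})

test_that("profiles and summaries match a brute-force recount", {
    set.seed(31)
    for (i in 1:5) {
        lens <- c(sample(30:1000, 400, TRUE), sample(1:29, 20, TRUE),
                  sample(1001:1500, 20, TRUE))
        p <- buildProfile(lens, "s", "nuclear", "DSP")
        oracle <- bruteProfileStats(lens)
        expect_equal(unname(profileFrequency(p)), oracle$frequency)
        expect_equal(totalReads(p), oracle$total)
        expect_equal(bandFraction(p, 90, 260),
                     oracle$bandFraction(90, 260))
        expect_equal(modalSize(p), oracle$modalSize)
        expect_equal(shortLongRatio(p), oracle$shortLongRatio)
        s <- profileSummary(p)
        expect_equal(s$fractionBelow90, oracle$fractionBelow90)
        expect_equal(s$fractionAbove200, oracle$fractionAbove200)
    }
})

test_that("duplicating every record leaves frequencies and summaries unchanged", {
    lens <- sample(30:1000, 300, TRUE)
    p1 <- buildProfile(lens, "s", "nuclear", "DSP")
    p2 <- buildProfile(c(lens, lens), "s", "nuclear", "DSP")
    expect_equal(profileFrequency(p1), profileFrequency(p2))
    expect_equal(modalSize(p1), modalSize(p2))
    expect_equal(shortLongRatio(p1), shortLongRatio(p2))
    expect_equal(totalReads(p2), 2 * totalReads(p1))
})

test_that("adding short fragments strictly increases the short/long ratio", {
    lens <- c(rep(150, 50), rep(250, 50))
    prev <- shortLongRatio(buildProfile(lens, "s", "nuclear", "DSP"))
    for (extra in c(1, 5, 20)) {
        cur <- shortLongRatio(buildProfile(c(lens, rep(80, extra)), "s",
                                           "nuclear", "DSP"))
        expect_gt(cur, prev)
        prev <- cur
    }
})
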