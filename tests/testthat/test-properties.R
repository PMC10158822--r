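test_that("without nicks or jags, DSP and SSP observations are equivalent", {
    spans <- function(n) sample(40:900, n, TRUE)
    m <- simulateMolecules(3000, span = spans, jag = 0, nickRate = 0,
                           seed = 19)
    dsp <- dspObserve(m)
    ssp <- sspObserve(m)
    # every molecule contributes its span once to DSP and twice to SSP
    expect_equal(sort(ssp), sort(rep(dsp, 2)))
    pDsp <- buildProfile(dsp, "sim", "nuclear", "DSP")
    pSsp <- buildProfile(ssp, "sim", "nuclear", "SSP")
    expect_equal(unname(profileFrequency(pDsp)),
                 unname(profileFrequency(pSsp)))   # bin-by-bin identical
})

test_that("nicking shortens SSP read-outs monotonically, never DSP", {
    for (seed in c(101, 202, 303)) {
        sspMeans <- numeric(0)
        dspMeans <- numeric(0)
        for (rate in c(0, 0.002, 0.01)) {
            m <- simulateMolecules(10000, span = 300, nickRate = rate,
                                   seed = seed)
            sspMeans <- c(sspMeans, mean(sspObserve(m, minLength = 0)))
            dspMeans <- c(dspMeans, mean(dspObserve(m)))
        }
        expect_true(all(diff(sspMeans) < 0))
        expect_equal(dspMeans, rep(300, 3))  # duplex extent ignores nicks
    }
})

test_that("SSP segment lengths are conserved molecule by molecule", {
    m <- simulateMolecules(500, span = function(n) sample(50:400, n, TRUE),
                           jag = function(n) rexp(n, 1 / 5),
                           nickRate = 0.02, jagStrand = "random", seed = 23)
    allSegs <- sspObserve(m, minLength = 0, maxLength = Inf)
    strandTotal <- sum(m@topEnd - m@topStart) + sum(m@botEnd - m@botStart)
    expect_equal(sum(allSegs), strandTotal)
    # kept + dropped partitions the segments
    kept <- sspObserve(m)
    dropped <- allSegs[allSegs < 30 | allSegs > 1000]
    expect_equal(sum(kept) + sum(dropped), strandTotal)
})

test_that("noise-free preparation series are exact class-survival arithmetic", {
    cls <- defaultStructuralClasses()
    protocols <- list(
        spinProtocol(),
        prepProtocol(centrifugeStep(1200, "LS"), filterStep(0.22),
                     centrifugeStep(16000, "HS")),
        prepProtocol(centrifugeStep(16000, "HS"), filterStep(0.22),
                     centrifugeStep(200000, "UC"))
    )
    for (proto in protocols) {
        s <- simulatePlasmaPrep(cls, c(nuclear = 1, mitochondrial = 1),
                                proto, noiseCv = 0, seed = 1)
        for (g in names(s)) {
            wcol <- if (g == "nuclear") "weight_nuclear"
                    else "weight_mitochondrial"
            amounts <- cls[[wcol]]
            expected <- numeric(nrow(proto))
            for (k in seq_len(nrow(proto))) {
                if (proto$type[k] == "centrifuge")
                    amounts[cls$pellet_g <= proto$value[k]] <- 0
                if (proto$type[k] == "filter")
                    amounts[cls$filter_trapped] <- 0
                expected[k] <- sum(amounts)
            }
            expect_equal(unname(s[[g]]@measurements[, 1]), expected)
            # supernatant signal never increases without a freeze step
            expect_true(all(diff(s[[g]]@measurements[, 1]) < 1e-12))
        }
    }
})

test_that("partition inference recovers configured weights under noise", {
    classMap <- c(UC40000 = "mid-structures", UC200000 = "small-structures")
    truth <- c(0.757, 0.201, 0.042)
    errs <- vapply(1:50, function(seed) {
        s <- simulatePlasmaPrep(defaultStructuralClasses(),
                                c(mitochondrial = 1), spinProtocol(),
                                noiseCv = 0.02, replicates = 20,
                                seed = seed)
        est <- suppressWarnings(
            inferPartition(s$mitochondrial, classMap))
        rec <- c(unname(classFractions(est)), residualFraction(est))
        mean(abs(rec - truth))
    }, 0)
    expect_lt(mean(errs), 0.02)    # mean abs error below 2 percentage points
})

test_that("the integrity index degrades monotonically with nicking", {
    diiAt <- function(rate) {
        m <- simulateMolecules(20000, span = 400, nickRate = rate,
                               seed = 29)
        lens <- sspObserve(m, minLength = 0)
        dnaIntegrityIndex(ampliconDetectableFraction(lens, 310),
                          ampliconDetectableFraction(lens, 67))
    }
    dii <- vapply(c(0, 0.002, 0.01, 0.03), diiAt, 0)
    expect_equal(dii[1], 1)               # unfragmented: index exactly 1
    expect_true(all(diff(dii) < 0))
})

test_that("simulated qPCR round-trips concentrations through the panel", {
    curve <- fitStandardCurve(rep(10^(0:5), 3),
                              40 - 3.4 * log10(rep(10^(0:5), 3)))
    for (qty in c(3, 250, 9e4)) {
        cq <- generateQpcrCq(qty, curve, sdCq = 0)
        expect_equal(quantifyCq(cq, curve)$quantity, qty, tolerance = 1e-6)
    }
    # with noise, triplicate quantification stays close on the log scale
    cq <- generateQpcrCq(1000, curve, sdCq = 0.1, replicates = 3, seed = 2)
    expect_lt(abs(log10(quantifyCq(cq, curve)$quantity) - 3), 0.1)
})
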