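perfectCurve <- function() standardCurve(-3.3219, 40)

test_that("simulated Cq values follow the calibration line", {
    curve <- perfectCurve()
    expect_equal(generateQpcrCq(1, curve, sdCq = 0, replicates = 3),
                 rep(40, 3))
    expect_equal(generateQpcrCq(100, curve, sdCq = 0, replicates = 1),
                 40 - 3.3219 * 2)
    # technical noise has the configured SD (normal sampling oracle)
    cq <- generateQpcrCq(100, curve, sdCq = 0.2, replicates = 1000, seed = 4)
    seOfSd <- 0.2 / sqrt(2 * 1000)
    expect_lt(abs(sd(cq) - 0.2), 3 * seOfSd)
    expect_error(generateQpcrCq(0, curve), "quantity")
})

test_that("standard-curve fitting recovers slope, efficiency and R^2", {
    q <- rep(10^(0:4), each = 3)
    fit <- fitStandardCurve(q, 40 - 3.3219 * log10(q))
    expect_equal(fit@slope, -3.3219, tolerance = 1e-9)
    expect_equal(fit@intercept, 40, tolerance = 1e-9)
    expect_equal(fit@efficiency, 1, tolerance = 1e-4)  # perfect doubling
    expect_equal(fit@rSquared, 1)
    # two-point slope arithmetic
    two <- fitStandardCurve(c(10, 100), c(30.00, 26.68))
    expect_equal(two@slope, -3.32, tolerance = 1e-9)
    expect_error(fitStandardCurve(c(10, 10), c(30, 30.1)), "distinct")
    expect_error(fitStandardCurve(c(0, 10), c(30, 27)), "> 0")
    # efficiency is monotone in slope: a -3.6 slope is a sub-100% assay
    expect_lt(standardCurve(-3.6, 40)@efficiency, 1)
})

test_that("quantification inverts the standard curve", {
    curve <- perfectCurve()
    expect_equal(quantifyCq(40, curve)$quantity, 1)
    expect_equal(quantifyCq(33.3562, curve)$quantity, 100, tolerance = 1e-4)
    res <- quantifyCq(c(33.30, 33.36, 33.41), curve)
    expect_equal(res$meanCq, mean(c(33.30, 33.36, 33.41)))
    expect_equal(res$n, 3L)
})

test_that("quantify after generate is the identity at zero noise", {
    for (slope in c(-3.3219, -3.6, -3.1)) {
        curve <- standardCurve(slope, 38)
        for (qty in c(0.5, 1, 100, 1e5)) {
            cq <- generateQpcrCq(qty, curve, sdCq = 0)
            expect_equal(quantifyCq(cq, curve)$quantity, qty,
                         tolerance = 1e-6)
        }
    }
})

test_that("plasma concentration scaling is dimensionally correct", {
    # 1 ng in 4 uL of an 80 uL eluate from 200 uL plasma -> 100 ng/mL
    expect_equal(toPlasmaConcentration(1, templateUl = 4), 100)
    # template = eluate and 1 mL plasma: concentration equals the quantity
    expect_equal(toPlasmaConcentration(7, templateUl = 80, eluateUl = 80,
                                       plasmaUl = 1000), 7)
    expect_equal(toPlasmaConcentration(0, templateUl = 4), 0)
    expect_error(toPlasmaConcentration(1, templateUl = 0), "templateUl")
})

test_that("DNA integrity index is the long/short concentration ratio", {
    expect_equal(dnaIntegrityIndex(0.5, 0.5), 1)
    expect_equal(dnaIntegrityIndex(0.2, 0.8), 0.25)
    expect_error(dnaIntegrityIndex(0.2, 0), "> 0")
    # unfragmented mitochondrial DNA: every molecule exceeds the 310-bp
    # amplicon, so the noise-free index is exactly 1
    lens <- seq(350, 16000, by = 50)
    dii <- dnaIntegrityIndex(ampliconDetectableFraction(lens, 310),
                             ampliconDetectableFraction(lens, 67))
    expect_equal(dii, 1)
})

test_that("mass-to-copy conversion matches molar-mass arithmetic", {
    expect_equal(copiesPerMl(1, 16569), 5.507e7, tolerance = 1e-3)
    expect_equal(copiesPerMl(1, 3.2e9), 285.1, tolerance = 1e-3)
    expect_equal(copiesPerMl(0, 16569), 0)
})

test_that("panel quantification yields per-genome concentrations and DII", {
    curve <- perfectCurve()
    curves <- list("KRAS-67" = curve, "KRAS-320" = curve,
                   "MT-CO3-67" = curve, "MT-CO3-310" = curve)
    qty <- c("KRAS-67" = 400, "KRAS-320" = 100,
             "MT-CO3-67" = 5000, "MT-CO3-310" = 4800)
    cqTable <- do.call(rbind, lapply(names(qty), function(t)
        data.frame(sample_id = "s1", target = t,
                   cq = generateQpcrCq(qty[[t]], curve, sdCq = 0))))
    res <- quantifyPanel(cqTable, curves, templateUl = 4)
    q <- res$quantifications
    expect_equal(q$quantity[match(names(qty), q$target)], unname(qty),
                 tolerance = 1e-6)
    expect_equal(q$concentration, toPlasmaConcentration(q$quantity, 4))
    dii <- res$dii
    expect_equal(dii$dii[dii$genome == "nuclear"], 100 / 400,
                 tolerance = 1e-6)
    expect_equal(dii$dii[dii$genome == "mitochondrial"], 4800 / 5000,
                 tolerance = 1e-6)
    expect_error(quantifyPanel(cqTable, curves[1:3], templateUl = 4),
                 "missing standard curve")
})
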