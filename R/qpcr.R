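#' qPCR target panel for nuclear and mitochondrial quantification
#'
#' The amplicon panel used throughout: a short and a long amplicon per
#' genome, on single-copy regions of the nuclear genome (KRAS wild-type
#' sequence, 67 and 320 bp) and the mitochondrial genome (MT-CO3, 67 and
#' 310 bp). The short amplicon measures total target DNA; the long/short
#' concentration ratio is the DNA Integrity Index (see
#' [dnaIntegrityIndex()]).
#'
#' @return data.frame with columns `target`, `genome`, `amplicon_length`.
#' @export
qpcrTargets <- function() {
    data.frame(
        target = c("KRAS-67", "KRAS-320", "MT-CO3-67", "MT-CO3-310"),
        genome = c("nuclear", "nuclear", "mitochondrial", "mitochondrial"),
        amplicon_length = c(67L, 320L, 67L, 310L),
        stringsAsFactors = FALSE
    )
}

#' Construct a standard curve from known coefficients
#'
#' @param slope Cq per log10(quantity); must be negative.
#' @param intercept Cq at quantity 1.
#' @param rSquared optional fit R^2.
#' @return A [StandardCurve-class]; efficiency is `10^(-1/slope) - 1`.
#' @examples
#' standardCurve(-1 / log10(2), 40)    # 100% efficient assay
#' @export
standardCurve <- function(slope, intercept, rSquared = NA_real_) {
    .assertScalarNumber(slope, "slope")
    .assertScalarNumber(intercept, "intercept")
    new("StandardCurve", slope = slope, intercept = intercept,
        efficiency = 10^(-1 / slope) - 1, rSquared = rSquared)
}

#' Fit a qPCR standard curve from a dilution series
#'
#' Least-squares fit of Cq against log10(quantity) over a calibration
#' dilution series (e.g. genomic DNA from a reference cell line).
#'
#' @param quantity known input quantities per reaction (> 0); at least two
#'   distinct values.
#' @param cq measured Cq values, parallel to `quantity`.
#' @return A [StandardCurve-class] with slope, intercept, efficiency and R^2.
#' @examples
#' q <- rep(10^(0:4), each = 3)
#' fitStandardCurve(q, 40 - 3.3219 * log10(q))
#' @export
fitStandardCurve <- function(quantity, cq) {
    if (length(quantity) != length(cq))
        stop("'quantity' and 'cq' must have the same length")
    if (any(quantity <= 0)) stop("quantities must be > 0")
    if (length(unique(quantity)) < 2L)
        stop("at least two distinct quantities are required")
    fit <- stats::lm(cq ~ log10(quantity))
    co <- unname(stats::coef(fit))
    # direct R^2: summary.lm warns on the zero-residual fits that exact
    # synthetic dilution series produce
    ssTot <- sum((cq - mean(cq))^2)
    r2 <- if (ssTot > 0) 1 - sum(stats::residuals(fit)^2) / ssTot
          else NA_real_
    standardCurve(slope = co[2L], intercept = co[1L], rSquared = r2)
}

#' Simulate replicate Cq measurements for a known quantity
#'
#' Inverse of [quantifyCq()]: generates Cq values from the calibration line
#' `Cq = intercept + slope * log10(quantity)` plus Gaussian technical noise,
#' emulating a triplicate qPCR measurement.
#'
#' @param quantity true quantity per reaction (> 0).
#' @param curve a [StandardCurve-class].
#' @param sdCq technical standard deviation in Cq units (>= 0).
#' @param replicates number of replicate wells (default triplicate).
#' @param seed integer seed.
#' @return Numeric vector of `replicates` Cq values.
#' @export
generateQpcrCq <- function(quantity, curve, sdCq = 0, replicates = 3,
                           seed = NULL) {
    .assertScalarNumber(quantity, "quantity", positive = TRUE)
    .assertScalarNumber(sdCq, "sdCq", nonneg = TRUE)
    .assertScalarNumber(replicates, "replicates", positive = TRUE)
    stopifnot(is(curve, "StandardCurve"))
    mu <- curve@intercept + curve@slope * log10(quantity)
    withSeed(seed, mu + stats::rnorm(as.integer(replicates), 0, sdCq))
}

#' Quantify a sample from replicate Cq values
#'
#' Replicates are summarised by their mean Cq (not by averaging back-
#' transformed quantities), then inverted through the standard curve:
#' `quantity = 10^((meanCq - intercept) / slope)`.
#'
#' @param cq replicate Cq values (>= 1).
#' @param curve a [StandardCurve-class].
#' @return List with `quantity` (per reaction), `meanCq`, `sdCq` (NA for a
#'   single replicate) and `n`.
#' @examples
#' curve <- standardCurve(-3.3219, 40)
#' quantifyCq(c(33.30, 33.36, 33.41), curve)$quantity   # ~100 copies
#' @export
quantifyCq <- function(cq, curve) {
    stopifnot(is(curve, "StandardCurve"))
    if (length(cq) < 1L) stop("at least one Cq value is required")
    if (curve@slope == 0) stop("curve slope must be non-zero")
    m <- mean(cq)
    list(quantity = 10^((m - curve@intercept) / curve@slope),
         meanCq = m,
         sdCq = if (length(cq) > 1L) stats::sd(cq) else NA_real_,
         n = length(cq))
}

#' Convert a per-reaction quantity to a plasma concentration
#'
#' Scales the amount measured in one reaction back through the extraction:
#' the reaction contains `templateUl` of an eluate of `eluateUl` derived
#' from `plasmaUl` of plasma, so
#' `concentration = quantity * (eluateUl / templateUl) / (plasmaUl / 1000)`
#' per mL of plasma. With `quantity` in ng the result is ng/mL; with copies,
#' copies/mL.
#'
#' @param quantity amount per reaction (>= 0).
#' @param templateUl eluate volume pipetted into the reaction (uL, > 0).
#' @param eluateUl extraction elution volume (uL; default 80).
#' @param plasmaUl plasma volume extracted (uL; default 200).
#' @return Concentration per mL plasma.
#' @examples
#' toPlasmaConcentration(1, templateUl = 4)   # 100 (ng/mL if quantity in ng)
#' @export
toPlasmaConcentration <- function(quantity, templateUl, eluateUl = 80,
                                  plasmaUl = 200) {
    .assertScalarNumber(templateUl, "templateUl", positive = TRUE)
    .assertScalarNumber(eluateUl, "eluateUl", positive = TRUE)
    .assertScalarNumber(plasmaUl, "plasmaUl", positive = TRUE)
    if (any(quantity < 0)) stop("quantity must be >= 0")
    quantity * (eluateUl / templateUl) / (plasmaUl / 1000)
}

#' DNA Integrity Index
#'
#' Ratio of the concentration measured with the long amplicon to the
#' concentration measured with the short amplicon of the same target
#' (nuclear: 320/67 bp; mitochondrial: 310/67 bp). Intact DNA amplifies
#' equally with both and gives an index near 1; fragmentation below the
#' long-amplicon size depresses the index toward 0. Also used as a blood
#' cell DNA contamination check in pre-analytics.
#'
#' @param concLong concentration from the long amplicon (>= 0).
#' @param concShort concentration from the short amplicon (> 0).
#' @return Dimensionless ratio `concLong / concShort`.
#' @export
dnaIntegrityIndex <- function(concLong, concShort) {
    if (any(concShort <= 0))
        stop("short-amplicon concentration must be > 0")
    if (any(concLong < 0)) stop("concentrations must be >= 0")
    concLong / concShort
}

#' Fraction of fragments long enough to amplify
#'
#' Detection model linking fragment populations to qPCR: a fragment
#' contributes to an amplicon's signal iff its length is at least the
#' amplicon length. The long/short detectable-fraction ratio of a fragment
#' population is its expected noise-free DNA Integrity Index.
#'
#' @param lengths fragment lengths (bp or nt).
#' @param ampliconLength amplicon size in bp (> 0).
#' @return Fraction of fragments with `length >= ampliconLength`.
#' @examples
#' lens <- c(50, 100, 200, 400)
#' ampliconDetectableFraction(lens, 67)    # 0.75
#' ampliconDetectableFraction(lens, 310)   # 0.25
#' @export
ampliconDetectableFraction <- function(lengths, ampliconLength) {
    .assertScalarNumber(ampliconLength, "ampliconLength", positive = TRUE)
    if (!length(lengths)) stop("'lengths' must not be empty")
    mean(lengths >= ampliconLength)
}

#' Convert a mass concentration to genome copies per mL
#'
#' `copies = conc * 1e-9 / (genomeLengthBp * massPerBp) * N_A`, with the
#' default 660 g/mol per base pair of double-stranded DNA. Defaults for the
#' genome lengths: 16,569 bp (human mitochondrial genome) and 3.2e9 bp
#' (haploid human nuclear genome).
#'
#' @param concNgPerMl concentration in ng per mL (>= 0).
#' @param genomeLengthBp genome (or target) length in bp (> 0).
#' @param massPerBp molar mass per base pair, g/mol (default 660).
#' @return Copies per mL.
#' @examples
#' copiesPerMl(1, genomeLengthBp = 16569)   # ~5.5e7 mitochondrial copies
#' copiesPerMl(1, genomeLengthBp = 3.2e9)   # ~285 nuclear copies
#' @export
copiesPerMl <- function(concNgPerMl, genomeLengthBp, massPerBp = 660) {
    .assertScalarNumber(genomeLengthBp, "genomeLengthBp", positive = TRUE)
    .assertScalarNumber(massPerBp, "massPerBp", positive = TRUE)
    if (any(concNgPerMl < 0)) stop("concentration must be >= 0")
    avogadro <- 6.02214076e23
    concNgPerMl * 1e-9 / (genomeLengthBp * massPerBp) * avogadro
}

#' Quantify a multi-target Cq table against standard curves
#'
#' Batch front-end over [quantifyCq()], [toPlasmaConcentration()] and
#' [dnaIntegrityIndex()]: takes a long-format Cq table (one row per well)
#' and a named list of standard curves, and returns per-sample, per-target
#' plasma concentrations plus the per-genome DNA Integrity Index where both
#' amplicons of a genome's pair are present.
#'
#' @param cqTable data.frame with columns `sample_id`, `target`, `cq`
#'   (replicate wells are additional rows).
#' @param curves named list of [StandardCurve-class], one per target.
#' @param templateUl,eluateUl,plasmaUl extraction volumes, see
#'   [toPlasmaConcentration()].
#' @param targets amplicon panel table (default [qpcrTargets()]).
#' @return List with `quantifications` (data.frame: sample_id, target,
#'   genome, quantity, concentration, mean_cq, sd_cq, n) and `dii`
#'   (data.frame: sample_id, genome, dii).
#' @export
quantifyPanel <- function(cqTable, curves, templateUl, eluateUl = 80,
                          plasmaUl = 200, targets = qpcrTargets()) {
    need <- c("sample_id", "target", "cq")
    if (!all(need %in% names(cqTable)))
        stop("cqTable must have columns: ", paste(need, collapse = ", "))
    if (!all(cqTable$target %in% names(curves)))
        stop("missing standard curve for target(s): ",
             paste(setdiff(unique(cqTable$target), names(curves)),
                   collapse = ", "))
    groups <- split(cqTable, list(cqTable$sample_id, cqTable$target),
                    drop = TRUE)
    rows <- lapply(groups, function(g) {
        q <- quantifyCq(g$cq, curves[[g$target[1L]]])
        data.frame(
            sample_id = g$sample_id[1L], target = g$target[1L],
            genome = targets$genome[match(g$target[1L], targets$target)],
            quantity = q$quantity,
            concentration = toPlasmaConcentration(q$quantity, templateUl,
                                                  eluateUl, plasmaUl),
            mean_cq = q$meanCq, sd_cq = q$sdCq, n = q$n,
            stringsAsFactors = FALSE
        )
    })
    quant <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

    short <- targets$target[targets$amplicon_length < 100]
    diiRows <- lapply(split(quant, list(quant$sample_id, quant$genome),
                            drop = TRUE), function(g) {
        s <- g$concentration[g$target %in% short]
        l <- g$concentration[!g$target %in% short]
        if (length(s) == 1L && length(l) == 1L && s > 0)
            data.frame(sample_id = g$sample_id[1L], genome = g$genome[1L],
                       dii = dnaIntegrityIndex(l, s),
                       stringsAsFactors = FALSE)
        else NULL
    })
    dii <- do.call(rbind, c(diiRows, list(make.row.names = FALSE)))
    list(quantifications = quant, dii = dii)
}
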