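#' @import methods
NULL

## Size window shared by every profile: the practical read-out limits of
## low-pass WGS fragmentometry (30 bp lower, ~1,000 bp upper).
.SIZE_MIN <- 30L
.SIZE_MAX <- 1000L

#' Sizes covered by every fragment-size profile
#'
#' Profiles are 1-bp histograms over the inclusive window 30--1,000 bp (nt),
#' the detection limits of low-pass whole-genome fragment-size analysis.
#'
#' @return Integer vector `30:1000`.
#' @export
profileSizes <- function() seq.int(.SIZE_MIN, .SIZE_MAX)

#' SizeProfile: a 1-bp fragment-size frequency profile
#'
#' Per-size read counts and relative frequencies over the inclusive
#' 30--1,000 bp (nt) window for one sample (or a mean across samples),
#' one genome compartment (nuclear or mitochondrial) and one library
#' chemistry (DSP, double-strand preparation, sizes in bp; SSP,
#' single-strand preparation, sizes in nt).
#'
#' @slot sampleId character scalar.
#' @slot genome `"nuclear"` or `"mitochondrial"`.
#' @slot library `"DSP"` or `"SSP"`.
#' @slot unit `"bp"` (DSP) or `"nt"` (SSP).
#' @slot counts numeric vector of per-size read counts, named `"30"`..`"1000"`.
#' @slot frequency per-size relative frequency; sums to 1 when any read
#'   falls in the window.
#' @slot totalReads total in-window reads (sum of `counts`).
#'
#' @export
setClass("SizeProfile",
    representation(
        sampleId  = "character",
        genome    = "character",
        library   = "character",
        unit      = "character",
        counts    = "numeric",
        frequency = "numeric",
        totalReads = "numeric"
    )
)

setValidity("SizeProfile", function(object) {
    msg <- NULL
    nsz <- .SIZE_MAX - .SIZE_MIN + 1L
    if (length(object@counts) != nsz || length(object@frequency) != nsz)
        msg <- c(msg, sprintf("counts/frequency must cover %d..%d (one bin per bp)",
                              .SIZE_MIN, .SIZE_MAX))
    if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
    if (!object@genome %in% c("nuclear", "mitochondrial"))
        msg <- c(msg, "genome must be 'nuclear' or 'mitochondrial'")
    if (!object@library %in% c("DSP", "SSP"))
        msg <- c(msg, "library must be 'DSP' or 'SSP'")
    if (!object@unit %in% c("bp", "nt"))
        msg <- c(msg, "unit must be 'bp' or 'nt'")
    if (object@totalReads > 0 &&
        abs(sum(object@frequency) - 1) > 1e-9)
        msg <- c(msg, "frequency must sum to 1 over the window")
    if (abs(object@totalReads - sum(object@counts)) > 1e-6 * max(1, object@totalReads))
        msg <- c(msg, "totalReads must equal sum(counts)")
    if (is.null(msg)) TRUE else msg
})

#' MixtureConfig: a banded fragment-length mixture
#'
#' Specifies the empirical fragment-length simulator as an ordered set of
#' non-overlapping bands, each carrying a probability mass (`weight`), a
#' within-band shape (asymmetric Laplace around a modal size, triangular, or
#' uniform) and optionally a "comb" of point masses emulating the 10-bp
#' nucleosomal sub-peaks seen in nuclear profiles.
#'
#' @slot genome `"nuclear"` or `"mitochondrial"`.
#' @slot library `"DSP"` or `"SSP"`.
#' @slot bands data.frame with one row per band; see [mixtureBand()].
#'
#' @seealso [defaultMixtureConfig()] for the calibrated defaults,
#'   [sampleFragmentLengths()] to draw fragments.
#' @export
setClass("MixtureConfig",
    representation(
        genome  = "character",
        library = "character",
        bands   = "data.frame"
    )
)

setValidity("MixtureConfig", function(object) {
    b <- object@bands
    msg <- NULL
    need <- c("lo", "hi", "weight", "shape", "mode",
              "scale_left", "scale_right", "comb_pos", "comb_mass")
    if (!all(need %in% names(b)))
        return(paste("bands must have columns:", paste(need, collapse = ", ")))
    if (nrow(b) == 0L) msg <- c(msg, "at least one band required")
    if (any(b$lo < .SIZE_MIN) || any(b$hi > .SIZE_MAX) || any(b$lo > b$hi))
        msg <- c(msg, sprintf("bands must satisfy %d <= lo <= hi <= %d",
                              .SIZE_MIN, .SIZE_MAX))
    if (any(b$weight < 0)) msg <- c(msg, "band weights must be non-negative")
    if (sum(b$weight) <= 0) msg <- c(msg, "band weights must not all be zero")
    if (nrow(b) > 1L) {
        o <- order(b$lo)
        if (any(b$lo[o][-1L] <= b$hi[o][-nrow(b)]))
            msg <- c(msg, "bands must not overlap")
    }
    tri_al <- b$shape %in% c("asymmetric-laplace", "triangular")
    if (any(tri_al & (is.na(b$mode) | b$mode < b$lo | b$mode > b$hi)))
        msg <- c(msg, "mode must lie within [lo, hi]")
    for (i in seq_len(nrow(b))) {
        cp <- b$comb_pos[[i]]
        if (length(cp)) {
            if (any(cp < b$lo[i] | cp > b$hi[i]))
                msg <- c(msg, "comb positions must lie within their band")
            if (length(cp) * b$comb_mass[i] > b$weight[i])
                msg <- c(msg, "total comb mass may not exceed the band weight")
        }
    }
    if (!object@genome %in% c("nuclear", "mitochondrial"))
        msg <- c(msg, "genome must be 'nuclear' or 'mitochondrial'")
    if (!object@library %in% c("DSP", "SSP"))
        msg <- c(msg, "library must be 'DSP' or 'SSP'")
    if (is.null(msg)) TRUE else msg
})

#' MoleculeSet: jagged, possibly nicked duplex DNA molecules
#'
#' A vectorised container for simulated circulating DNA duplexes. Each
#' molecule is a duplex of span `span(m)` bp whose top and bottom strands may
#' be recessed at either end (jagged ends) and may carry internal
#' single-strand breaks (nicks). All coordinates are duplex coordinates in
#' `[0, span]`; nick positions lie strictly inside the owning strand.
#'
#' @slot span duplex span in bp.
#' @slot topStart,topEnd,botStart,botEnd strand extents (duplex coordinates).
#' @slot nicksTop,nicksBottom list of sorted nick positions per molecule.
#'
#' @seealso [simulateMolecules()], [dspObserve()], [sspObserve()]
#' @export
setClass("MoleculeSet",
    representation(
        span        = "numeric",
        topStart    = "numeric",
        topEnd      = "numeric",
        botStart    = "numeric",
        botEnd      = "numeric",
        nicksTop    = "list",
        nicksBottom = "list"
    )
)

setValidity("MoleculeSet", function(object) {
    n <- length(object@span)
    msg <- NULL
    if (any(vapply(list(object@topStart, object@topEnd, object@botStart,
                        object@botEnd), length, 0L) != n) ||
        length(object@nicksTop) != n || length(object@nicksBottom) != n)
        return("all slots must have one entry per molecule")
    if (any(object@span < 1)) msg <- c(msg, "spans must be >= 1 bp")
    ok_extent <- object@topStart >= 0 & object@topEnd <= object@span &
        object@botStart >= 0 & object@botEnd <= object@span &
        object@topStart <= object@topEnd & object@botStart <= object@botEnd
    if (!all(ok_extent)) msg <- c(msg, "strand extents must lie within [0, span]")
    overlap <- pmin(object@topEnd, object@botEnd) -
        pmax(object@topStart, object@botStart)
    if (any(overlap < 1)) msg <- c(msg, "strands must overlap by >= 1 bp (duplex)")
    for (i in seq_len(n)) {
        nt <- object@nicksTop[[i]]; nb <- object@nicksBottom[[i]]
        if (length(nt) && (is.unsorted(nt) || any(nt <= object@topStart[i]) ||
                           any(nt >= object@topEnd[i])))
            msg <- c(msg, "top-strand nicks must be sorted, strictly inside the strand")
        if (length(nb) && (is.unsorted(nb) || any(nb <= object@botStart[i]) ||
                           any(nb >= object@botEnd[i])))
            msg <- c(msg, "bottom-strand nicks must be sorted, strictly inside the strand")
    }
    if (is.null(msg)) TRUE else unique(msg)
})

#' StandardCurve: a fitted qPCR calibration line
#'
#' Cq as a linear function of log10(quantity). A perfectly efficient assay
#' doubles each cycle, giving slope -1/log10(2) = -3.3219 and efficiency
#' 100%; efficiency is `10^(-1/slope) - 1`.
#'
#' @slot slope Cq change per log10(quantity); negative for a valid assay.
#' @slot intercept Cq at quantity 1.
#' @slot efficiency amplification efficiency as a fraction (1 = 100%).
#' @slot rSquared coefficient of determination of the fit (NA if constructed
#'   directly).
#'
#' @seealso [fitStandardCurve()], [quantifyCq()], [generateQpcrCq()]
#' @export
setClass("StandardCurve",
    representation(
        slope      = "numeric",
        intercept  = "numeric",
        efficiency = "numeric",
        rSquared   = "numeric"
    )
)

setValidity("StandardCurve", function(object) {
    msg <- NULL
    if (length(object@slope) != 1L || length(object@intercept) != 1L)
        msg <- c(msg, "slope and intercept must be scalars")
    if (!is.na(object@slope) && object@slope >= 0)
        msg <- c(msg, "slope must be negative for a valid assay")
    if (is.null(msg)) TRUE else msg
})

#' PrepSeries: supernatant measurements along a plasma-preparation protocol
#'
#' An ordered sequence of physical steps (centrifugation at a given g-force,
#' 0.22-um filtration, freezing) with the supernatant DNA signal measured
#' after each step, possibly in replicate. The reference step names the
#' supernatant whose signal is the denominator for remaining-fraction
#' calculations.
#'
#' @slot genome `"nuclear"` or `"mitochondrial"`.
#' @slot steps data.frame with columns `label`, `type`
#'   (`centrifuge`/`filter`/`freeze`) and `value` (g-force or pore size in um;
#'   NA for freeze).
#' @slot measurements numeric matrix, one row per step, one column per
#'   replicate.
#' @slot unit measurement unit, e.g. `"ng/mL"` or `"copies/mL"`.
#' @slot referenceStep label of the reference supernatant.
#'
#' @seealso [simulatePlasmaPrep()], [supernatantFractions()], [inferPartition()]
#' @export
setClass("PrepSeries",
    representation(
        genome        = "character",
        steps         = "data.frame",
        measurements  = "matrix",
        unit          = "character",
        referenceStep = "character"
    )
)

setValidity("PrepSeries", function(object) {
    msg <- NULL
    if (!all(c("label", "type", "value") %in% names(object@steps)))
        return("steps must have columns label, type, value")
    if (nrow(object@steps) < 1L) msg <- c(msg, "at least one step required")
    if (nrow(object@measurements) != nrow(object@steps))
        msg <- c(msg, "one measurement row per step required")
    if (any(object@measurements < 0, na.rm = TRUE))
        msg <- c(msg, "measurements must be non-negative")
    if (!all(object@steps$type %in% c("centrifuge", "filter", "freeze")))
        msg <- c(msg, "step types must be centrifuge, filter or freeze")
    if (anyDuplicated(object@steps$label))
        msg <- c(msg, "step labels must be unique")
    if (!object@referenceStep %in% object@steps$label)
        msg <- c(msg, "referenceStep must be one of the step labels")
    if (is.null(msg)) TRUE else msg
})

#' PartitionEstimate: repartition of circulating DNA across structural classes
#'
#' Per-class fractions of the reference-supernatant DNA amount removed at
#' each successive physical step, plus the residual still in the final
#' supernatant. Fractions and residual sum to 1.
#'
#' @slot fractions named numeric, one fraction per structural class.
#' @slot residual fraction remaining in the last supernatant.
#' @slot referenceStep label of the reference step used as denominator.
#'
#' @seealso [inferPartition()]
#' @export
setClass("PartitionEstimate",
    representation(
        fractions     = "numeric",
        residual      = "numeric",
        referenceStep = "character"
    )
)

setValidity("PartitionEstimate", function(object) {
    msg <- NULL
    if (any(object@fractions < -1e-9) || any(object@fractions > 1 + 1e-9))
        msg <- c(msg, "fractions must lie in [0, 1]")
    tot <- sum(object@fractions) + object@residual
    if (abs(tot - 1) > 1e-9)
        msg <- c(msg, "fractions + residual must sum to 1")
    if (is.null(msg)) TRUE else msg
})
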