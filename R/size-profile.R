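#' Build a 1-bp fragment-size frequency profile
#'
#' Tallies fragment lengths into exact 1-bp bins over the inclusive
#' 30--1,000 bp (nt) window and normalises by the in-window total, so
#' frequencies are the ratio of reads at each size to all reads between 30
#' and 1,000. Lengths outside the window are excluded from both numerator
#' and denominator. No smoothing is applied anywhere: all downstream
#' statistics work on the raw 1-bp histogram.
#'
#' @param x fragment lengths: a numeric vector, or a fragment-record
#'   data.frame with a `length` column (as produced by
#'   [sampleFragmentLengths()], [readInsertSizes()] or [readFragmentTsv()]).
#' @param sampleId,genome,library profile metadata; taken from the record
#'   table when unambiguous there and omitted here.
#'
#' @return A [SizeProfile-class].
#' @examples
#' p <- buildProfile(c(100, 100, 200, 500), "ex", "nuclear", "DSP")
#' profileFrequency(p)[c("100", "200", "500")]   # 0.50 0.25 0.25
#' @export
buildProfile <- function(x, sampleId = NULL, genome = NULL, library = NULL) {
    if (is.data.frame(x)) {
        if (!"length" %in% names(x))
            stop("record data.frame must have a 'length' column")
        infer <- function(given, col) {
            if (!is.null(given)) return(given)
            v <- unique(x[[col]])
            if (length(v) != 1L)
                stop("'", col, "' is not unique in the records; pass it explicitly")
            v
        }
        sampleId <- infer(sampleId, "sample_id")
        genome <- infer(genome, "genome")
        library <- infer(library, "library")
        x <- x$length
    }
    if (is.null(sampleId) || is.null(genome) || is.null(library))
        stop("sampleId, genome and library are required for length vectors")
    genome <- .matchGenome(genome)
    library <- .matchLibrary(library)
    lens <- round(as.numeric(x))
    lens <- lens[!is.na(lens) & lens >= .SIZE_MIN & lens <= .SIZE_MAX]
    if (!length(lens))
        stop("no fragments inside the 30..1000 window; profile undefined")
    counts <- as.numeric(tabulate(lens - .SIZE_MIN + 1L,
                                  nbins = .SIZE_MAX - .SIZE_MIN + 1L))
    names(counts) <- profileSizes()
    new("SizeProfile", sampleId = as.character(sampleId), genome = genome,
        library = library, unit = .unitFor(library), counts = counts,
        frequency = counts / sum(counts), totalReads = sum(counts))
}

#' Average size profiles across samples
#'
#' The mean profile weights each sample equally: per-size frequencies are
#' the unweighted mean of the per-sample frequencies (then renormalised),
#' not a pooled recount -- a deep sample does not dominate the mean.
#'
#' @param profiles list of [SizeProfile-class] with identical genome,
#'   library and unit.
#' @param sampleId identifier for the mean profile.
#' @return A [SizeProfile-class] whose `totalReads` is the summed depth.
#' @export
meanProfile <- function(profiles, sampleId = "mean") {
    if (is(profiles, "SizeProfile")) profiles <- list(profiles)
    if (!length(profiles)) stop("at least one profile is required")
    stopifnot(all(vapply(profiles, is, TRUE, "SizeProfile")))
    meta <- vapply(profiles, function(p)
        c(p@genome, p@library, p@unit), character(3))
    if (any(apply(meta, 1L, function(v) length(unique(v))) != 1L))
        stop("profiles must share genome, library and unit")
    fmat <- vapply(profiles, profileFrequency,
                   numeric(.SIZE_MAX - .SIZE_MIN + 1L))
    freq <- rowMeans(fmat)
    freq <- freq / sum(freq)
    total <- sum(vapply(profiles, totalReads, 0))
    counts <- freq * total
    names(counts) <- names(freq) <- profileSizes()
    new("SizeProfile", sampleId = sampleId, genome = meta[1L, 1L],
        library = meta[2L, 1L], unit = meta[3L, 1L], counts = counts,
        frequency = freq, totalReads = total)
}

#' Fraction of fragments inside a size band
#'
#' Sum of profile frequencies over the inclusive band `[lo, hi]` -- e.g.
#' the mono-nucleosomal 90--260 bp band of mitochondrial DSP profiles.
#'
#' @param profile a [SizeProfile-class].
#' @param lo,hi inclusive band bounds within 30..1000, `lo <= hi`.
#' @return Band fraction in `[0, 1]`.
#' @examples
#' p <- buildProfile(c(100, 100, 200, 500), "ex", "nuclear", "DSP")
#' bandFraction(p, 90, 260)   # 0.75
#' @export
bandFraction <- function(profile, lo, hi) {
    stopifnot(is(profile, "SizeProfile"))
    if (lo > hi) stop("inverted band bounds: lo > hi")
    if (lo < .SIZE_MIN || hi > .SIZE_MAX)
        stop(sprintf("band must lie within [%d, %d]", .SIZE_MIN, .SIZE_MAX))
    sizes <- profileSizes()
    sum(profile@frequency[sizes >= lo & sizes <= hi])
}

#' Modal fragment size
#'
#' The size with maximal frequency; ties break toward the smallest size so
#' the result is deterministic.
#'
#' @param profile a [SizeProfile-class].
#' @return Modal size in bp (nt).
#' @export
modalSize <- function(profile) {
    stopifnot(is(profile, "SizeProfile"))
    profileSizes()[which.max(profile@frequency)]
}

#' Short/long fragment frequency ratio
#'
#' Ratio of the frequency of fragments strictly below `shortBelow` to the
#' frequency strictly above `longAbove` (defaults 90 and 200 bp/nt). This
#' ratio separates library chemistries sharply: double-strand preparations
#' barely see the short single-stranded material that single-strand
#' preparations recover.
#'
#' @param profile a [SizeProfile-class].
#' @param shortBelow,longAbove thresholds, exclusive on both sides.
#' @return The ratio, or `NA` (flagged, not an error) when no fragment lies
#'   above `longAbove`.
#' @examples
#' p <- buildProfile(c(80, 80, 250, 300), "ex", "mitochondrial", "DSP")
#' shortLongRatio(p)   # 1
#' @export
shortLongRatio <- function(profile, shortBelow = 90, longAbove = 200) {
    stopifnot(is(profile, "SizeProfile"))
    if (shortBelow <= .SIZE_MIN || longAbove >= .SIZE_MAX)
        stop("thresholds must lie inside the 30..1000 window")
    sizes <- profileSizes()
    num <- sum(profile@frequency[sizes < shortBelow])
    den <- sum(profile@frequency[sizes > longAbove])
    if (den == 0) return(NA_real_)
    num / den
}

#' 10-bp periodicity score
#'
#' Detects the 10-bp nucleosomal sub-peak comb of nuclear profiles: the
#' mean, over the listed peak positions, of the excess of the frequency at
#' the peak over the average frequency at the two half-spacing (+/- 5 bp)
#' neighbours. Zero for any locally linear (e.g. uniform) profile; positive
#' when the comb is present.
#'
#' @param profile a [SizeProfile-class].
#' @param positions expected peak positions (default the nuclear DSP comb
#'   102, 112, ..., 152 bp).
#' @param spacing peak spacing in bp; neighbours sit at +/- `spacing / 2`.
#' @return Dimensionless score; positive means 10-bp combing present.
#' @export
periodicityScore <- function(profile, positions = seq(102L, 152L, 10L),
                             spacing = 10L) {
    stopifnot(is(profile, "SizeProfile"))
    half <- spacing / 2
    if (any(positions - half < .SIZE_MIN | positions + half > .SIZE_MAX))
        stop("positions and their half-spacing neighbours must lie in the window")
    f <- profile@frequency
    at <- function(p) f[as.character(p)]
    mean(at(positions) - (at(positions - half) + at(positions + half)) / 2)
}

#' Shift a profile along the size axis
#'
#' Moves every count by `offset` sizes (positive = toward larger sizes);
#' counts shifted outside the 30..1000 window are dropped and frequencies
#' renormalised. Used to overlay single-strand profiles on double-strand
#' profiles, whose end-repair step extends fragments by ~3 bp.
#'
#' @param profile a [SizeProfile-class].
#' @param offset integer shift in bp (nt).
#' @return A shifted [SizeProfile-class].
#' @export
shiftProfile <- function(profile, offset) {
    stopifnot(is(profile, "SizeProfile"))
    offset <- as.integer(offset)
    if (offset == 0L) return(profile)
    sizes <- profileSizes()
    counts <- numeric(length(sizes))
    names(counts) <- sizes
    newSizes <- sizes + offset
    ok <- newSizes >= .SIZE_MIN & newSizes <= .SIZE_MAX
    counts[as.character(newSizes[ok])] <- profile@counts[ok]
    if (sum(counts) == 0)
        stop("shift moved every fragment outside the 30..1000 window")
    new("SizeProfile", sampleId = profile@sampleId, genome = profile@genome,
        library = profile@library, unit = profile@unit, counts = counts,
        frequency = counts / sum(counts), totalReads = sum(counts))
}

#' Compare DSP and SSP profiles of the same genome
#'
#' Quantifies the library-chemistry contrast on one genome compartment:
#'
#' * `foldBelow90` -- SSP/DSP ratio of the fraction of fragments < 90
#'   (single-strand preparations recover far more short material);
#' * `foldAbove200` -- DSP/SSP ratio of the fraction > 200;
#' * `ratioOfRatios` -- SSP/DSP ratio of the [shortLongRatio()].
#'
#' The SSP profile can be shifted by `offsetBp` before computation to
#' compensate the ~3-bp end-repair extension of DSP fragment sizes
#' (overlay convention: SSP sizes = DSP sizes - 3; default 0 for synthetic
#' data). Undefined components (zero denominators) propagate as `NA`.
#'
#' @param dsp,ssp [SizeProfile-class] objects of the same genome, DSP and
#'   SSP respectively.
#' @param offsetBp integer shift applied to the SSP profile (typically 0 or
#'   +/- 3).
#' @return A `LibraryComparison` list with elements `foldBelow90`,
#'   `foldAbove200`, `ratioOfRatios`, `offsetBp`.
#' @export
compareLibraries <- function(dsp, ssp, offsetBp = 0L) {
    stopifnot(is(dsp, "SizeProfile"), is(ssp, "SizeProfile"))
    if (dsp@genome != ssp@genome)
        stop("profiles must describe the same genome compartment")
    if (dsp@library != "DSP" || ssp@library != "SSP")
        stop("'dsp' must be a DSP profile and 'ssp' an SSP profile")
    ssp <- shiftProfile(ssp, offsetBp)
    sizes <- profileSizes()
    frac <- function(p, sel) sum(p@frequency[sel])
    dspB90 <- frac(dsp, sizes < 90); sspB90 <- frac(ssp, sizes < 90)
    dspA200 <- frac(dsp, sizes > 200); sspA200 <- frac(ssp, sizes > 200)
    safeDiv <- function(a, b) if (b == 0) NA_real_ else a / b
    rr <- {
        d <- shortLongRatio(dsp); s <- shortLongRatio(ssp)
        if (is.na(d) || is.na(s) || d == 0) NA_real_ else s / d
    }
    structure(list(
        foldBelow90 = safeDiv(sspB90, dspB90),
        foldAbove200 = safeDiv(dspA200, sspA200),
        ratioOfRatios = rr,
        offsetBp = as.integer(offsetBp)
    ), class = "LibraryComparison")
}

#' @export
print.LibraryComparison <- function(x, ...) {
    cat("Library comparison (SSP overlaid with offset",
        sprintf("%+d)\n", x$offsetBp))
    cat(sprintf("  fold below 90 (SSP/DSP): %s\n", format(x$foldBelow90)))
    cat(sprintf("  fold above 200 (DSP/SSP): %s\n", format(x$foldAbove200)))
    cat(sprintf("  short/long ratio-of-ratios (SSP/DSP): %s\n",
                format(x$ratioOfRatios)))
    invisible(x)
}

#' Summary statistics of a size profile
#'
#' One-stop summary: band fractions, modal size, short/long ratio,
#' periodicity score and the two threshold fractions used in library
#' comparisons.
#'
#' @param profile a [SizeProfile-class].
#' @param bands optional data.frame or matrix with columns `lo`, `hi`.
#' @return List with `bandFractions` (data.frame lo/hi/fraction),
#'   `modalSize`, `shortLongRatio`, `periodicityScore`, `fractionBelow90`,
#'   `fractionAbove200`.
#' @export
profileSummary <- function(profile, bands = NULL) {
    stopifnot(is(profile, "SizeProfile"))
    sizes <- profileSizes()
    bf <- NULL
    if (!is.null(bands)) {
        bands <- as.data.frame(bands)
        bf <- data.frame(lo = bands$lo, hi = bands$hi,
                         fraction = mapply(function(l, h)
                             bandFraction(profile, l, h),
                             bands$lo, bands$hi))
    }
    list(
        bandFractions = bf,
        modalSize = modalSize(profile),
        shortLongRatio = shortLongRatio(profile),
        periodicityScore = periodicityScore(profile),
        fractionBelow90 = sum(profile@frequency[sizes < 90]),
        fractionAbove200 = sum(profile@frequency[sizes > 200])
    )
}
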