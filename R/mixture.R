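#' Define one band of a fragment-length mixture
#'
#' A band is a contiguous size interval `[lo, hi]` carrying probability mass
#' `weight`. Within the band, lengths follow one of three discrete shapes:
#'
#' * `asymmetric-laplace(mode, scaleLeft, scaleRight)` -- exponential decay
#'   away from a sharp modal size, with separate left/right decay scales
#'   (bp); the shape of nucleosome-protected fragment peaks.
#' * `triangular(mode)` -- linear rise to `mode`, linear fall to `hi`;
#'   used for smear-like minor populations.
#' * `uniform` -- flat.
#'
#' An optional comb adds point mass at listed positions (e.g. the 10-bp
#' periodic sub-peaks of nuclear DNA); the comb mass is carved out of the
#' band's own weight, so band totals stay exact in expectation.
#'
#' @param lo,hi inclusive band bounds in bp (nt), within 30..1000.
#' @param weight probability mass of the band (>= 0; normalised across bands).
#' @param shape `"asymmetric-laplace"`, `"triangular"` or `"uniform"`.
#' @param mode modal size for the two peaked shapes.
#' @param scaleLeft,scaleRight asymmetric-Laplace decay scales (bp) below and
#'   above the mode.
#' @param combPositions optional integer positions receiving extra point mass.
#' @param combMass absolute probability mass added at each comb position.
#'
#' @return A one-row data.frame usable as a row of a [MixtureConfig-class]
#'   band table.
#' @examples
#' mixtureBand(90, 260, 0.779, "asymmetric-laplace",
#'             mode = 120, scaleLeft = 12, scaleRight = 55)
#' @export
mixtureBand <- function(lo, hi, weight,
                        shape = c("asymmetric-laplace", "triangular",
                                  "uniform"),
                        mode = NA_real_, scaleLeft = NA_real_,
                        scaleRight = NA_real_,
                        combPositions = integer(0), combMass = 0) {
    shape <- match.arg(shape)
    data.frame(
        lo = as.integer(lo), hi = as.integer(hi), weight = as.numeric(weight),
        shape = shape, mode = as.numeric(mode),
        scale_left = as.numeric(scaleLeft), scale_right = as.numeric(scaleRight),
        comb_pos = I(list(as.integer(combPositions))),
        comb_mass = as.numeric(combMass),
        stringsAsFactors = FALSE
    )
}

#' Construct a fragment-length mixture configuration
#'
#' @param genome `"nuclear"` or `"mitochondrial"`.
#' @param library `"DSP"` or `"SSP"`.
#' @param bands data.frame of bands, typically `rbind()` of [mixtureBand()]
#'   rows. Weights are normalised to sum to 1.
#'
#' @return A [MixtureConfig-class] object.
#' @export
mixtureConfig <- function(genome, library, bands) {
    genome <- .matchGenome(genome)
    library <- .matchLibrary(library)
    if (!is.data.frame(bands) || nrow(bands) == 0L)
        stop("'bands' must be a non-empty data.frame of mixture bands")
    if (sum(bands$weight) <= 0)
        stop("band weights must not all be zero")
    bands <- bands[order(bands$lo), , drop = FALSE]
    tot <- sum(bands$weight)
    bands$weight <- bands$weight / tot
    bands$comb_mass <- bands$comb_mass / tot
    rownames(bands) <- NULL
    new("MixtureConfig", genome = genome, library = library, bands = bands)
}

#' Calibrated default mixture configurations
#'
#' Banded mixtures reproducing the published healthy-individual mean size
#' profiles of circulating DNA for each genome/library combination:
#'
#' * mitochondrial DSP: major band 90--260 bp (77.9% of fragments) peaking
#'   sharply at 120 bp; minor short band 55--89 bp (0.9%); long smear
#'   261--425 bp (21.2%).
#' * mitochondrial SSP: monomodal 50--150 nt (74.4%) peaking at 80 nt; smear
#'   151--475 nt (25.6%).
#' * nuclear DSP: mono-nucleosomal band 85--260 bp (89.2%) peaking at 166 bp
#'   with 10-bp periodic sub-peaks at 102..152 bp; di-nucleosomal band
#'   261--420 bp (10.8%).
#' * nuclear SSP: 45--260 nt (96.3%) peaking at 166 nt with 10-nt sub-peaks
#'   at 53..143 nt; minor band 261--400 nt (3.7%).
#'
#' Residual mass unreported alongside the published major-band percentages
#' is folded into the long band, so band fractions are exact in expectation.
#'
#' @param genome `"nuclear"` or `"mitochondrial"`.
#' @param library `"DSP"` or `"SSP"`.
#'
#' @return A [MixtureConfig-class].
#' @examples
#' defaultMixtureConfig("mitochondrial", "DSP")
#' @export
defaultMixtureConfig <- function(genome = c("nuclear", "mitochondrial"),
                                 library = c("DSP", "SSP")) {
    genome <- .matchGenome(genome)
    library <- .matchLibrary(library)
    bands <- switch(paste(genome, library),
        "mitochondrial DSP" = rbind(
            mixtureBand(55, 89, 0.009, "triangular", mode = 89),
            mixtureBand(90, 260, 0.779, "asymmetric-laplace",
                        mode = 120, scaleLeft = 12, scaleRight = 55),
            mixtureBand(261, 425, 0.212, "triangular", mode = 261)
        ),
        "mitochondrial SSP" = rbind(
            mixtureBand(50, 150, 0.744, "asymmetric-laplace",
                        mode = 80, scaleLeft = 10, scaleRight = 28),
            mixtureBand(151, 475, 0.256, "triangular", mode = 151)
        ),
        "nuclear DSP" = rbind(
            mixtureBand(85, 260, 0.892, "asymmetric-laplace",
                        mode = 166, scaleLeft = 22, scaleRight = 18,
                        combPositions = seq(102L, 152L, 10L),
                        combMass = 0.003),
            mixtureBand(261, 420, 0.108, "asymmetric-laplace",
                        mode = 332, scaleLeft = 25, scaleRight = 30)
        ),
        "nuclear SSP" = rbind(
            mixtureBand(45, 260, 0.963, "asymmetric-laplace",
                        mode = 166, scaleLeft = 40, scaleRight = 16,
                        combPositions = seq(53L, 143L, 10L),
                        combMass = 0.002),
            mixtureBand(261, 400, 0.037, "triangular", mode = 261)
        )
    )
    mixtureConfig(genome, library, bands)
}

## Discrete within-band pmf on lo:hi. The continuous shape carries the
## band's weight minus the total comb mass; comb positions then get their
## point mass on top. Returned pmf is conditional (sums to 1).
.bandPmf <- function(band) {
    sizes <- seq.int(band$lo, band$hi)
    w <- switch(band$shape,
        "uniform" = rep(1, length(sizes)),
        "triangular" = {
            m <- band$mode
            up <- ifelse(sizes <= m, (sizes - band$lo + 1) / (m - band$lo + 1), 0)
            dn <- ifelse(sizes > m, (band$hi - sizes + 1) / (band$hi - m + 1), 0)
            up + dn
        },
        "asymmetric-laplace" = {
            m <- band$mode
            ifelse(sizes <= m, exp((sizes - m) / band$scale_left),
                   exp((m - sizes) / band$scale_right))
        },
        stop("unknown band shape: ", band$shape)
    )
    pmf <- w / sum(w)
    cp <- band$comb_pos[[1L]]
    if (length(cp)) {
        combCond <- band$comb_mass / band$weight   # conditional mass per tooth
        pmf <- pmf * (1 - length(cp) * combCond)
        pmf[match(cp, sizes)] <- pmf[match(cp, sizes)] + combCond
    }
    names(pmf) <- sizes
    pmf
}

#' Draw fragment lengths from a banded mixture
#'
#' Samples `n` fragment lengths from a [MixtureConfig-class]: a band is
#' chosen by its weight, then a length from the band's discrete shape (plus
#' comb point masses). Marginal band frequencies therefore converge to the
#' configured weights, and sampling is fully reproducible for a fixed seed.
#'
#' @param config a [MixtureConfig-class].
#' @param n number of fragments to draw (>= 1).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @param sampleId sample identifier stored in the output.
#'
#' @return A fragment-record data.frame with columns `sample_id`, `genome`,
#'   `library`, `length` -- the same table [readFragmentTsv()] reads and
#'   [buildProfile()] consumes.
#' @examples
#' cfg <- defaultMixtureConfig("mitochondrial", "DSP")
#' frags <- sampleFragmentLengths(cfg, 1000, seed = 1)
#' table(cut(frags$length, c(30, 89, 260, 1000)))
#' @export
sampleFragmentLengths <- function(config, n, seed = NULL,
                                  sampleId = "synthetic") {
    stopifnot(is(config, "MixtureConfig"))
    validObject(config)
    .assertScalarNumber(n, "n", positive = TRUE)
    n <- as.integer(n)
    b <- config@bands
    lengths <- withSeed(seed, {
        idx <- sample.int(nrow(b), n, replace = TRUE, prob = b$weight)
        out <- integer(n)
        for (i in seq_len(nrow(b))) {
            take <- which(idx == i)
            if (!length(take)) next
            pmf <- .bandPmf(b[i, , drop = FALSE])
            sizes <- seq.int(b$lo[i], b$hi[i])
            # sample.int avoids sample()'s scalar-x surprise on 1-size bands
            out[take] <- sizes[sample.int(length(sizes), length(take),
                                          replace = TRUE, prob = pmf)]
        }
        out
    })
    data.frame(
        sample_id = sampleId,
        genome = config@genome,
        library = config@library,
        length = lengths,
        stringsAsFactors = FALSE
    )
}

#' Read or write a mixture configuration as YAML
#'
#' Round-trips a [MixtureConfig-class] through a plain-text YAML document so
#' simulation scenarios can be version-controlled and shared.
#'
#' @param config a [MixtureConfig-class].
#' @param path file path.
#' @return `readMixtureConfig()` returns a [MixtureConfig-class];
#'   `writeMixtureConfig()` returns `path` invisibly.
#' @export
writeMixtureConfig <- function(config, path) {
    stopifnot(is(config, "MixtureConfig"))
    b <- config@bands
    bands <- lapply(seq_len(nrow(b)), function(i) {
        x <- list(lo = b$lo[i], hi = b$hi[i], weight = b$weight[i],
                  shape = b$shape[i])
        if (!is.na(b$mode[i])) x$mode <- b$mode[i]
        if (!is.na(b$scale_left[i])) x$scale_left <- b$scale_left[i]
        if (!is.na(b$scale_right[i])) x$scale_right <- b$scale_right[i]
        if (length(b$comb_pos[[i]])) {
            x$comb_positions <- b$comb_pos[[i]]
            x$comb_mass <- b$comb_mass[i]
        }
        x
    })
    yaml::write_yaml(list(genome = config@genome, library = config@library,
                          bands = bands), path)
    invisible(path)
}

#' @rdname writeMixtureConfig
#' @export
readMixtureConfig <- function(path) {
    x <- yaml::read_yaml(path)
    bands <- do.call(rbind, lapply(x$bands, function(bb) {
        mixtureBand(bb$lo, bb$hi, bb$weight, bb$shape,
                    mode = if (is.null(bb$mode)) NA_real_ else bb$mode,
                    scaleLeft = if (is.null(bb$scale_left)) NA_real_
                                else bb$scale_left,
                    scaleRight = if (is.null(bb$scale_right)) NA_real_
                                 else bb$scale_right,
                    combPositions = if (is.null(bb$comb_positions)) integer(0)
                                    else bb$comb_positions,
                    combMass = if (is.null(bb$comb_mass)) 0 else bb$comb_mass)
    }))
    mixtureConfig(x$genome, x$library, bands)
}
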