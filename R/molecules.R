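#' Simulate jagged, nicked duplex DNA molecules
#'
#' Mechanistic generator behind the DSP/SSP contrast: circulating DNA is
#' modelled as double-stranded molecules whose strands may be recessed at
#' either duplex end (jagged ends) and carry internal single-strand breaks
#' (nicks) accumulated in circulation. A double-strand library preparation
#' end-repairs and reads the whole duplex; a single-strand preparation
#' denatures first, so every nick-delimited single-strand segment becomes
#' its own library molecule (see [dspObserve()] and [sspObserve()]).
#'
#' `span` and `jag` may each be a single number (fixed value) or a
#' `function(n)` returning `n` draws, allowing arbitrary span and jag-length
#' distributions. Nick counts per strand are Poisson with mean
#' `nickRate * strand length`; nick positions are uniform strictly inside
#' the strand (duplex coordinates).
#'
#' @param n number of molecules (>= 1).
#' @param span duplex span in bp: number or `function(n)`.
#' @param jag single-strand recess length at each duplex end: number or
#'   `function(n)`. Recesses are clamped so the two strands always overlap.
#' @param nickRate expected nicks per bp of strand (>= 0).
#' @param jagStrand which strand is recessed at each end: `"top"` (both ends
#'   of the top strand, the default), `"bottom"`, or `"random"`
#'   (independently per end).
#' @param seed integer seed.
#'
#' @return A [MoleculeSet-class] of `n` molecules.
#' @examples
#' m <- simulateMolecules(5, span = 166)         # intact mono-nucleosome size
#' dspObserve(m)                                  # 166 166 166 166 166
#' sspObserve(m)                                  # each strand once: ten 166s
#' @export
simulateMolecules <- function(n, span = 166, jag = 0, nickRate = 0,
                              jagStrand = c("top", "bottom", "random"),
                              seed = NULL) {
    .assertScalarNumber(n, "n", positive = TRUE)
    .assertScalarNumber(nickRate, "nickRate", nonneg = TRUE)
    jagStrand <- match.arg(jagStrand)
    n <- as.integer(n)
    draw <- function(x, name) {
        v <- if (is.function(x)) x(n) else rep_len(as.numeric(x), n)
        if (length(v) != n || any(is.na(v)))
            stop(sprintf("'%s' must yield %d finite values", name, n))
        v
    }
    withSeed(seed, {
        spans <- draw(span, "span")
        if (any(spans < 1))
            stop("span distribution produced spans < 1 bp")
        jag5 <- pmax(0, draw(jag, "jag"))
        jag3 <- pmax(0, draw(jag, "jag"))
        ## clamp so the recessed strand keeps >= 1 bp of duplex overlap
        over <- jag5 + jag3 > spans - 1
        if (any(over)) {
            shrink <- (spans[over] - 1) / (jag5[over] + jag3[over])
            jag5[over] <- jag5[over] * shrink
            jag3[over] <- jag3[over] * shrink
        }
        topStart <- numeric(n); topEnd <- spans
        botStart <- numeric(n); botEnd <- spans
        leftOnTop <- switch(jagStrand,
            top = rep(TRUE, n), bottom = rep(FALSE, n),
            random = stats::runif(n) < 0.5)
        rightOnTop <- switch(jagStrand,
            top = rep(TRUE, n), bottom = rep(FALSE, n),
            random = stats::runif(n) < 0.5)
        topStart[leftOnTop] <- jag5[leftOnTop]
        botStart[!leftOnTop] <- jag5[!leftOnTop]
        topEnd[rightOnTop] <- spans[rightOnTop] - jag3[rightOnTop]
        botEnd[!rightOnTop] <- spans[!rightOnTop] - jag3[!rightOnTop]

        nickStrand <- function(start, end) {
            len <- end - start
            k <- stats::rpois(n, nickRate * len)
            lapply(seq_len(n), function(i) {
                if (k[i] == 0L) numeric(0)
                else sort(start[i] + stats::runif(k[i]) * len[i])
            })
        }
        new("MoleculeSet",
            span = spans,
            topStart = topStart, topEnd = topEnd,
            botStart = botStart, botEnd = botEnd,
            nicksTop = nickStrand(topStart, topEnd),
            nicksBottom = nickStrand(botStart, botEnd))
    })
}

#' Observe molecules through a double-strand library preparation
#'
#' DSP chemistry end-repairs jagged ends and ligates adapters to the intact
#' duplex, so the read-out length is the maximal extent covered by either
#' strand; internal nicks are invisible (the duplex holds together).
#' Molecules whose extent falls outside the sequencing read-out window are
#' not observed.
#'
#' @param molecules a [MoleculeSet-class].
#' @param minLength,maxLength read-out window (defaults 30 and 1000 bp).
#'
#' @return Numeric vector of observed fragment lengths (one per observable
#'   molecule, in bp).
#' @export
dspObserve <- function(molecules, minLength = 30, maxLength = 1000) {
    stopifnot(is(molecules, "MoleculeSet"))
    extent <- pmax(molecules@topEnd, molecules@botEnd) -
        pmin(molecules@topStart, molecules@botStart)
    extent[extent >= minLength & extent <= maxLength]
}

#' Observe molecules through a single-strand library preparation
#'
#' SSP chemistry heat-denatures the input, so each strand enters the library
#' independently and falls apart at every nick: each maximal nick-free
#' single-strand segment becomes one library molecule. For an intact,
#' blunt-ended duplex the observed multiset is therefore `{span, span}`.
#' Segments outside the read-out window are dropped.
#'
#' @param molecules a [MoleculeSet-class].
#' @param minLength,maxLength read-out window in nt; use `c(0, Inf)` to
#'   recover every segment (e.g. for conservation checks).
#'
#' @return Numeric vector of observed single-strand segment lengths (nt),
#'   pooled over strands and molecules.
#' @export
sspObserve <- function(molecules, minLength = 30, maxLength = 1000) {
    stopifnot(is(molecules, "MoleculeSet"))
    segs <- function(start, end, nicks) {
        out <- vector("list", length(start))
        for (i in seq_along(start))
            out[[i]] <- diff(c(start[i], nicks[[i]], end[i]))
        unlist(out, use.names = FALSE)
    }
    lens <- c(
        segs(molecules@topStart, molecules@topEnd, molecules@nicksTop),
        segs(molecules@botStart, molecules@botEnd, molecules@nicksBottom)
    )
    lens[lens >= minLength & lens <= maxLength]
}
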