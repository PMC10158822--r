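## Shared fixtures, all built in code at test time.

## Write a small SAM file of proper read pairs. `pairs` is a data.frame with
## columns rname, tlen and optionally flag1/flag2 overrides.
writeSamFixture <- function(pairs, path = tempfile(fileext = ".sam")) {
    header <- c(
        "@HD\tVN:1.6\tSO:coordinate",
        "@SQ\tSN:chr1\tLN:248956422",
        "@SQ\tSN:chr2\tLN:242193529",
        "@SQ\tSN:chrM\tLN:16569"
    )
    lines <- character(0)
    for (i in seq_len(nrow(pairs))) {
        rn <- pairs$rname[i]
        tl <- pairs$tlen[i]
        f1 <- if ("flag1" %in% names(pairs)) pairs$flag1[i] else 99L
        f2 <- if ("flag2" %in% names(pairs)) pairs$flag2[i] else 147L
        pos1 <- 1000L + i * 10L
        pos2 <- pos1 + tl - 4L
        q <- sprintf("pair%03d", i)
        lines <- c(lines,
            paste(q, f1, rn, pos1, 60L, "4M", "=", pos2, tl,
                  "ACGT", "IIII", sep = "\t"),
            paste(q, f2, rn, pos2, 60L, "4M", "=", pos1, -tl,
                  "ACGT", "IIII", sep = "\t"))
    }
    writeLines(c(header, lines), path)
    path
}

## Build a MoleculeSet directly from explicit coordinates (bypasses the
## simulator; for hand-constructed observation examples).
makeMolecules <- function(span, topStart = 0, topEnd = span,
                          botStart = 0, botEnd = span,
                          nicksTop = list(), nicksBottom = list()) {
    n <- length(span)
    pad <- function(l) if (length(l)) l else rep(list(numeric(0)), n)
    methods::new("MoleculeSet",
        span = as.numeric(span),
        topStart = rep_len(as.numeric(topStart), n),
        topEnd = rep_len(as.numeric(topEnd), n),
        botStart = rep_len(as.numeric(botStart), n),
        botEnd = rep_len(as.numeric(botEnd), n),
        nicksTop = pad(nicksTop), nicksBottom = pad(nicksBottom))
}

## Independent brute-force recount of every profile statistic, written
## against the definitions (loops and plain arithmetic), deliberately not
## sharing code with the package internals.
bruteProfileStats <- function(lengths) {
    keep <- lengths[lengths >= 30 & lengths <= 1000]
    total <- length(keep)
    freq <- numeric(971)
    for (s in 30:1000) freq[s - 29] <- sum(keep == s) / total
    below90 <- sum(keep < 90) / total
    above200 <- sum(keep > 200) / total
    mode <- (30:1000)[which(freq == max(freq))[1]]
    list(
        frequency = freq,
        total = total,
        bandFraction = function(lo, hi) sum(keep >= lo & keep <= hi) / total,
        modalSize = mode,
        shortLongRatio = if (above200 == 0) NA_real_ else below90 / above200,
        fractionBelow90 = below90,
        fractionAbove200 = above200
    )
}

## Default three-spin protocol used by the partition studies.
spinProtocol <- function() {
    prepProtocol(centrifugeStep(16000, "HS16000"),
                 centrifugeStep(40000, "UC40000"),
                 centrifugeStep(200000, "UC200000"))
}
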