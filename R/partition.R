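#' Construct a preparation series from measurements
#'
#' Packages supernatant measurements taken after each step of a plasma
#' preparation protocol into a [PrepSeries-class]. Measurements may be a
#' vector (one replicate) or a matrix with one row per step and one column
#' per replicate.
#'
#' @param genome `"nuclear"` or `"mitochondrial"`.
#' @param protocol protocol table from [prepProtocol()] (columns `label`,
#'   `type`, `value`).
#' @param measurements numeric vector or step-by-replicate matrix.
#' @param unit measurement unit, e.g. `"ng/mL"` or `"copies/mL"`.
#' @param referenceStep label of the reference supernatant (default: first
#'   step).
#' @return A [PrepSeries-class].
#' @examples
#' prepSeries("mitochondrial",
#'            prepProtocol(centrifugeStep(16000), centrifugeStep(40000),
#'                         centrifugeStep(2e5)),
#'            c(3.7e6, 9.2e5, 1.1e5), unit = "copies/mL")
#' @export
prepSeries <- function(genome, protocol, measurements, unit = "arbitrary",
                       referenceStep = NULL) {
    genome <- .matchGenome(genome)
    if (is.null(dim(measurements)))
        measurements <- matrix(measurements, ncol = 1L)
    rownames(measurements) <- protocol$label
    if (is.null(referenceStep)) referenceStep <- protocol$label[1L]
    new("PrepSeries", genome = genome, steps = protocol,
        measurements = measurements, unit = unit,
        referenceStep = referenceStep)
}

#' Remaining supernatant fraction after each step
#'
#' Divides each step's supernatant measurement by the reference step's
#' measurement, per replicate, then averages across replicates. Fractions
#' above 1 (possible under measurement noise, e.g. a high-speed supernatant
#' reading slightly above the low-speed one) are clipped to 1 with a
#' warning rather than rejected.
#'
#' @param series a [PrepSeries-class].
#' @param reference reference step label; defaults to the series'
#'   `referenceStep`.
#' @return Named numeric vector of mean remaining fractions, one per step,
#'   with the per-replicate fraction matrix as attribute `"replicates"`.
#' @export
supernatantFractions <- function(series, reference = NULL) {
    stopifnot(is(series, "PrepSeries"))
    if (is.null(reference)) reference <- series@referenceStep
    if (!reference %in% series@steps$label)
        stop("reference step '", reference, "' is not in the series")
    m <- series@measurements
    ref <- m[reference, ]
    if (any(ref == 0))
        stop("zero reference measurement; fractions undefined")
    frac <- sweep(m, 2L, ref, "/")
    over <- frac > 1
    if (any(over)) {
        warning(sum(over), " remaining fraction(s) > 1 clipped to 1 ",
                "(measurement noise)")
        frac[over] <- 1
    }
    out <- rowMeans(frac)
    names(out) <- series@steps$label
    attr(out, "replicates") <- frac
    out
}

#' Infer the structural repartition of circulating DNA
#'
#' Converts a sequential centrifugation/filtration series into per-class
#' DNA fractions: the DNA associated with the structural class removed at a
#' step is the drop in remaining supernatant fraction across that step, and
#' the residual is whatever remains after the last step -- all relative to
#' the reference supernatant.
#'
#' `classMap` names, in order, the structural class removed at each step
#' after the reference; it must list exactly the post-reference step labels
#' in their protocol order (inference on a reordered series would silently
#' produce a different answer, so a mismatch is an error, not a warning).
#'
#' For monotone series, fractions and residual sum to 1 exactly; when noise
#' makes the clipped series non-monotone, negative class fractions are
#' clipped to 0 and the vector renormalised (with a warning).
#'
#' @param series a [PrepSeries-class].
#' @param classMap named character vector: step label -> structural class
#'   name, covering every step after the reference, in order.
#' @param reference reference step label (default: the series' own).
#' @return A [PartitionEstimate-class].
#' @examples
#' s <- prepSeries("nuclear",
#'     prepProtocol(centrifugeStep(16000), centrifugeStep(40000),
#'                  centrifugeStep(2e5)),
#'     c(1100, 1001, 705), unit = "copies/mL")
#' inferPartition(s, c("40000g" = "mid-structures",
#'                     "2e+05g" = "small-structures"))
#' @export
inferPartition <- function(series, classMap, reference = NULL) {
    stopifnot(is(series, "PrepSeries"))
    if (is.null(reference)) reference <- series@referenceStep
    labels <- series@steps$label
    refIdx <- match(reference, labels)
    if (is.na(refIdx)) stop("reference step '", reference, "' not found")
    after <- labels[seq_along(labels) > refIdx]
    if (!length(after))
        stop("no steps after the reference; nothing to infer")
    if (is.null(names(classMap)) ||
        !identical(names(classMap), after))
        stop("classMap must name, in protocol order, exactly the steps ",
             "after the reference: ", paste(after, collapse = ", "))
    rem <- supernatantFractions(series, reference)
    remAfter <- rem[after]
    prev <- c(1, remAfter[-length(remAfter)])
    fractions <- prev - remAfter
    names(fractions) <- unname(classMap)
    residual <- unname(remAfter[length(remAfter)])
    if (any(fractions < 0)) {
        warning("non-monotone remaining fractions; negative class ",
                "fractions clipped to 0 and renormalised")
        fractions[fractions < 0] <- 0
        tot <- sum(fractions) + residual
        fractions <- fractions / tot
        residual <- residual / tot
    }
    new("PartitionEstimate", fractions = fractions, residual = residual,
        referenceStep = reference)
}

#' Effect of a preparation step on measured DNA
#'
#' Percent change of the across-subject mean after a step relative to
#' before, with a two-sided paired t-test when at least two subject pairs
#' are available. Per-subject percent changes are reported alongside.
#'
#' @param before,after paired measurements per subject (equal length >= 1).
#' @return List with `percentChange` (on the means), `pValue` (NA with < 2
#'   pairs or zero variance), and `perSubject` percent changes.
#' @examples
#' stepEffect(before = c(2, 2, 2), after = c(1, 1.1, 0.9))
#' @export
stepEffect <- function(before, after) {
    if (length(before) != length(after))
        stop("'before' and 'after' must be paired (equal length)")
    if (!length(before)) stop("at least one pair is required")
    if (mean(before) == 0) stop("zero baseline mean; percent change undefined")
    pct <- 100 * (mean(after) - mean(before)) / mean(before)
    p <- NA_real_
    if (length(before) >= 2L && stats::sd(after - before) > 0)
        p <- stats::t.test(after, before, paired = TRUE)$p.value
    list(percentChange = pct,
         pValue = p,
         perSubject = 100 * (after - before) / before)
}

#' Read and write preparation series tables
#'
#' Preparation series travel as tab-separated tables with columns `genome`,
#' `step_label`, `step_type`, `g_or_pore`, `replicate`, `measurement`,
#' `unit` -- one row per step and replicate, steps in protocol order.
#'
#' @param series a [PrepSeries-class] or named list of them.
#' @param path file path.
#' @return `readPrepSeries()` returns a named list of [PrepSeries-class]
#'   (one per genome in the file); `writePrepSeries()` returns `path`
#'   invisibly.
#' @export
writePrepSeries <- function(series, path) {
    if (is(series, "PrepSeries")) series <- list(series)
    rows <- lapply(series, function(s) {
        m <- s@measurements
        data.frame(
            genome = s@genome,
            step_label = rep(s@steps$label, ncol(m)),
            step_type = rep(s@steps$type, ncol(m)),
            g_or_pore = rep(s@steps$value, ncol(m)),
            replicate = rep(seq_len(ncol(m)), each = nrow(m)),
            measurement = as.vector(m),
            unit = s@unit,
            stringsAsFactors = FALSE
        )
    })
    utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writePrepSeries
#' @export
readPrepSeries <- function(path) {
    x <- utils::read.delim(path)
    need <- c("genome", "step_label", "step_type", "g_or_pore", "replicate",
              "measurement", "unit")
    if (!all(need %in% names(x)))
        stop("prep-series TSV must have columns: ",
             paste(need, collapse = ", "))
    out <- lapply(split(x, x$genome), function(g) {
        first <- g[g$replicate == g$replicate[1L], ]
        protocol <- data.frame(label = first$step_label,
                               type = first$step_type,
                               value = first$g_or_pore,
                               stringsAsFactors = FALSE)
        m <- matrix(g$measurement, nrow = nrow(protocol),
                    dimnames = list(protocol$label, NULL))
        prepSeries(g$genome[1L], protocol, m, unit = g$unit[1L])
    })
    out
}
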