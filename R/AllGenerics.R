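#' @rdname SizeProfile-class
#' @param object,x a `SizeProfile` or `MoleculeSet`.
#' @export
setGeneric("profileCounts", function(object) standardGeneric("profileCounts"))

#' @rdname SizeProfile-class
#' @export
setGeneric("profileFrequency",
           function(object) standardGeneric("profileFrequency"))

#' @rdname SizeProfile-class
#' @export
setGeneric("totalReads", function(object) standardGeneric("totalReads"))

#' @rdname SizeProfile-class
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname SizeProfile-class
#' @export
setGeneric("genomeOrigin", function(object) standardGeneric("genomeOrigin"))

#' @rdname SizeProfile-class
#' @export
setGeneric("libraryType", function(object) standardGeneric("libraryType"))

setMethod("profileCounts", "SizeProfile", function(object) object@counts)
setMethod("profileFrequency", "SizeProfile", function(object) object@frequency)
setMethod("totalReads", "SizeProfile", function(object) object@totalReads)
setMethod("sampleId", "SizeProfile", function(object) object@sampleId)
setMethod("genomeOrigin", "SizeProfile", function(object) object@genome)
setMethod("libraryType", "SizeProfile", function(object) object@library)

#' @rdname SizeProfile-class
#' @export
setMethod("show", "SizeProfile", function(object) {
    cat(sprintf("SizeProfile: %s [%s, %s]\n", object@sampleId,
                object@genome, object@library))
    cat(sprintf("  window 30..1000 %s, %s in-window reads\n", object@unit,
                format(object@totalReads, big.mark = ",")))
    if (object@totalReads > 0)
        cat(sprintf("  modal size %d %s (frequency %.4f)\n",
                    modalSize(object), object@unit,
                    max(object@frequency)))
    invisible(NULL)
})

#' @rdname MoleculeSet-class
#' @param x a `MoleculeSet`.
#' @export
setMethod("length", "MoleculeSet", function(x) length(x@span))

#' @rdname MoleculeSet-class
#' @export
setMethod("show", "MoleculeSet", function(object) {
    n <- length(object)
    cat(sprintf("MoleculeSet of %d duplex molecule%s\n", n,
                if (n == 1L) "" else "s"))
    if (n > 0L) {
        nt <- sum(lengths(object@nicksTop)) + sum(lengths(object@nicksBottom))
        cat(sprintf("  span: %.0f..%.0f bp; %d nick%s total\n",
                    min(object@span), max(object@span), nt,
                    if (nt == 1L) "" else "s"))
    }
    invisible(NULL)
})

#' @rdname MixtureConfig-class
#' @export
setMethod("show", "MixtureConfig", function(object) {
    cat(sprintf("MixtureConfig [%s, %s]: %d band(s)\n", object@genome,
                object@library, nrow(object@bands)))
    b <- object@bands
    for (i in seq_len(nrow(b))) {
        comb <- if (length(b$comb_pos[[i]]))
            sprintf(" + comb(%d positions)", length(b$comb_pos[[i]])) else ""
        cat(sprintf("  [%d,%d] w=%.3f %s%s\n", b$lo[i], b$hi[i], b$weight[i],
                    b$shape[i], comb))
    }
    invisible(NULL)
})

#' @rdname StandardCurve-class
#' @export
setMethod("show", "StandardCurve", function(object) {
    cat(sprintf("StandardCurve: Cq = %.4f %+.4f * log10(quantity)\n",
                object@intercept, object@slope))
    cat(sprintf("  efficiency %.1f%%, R^2 %s\n", 100 * object@efficiency,
                ifelse(is.na(object@rSquared), "NA",
                       sprintf("%.4f", object@rSquared))))
    invisible(NULL)
})

#' @rdname PrepSeries-class
#' @export
setMethod("show", "PrepSeries", function(object) {
    cat(sprintf("PrepSeries [%s], %d step(s), %d replicate(s), unit %s\n",
                object@genome, nrow(object@steps), ncol(object@measurements),
                object@unit))
    m <- rowMeans(object@measurements)
    for (i in seq_len(nrow(object@steps)))
        cat(sprintf("  %s%-14s %-10s %s\n",
                    ifelse(object@steps$label[i] == object@referenceStep,
                           "*", " "),
                    object@steps$label[i], object@steps$type[i],
                    format(m[i], digits = 4)))
    cat("  (* = reference supernatant)\n")
    invisible(NULL)
})

#' @rdname PartitionEstimate-class
#' @export
setMethod("show", "PartitionEstimate", function(object) {
    cat("PartitionEstimate (fraction of reference supernatant DNA)\n")
    for (nm in names(object@fractions))
        cat(sprintf("  %-20s %6.1f%%\n", nm, 100 * object@fractions[[nm]]))
    cat(sprintf("  %-20s %6.1f%%\n", "residual supernatant",
                100 * object@residual))
    invisible(NULL)
})

#' @rdname PartitionEstimate-class
#' @param object a `PartitionEstimate`.
#' @export
setGeneric("classFractions", function(object) standardGeneric("classFractions"))

#' @rdname PartitionEstimate-class
#' @export
setGeneric("residualFraction",
           function(object) standardGeneric("residualFraction"))

setMethod("classFractions", "PartitionEstimate", function(object) object@fractions)
setMethod("residualFraction", "PartitionEstimate", function(object) object@residual)
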