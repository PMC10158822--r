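#' Structural classes carrying circulating DNA
#'
#' A structural-class table describes the physical forms in which
#' circulating DNA travels in plasma and how each form behaves under the
#' preparation steps:
#'
#' * `pellet_g` -- smallest centrifugal force (g) that removes the class
#'   from the supernatant (`Inf` = never pellets);
#' * `filter_trapped` -- whether a 0.22-um membrane filter retains it;
#' * `freeze_release_to` / `freeze_fold` -- for the platelet-internal
#'   compartment only: on a freeze-thaw step the platelets lyse and release
#'   their mitochondrial DNA into the named supernatant class, raising the
#'   total mitochondrial supernatant signal by `freeze_fold`;
#' * `weight_nuclear` / `weight_mitochondrial` -- the fraction of each
#'   genome's supernatant DNA associated with the class (each column sums
#'   to 1).
#'
#' @param name,pellet_g,filter_trapped,freeze_release_to,freeze_fold,weight_nuclear,weight_mitochondrial
#'   vectors of equal length, one entry per class.
#'
#' @return A validated structural-class data.frame.
#' @seealso [defaultStructuralClasses()], [simulatePlasmaPrep()]
#' @export
structuralClasses <- function(name, pellet_g, filter_trapped,
                              weight_nuclear, weight_mitochondrial,
                              freeze_release_to = NA_character_,
                              freeze_fold = NA_real_) {
    x <- data.frame(
        name = as.character(name),
        pellet_g = as.numeric(pellet_g),
        filter_trapped = as.logical(filter_trapped),
        freeze_release_to = as.character(freeze_release_to),
        freeze_fold = as.numeric(freeze_fold),
        weight_nuclear = as.numeric(weight_nuclear),
        weight_mitochondrial = as.numeric(weight_mitochondrial),
        stringsAsFactors = FALSE
    )
    .validateClasses(x)
    x
}

.validateClasses <- function(x) {
    if (anyDuplicated(x$name)) stop("class names must be unique")
    if (any(x$pellet_g <= 0)) stop("pellet_g must be positive")
    for (col in c("weight_nuclear", "weight_mitochondrial")) {
        if (any(x[[col]] < 0)) stop(col, " must be non-negative")
        if (abs(sum(x[[col]]) - 1) > 1e-9)
            stop(col, " must sum to 1 across classes")
    }
    tgt <- x$freeze_release_to[!is.na(x$freeze_release_to)]
    if (length(tgt) && !all(tgt %in% x$name))
        stop("freeze_release_to must name an existing class")
    invisible(x)
}

#' Default structural-class repartition
#'
#' The calibrated repartition of supernatant circulating DNA (relative to a
#' 16,000 g supernatant) across pelletable structure classes:
#'
#' * mid-structures (extracellular mitochondria, large EVs; pellet at
#'   40,000 g, filter-trapped): 75.7% of mitochondrial, 36.3% of nuclear DNA;
#' * small-structures (small EVs, chromatin; pellet at 200,000 g): 20.1%
#'   mitochondrial, 53.1% nuclear;
#' * soluble (exosome-borne and protein/nucleoprotein complexes,
#'   oligo/mono-nucleosomes; never pellets): 4.2% mitochondrial, 10.6%
#'   nuclear.
#'
#' So 24.3% of mitochondrial and 63.7% of nuclear DNA remain after
#' 40,000 g, and 4.2% / 10.6% after 200,000 g, by construction. Two
#' zero-weight bookkeeping classes complete the model: `large-structures`
#' (apoptotic bodies, cell debris; already removed by the 16,000 g
#' reference spin) and `platelet-internal`, whose mitochondrial DNA is
#' released into the soluble class by a freeze-thaw step with a 12-fold
#' supernatant increase.
#'
#' @return A structural-class data.frame (see [structuralClasses()]).
#' @export
defaultStructuralClasses <- function() {
    structuralClasses(
        name = c("large-structures", "mid-structures", "small-structures",
                 "soluble", "platelet-internal"),
        pellet_g = c(16000, 40000, 200000, Inf, 16000),
        filter_trapped = c(TRUE, TRUE, FALSE, FALSE, FALSE),
        weight_nuclear = c(0, 0.363, 0.531, 0.106, 0),
        weight_mitochondrial = c(0, 0.757, 0.201, 0.042, 0),
        freeze_release_to = c(NA, NA, NA, NA, "soluble"),
        freeze_fold = c(NA, NA, NA, NA, 12)
    )
}

#' Build a plasma-preparation protocol
#'
#' A protocol is an ordered table of physical steps applied to plasma:
#' centrifugations at increasing g-force, 0.22-um filtration, or a
#' freeze-thaw cycle. Helpers [centrifugeStep()], [filterStep()] and
#' [freezeStep()] build the rows.
#'
#' @param ... step rows created by the helper constructors.
#' @return A protocol data.frame with columns `label`, `type`, `value`.
#' @examples
#' prepProtocol(centrifugeStep(16000), centrifugeStep(40000),
#'              centrifugeStep(2e5))
#' @export
prepProtocol <- function(...) {
    steps <- rbind(...)
    if (is.null(steps) || nrow(steps) == 0L)
        stop("a protocol needs at least one step")
    if (anyDuplicated(steps$label))
        stop("step labels must be unique")
    rownames(steps) <- NULL
    steps
}

#' @rdname prepProtocol
#' @param g centrifugal force in g (> 0).
#' @param label step label; defaults to a descriptive one.
#' @export
centrifugeStep <- function(g, label = sprintf("%gg", g)) {
    .assertScalarNumber(g, "g", positive = TRUE)
    data.frame(label = label, type = "centrifuge", value = as.numeric(g),
               stringsAsFactors = FALSE)
}

#' @rdname prepProtocol
#' @param pore filter pore size in um.
#' @export
filterStep <- function(pore = 0.22, label = sprintf("filter%g", pore)) {
    .assertScalarNumber(pore, "pore", positive = TRUE)
    data.frame(label = label, type = "filter", value = as.numeric(pore),
               stringsAsFactors = FALSE)
}

#' @rdname prepProtocol
#' @export
freezeStep <- function(label = "freeze") {
    data.frame(label = label, type = "freeze", value = NA_real_,
               stringsAsFactors = FALSE)
}

#' Simulate supernatant DNA measurements along a preparation protocol
#'
#' Distributes each genome's total DNA across the structural classes by
#' their weights, then walks the protocol: a centrifugation at `g` empties
#' every class with `pellet_g <= g`; a filtration empties filter-trapped
#' classes; a freeze-thaw step releases platelet-internal mitochondrial DNA
#' into its target class so that the mitochondrial supernatant total rises
#' by the configured fold factor (nuclear DNA is unaffected by freezing).
#' After each step the surviving class amounts are summed and measured with
#' multiplicative log-normal noise of coefficient of variation `noiseCv`
#' (mean-unbiased), independently per replicate.
#'
#' @param classes structural-class table (see [structuralClasses()]).
#' @param totals named vector: total supernatant signal per genome at the
#'   start of the protocol, e.g. `c(nuclear = 1000, mitochondrial = 3.7e6)`.
#'   Genomes may be omitted.
#' @param protocol protocol table from [prepProtocol()].
#' @param noiseCv coefficient of variation of the measurement noise (>= 0).
#' @param replicates number of replicate measurement series.
#' @param seed integer seed.
#' @param unit measurement unit label stored in the result.
#'
#' @return A named list of [PrepSeries-class], one per genome in `totals`,
#'   with the first protocol step as reference.
#' @examples
#' series <- simulatePlasmaPrep(
#'     defaultStructuralClasses(),
#'     totals = c(mitochondrial = 3.7e6),
#'     protocol = prepProtocol(centrifugeStep(16000), centrifugeStep(40000),
#'                             centrifugeStep(2e5)),
#'     noiseCv = 0, replicates = 1, seed = 1)
#' supernatantFractions(series$mitochondrial)   # 1.000 0.243 0.042
#' @export
simulatePlasmaPrep <- function(classes, totals, protocol, noiseCv = 0.2,
                               replicates = 1, seed = NULL,
                               unit = "arbitrary") {
    .validateClasses(classes)
    .assertScalarNumber(noiseCv, "noiseCv", nonneg = TRUE)
    .assertScalarNumber(replicates, "replicates", positive = TRUE)
    if (is.null(protocol) || nrow(protocol) == 0L)
        stop("protocol must contain at least one step")
    if (is.null(names(totals)) ||
        !all(names(totals) %in% c("nuclear", "mitochondrial")))
        stop("'totals' must be named with genomes (nuclear, mitochondrial)")
    replicates <- as.integer(replicates)
    sigma <- sqrt(log(1 + noiseCv^2))

    withSeed(seed, {
        out <- lapply(names(totals), function(genome) {
            wcol <- if (genome == "nuclear") "weight_nuclear"
                    else "weight_mitochondrial"
            meas <- matrix(0, nrow(protocol), replicates,
                           dimnames = list(protocol$label, NULL))
            for (r in seq_len(replicates)) {
                amounts <- classes[[wcol]] * unname(totals[[genome]])
                names(amounts) <- classes$name
                for (s in seq_len(nrow(protocol))) {
                    type <- protocol$type[s]
                    if (type == "centrifuge") {
                        amounts[classes$pellet_g <= protocol$value[s]] <- 0
                    } else if (type == "filter") {
                        amounts[classes$filter_trapped] <- 0
                    } else if (type == "freeze" && genome == "mitochondrial") {
                        src <- which(!is.na(classes$freeze_release_to))
                        for (i in src) {
                            release <- (classes$freeze_fold[i] - 1) *
                                sum(amounts)
                            tgt <- classes$freeze_release_to[i]
                            amounts[tgt] <- amounts[tgt] + release
                            amounts[classes$name[i]] <- 0
                        }
                    }
                    true <- sum(amounts)
                    meas[s, r] <- if (sigma > 0)
                        true * stats::rlnorm(1, -sigma^2 / 2, sigma)
                    else true
                }
            }
            new("PrepSeries", genome = genome, steps = protocol,
                measurements = meas, unit = unit,
                referenceStep = protocol$label[1L])
        })
        names(out) <- names(totals)
        out
    })
}
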