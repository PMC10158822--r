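#' Filter settings for paired-end fragment extraction
#'
#' @param minLength,maxLength inclusive insert-size window (defaults 1 and
#'   1000 bp; sizes outside are dropped on read).
#' @param requireProperPair keep only reads flagged as properly paired.
#' @param excludeSecondarySupplementary drop secondary and supplementary
#'   alignments.
#' @param mitoContigs reference contig names (case-insensitive) classified
#'   as mitochondrial; everything else is nuclear.
#' @param minMapq optional minimum mapping quality (default 0 = no filter).
#'
#' @return A `ReadFilter` list.
#' @export
readFilter <- function(minLength = 1L, maxLength = 1000L,
                       requireProperPair = TRUE,
                       excludeSecondarySupplementary = TRUE,
                       mitoContigs = c("chrM", "MT", "chrMT"),
                       minMapq = 0L) {
    if (minLength <= 0 || minLength > maxLength)
        stop("need 0 < minLength <= maxLength")
    structure(list(minLength = as.integer(minLength),
                   maxLength = as.integer(maxLength),
                   requireProperPair = isTRUE(requireProperPair),
                   excludeSecondarySupplementary =
                       isTRUE(excludeSecondarySupplementary),
                   mitoContigs = as.character(mitoContigs),
                   minMapq = as.integer(minMapq)),
              class = "ReadFilter")
}

#' Extract fragment lengths from aligned paired-end reads
#'
#' Reads a SAM or BAM file and returns one fragment record per read pair,
#' taking the insert size from the mate with a positive template length
#' (TLEN field), so each pair is counted exactly once. Pairs are classified
#' as mitochondrial when their reference contig name matches
#' `filter$mitoContigs` (case-insensitive), nuclear otherwise. Pairs failing
#' the filter (improper pairs, secondary/supplementary alignments, zero or
#' out-of-window template length, low MAPQ) are omitted.
#'
#' @param path SAM or BAM file with a header.
#' @param sampleId sample identifier stored in the records.
#' @param library `"DSP"` or `"SSP"` (stored; not inferable from the BAM).
#' @param filter a [readFilter()].
#'
#' @return Fragment-record data.frame (`sample_id`, `genome`, `library`,
#'   `length`); zero usable pairs gives an empty data.frame with a warning.
#' @export
readInsertSizes <- function(path, sampleId, library, filter = readFilter()) {
    if (!file.exists(path)) stop("no such file: ", path)
    library <- .matchLibrary(library)
    stopifnot(inherits(filter, "ReadFilter"))
    bam <- path
    if (grepl("\\.sam$", path, ignore.case = TRUE))
        bam <- Rsamtools::asBam(path,
                                destination = tempfile(fileext = ""),
                                overwrite = TRUE, indexDestination = FALSE)
    flags <- Rsamtools::scanBamFlag(
        isProperPair = if (filter$requireProperPair) TRUE else NA,
        isSecondaryAlignment =
            if (filter$excludeSecondarySupplementary) FALSE else NA,
        isSupplementaryAlignment =
            if (filter$excludeSecondarySupplementary) FALSE else NA,
        isUnmappedQuery = FALSE
    )
    param <- Rsamtools::ScanBamParam(
        flag = flags, what = c("rname", "isize", "mapq"))
    res <- Rsamtools::scanBam(bam, param = param)[[1L]]
    keep <- !is.na(res$isize) & res$isize > 0 &
        res$isize >= filter$minLength & res$isize <= filter$maxLength
    if (filter$minMapq > 0)
        keep <- keep & !is.na(res$mapq) & res$mapq >= filter$minMapq
    rname <- as.character(res$rname[keep])
    len <- res$isize[keep]
    if (!length(len))
        warning("no usable read pairs in ", path)
    mito <- tolower(rname) %in% tolower(filter$mitoContigs)
    data.frame(
        sample_id = rep(sampleId, length(len)),
        genome = ifelse(mito, "mitochondrial", "nuclear"),
        library = rep(library, length(len)),
        length = as.integer(len),
        stringsAsFactors = FALSE
    )
}

#' Read and write fragment tables
#'
#' The fragment TSV dialect is tab-separated UTF-8 with a header row and
#' columns `sample_id`, `genome`, `library`, `length`; extra columns are
#' preserved on read and ignored downstream. Writing then reading is
#' lossless.
#'
#' @param records fragment-record data.frame.
#' @param path file path.
#' @return `readFragmentTsv()` returns the fragment-record data.frame
#'   (empty, with a warning, for a header-only file); `writeFragmentTsv()`
#'   returns `path` invisibly.
#' @export
writeFragmentTsv <- function(records, path) {
    need <- c("sample_id", "genome", "library", "length")
    if (!all(need %in% names(records)))
        stop("records must have columns: ", paste(need, collapse = ", "))
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' @rdname writeFragmentTsv
#' @export
readFragmentTsv <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    x <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, fileEncoding = "UTF-8")
    need <- c("sample_id", "genome", "library", "length")
    if (!all(need %in% names(x)))
        stop("fragment TSV must have columns: ",
             paste(need, collapse = ", "), " (missing: ",
             paste(setdiff(need, names(x)), collapse = ", "), ")")
    if (nrow(x) == 0L) {
        warning("fragment TSV contains a header but no records: ", path)
        x$length <- integer(0)
        return(x)
    }
    len <- suppressWarnings(as.numeric(x$length))
    bad <- which(is.na(len) | len < 1 | len != floor(len))
    if (length(bad))
        stop("malformed length value(s) in ", path, " at line(s) ",
             paste(bad + 1L, collapse = ", "),
             " (line 1 is the header): ",
             paste(utils::head(x$length[bad], 5L), collapse = ", "))
    x$length <- as.integer(len)
    x
}

#' Read and write profile tables
#'
#' Size profiles are stored as tab-separated tables with columns `size`,
#' `count`, `frequency` covering every size 30..1000.
#'
#' @param profile a [SizeProfile-class].
#' @param path file path.
#' @param sampleId,genome,library metadata for the reconstructed profile
#'   (not stored in the table).
#' @return `readProfileTsv()` returns a [SizeProfile-class];
#'   `writeProfileTsv()` returns `path` invisibly.
#' @export
writeProfileTsv <- function(profile, path) {
    stopifnot(is(profile, "SizeProfile"))
    utils::write.table(
        data.frame(size = profileSizes(),
                   count = unname(profile@counts),
                   frequency = unname(profile@frequency)),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeProfileTsv
#' @export
readProfileTsv <- function(path, sampleId, genome, library) {
    x <- utils::read.delim(path)
    if (!all(c("size", "count", "frequency") %in% names(x)))
        stop("profile TSV must have columns size, count, frequency")
    if (!identical(as.integer(x$size), profileSizes()))
        stop("profile TSV must cover sizes 30..1000 in order")
    genome <- .matchGenome(genome)
    library <- .matchLibrary(library)
    counts <- as.numeric(x$count)
    names(counts) <- x$size
    freq <- as.numeric(x$frequency)
    names(freq) <- x$size
    new("SizeProfile", sampleId = sampleId, genome = genome,
        library = library, unit = .unitFor(library), counts = counts,
        frequency = freq, totalReads = sum(counts))
}
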