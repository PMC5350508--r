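#' Construct a peak set
#'
#' A `PeakSet` holds the genomic intervals (BED convention: 0-based,
#' half-open) called for one cell state, e.g. unstimulated MHCII-lo,
#' unstimulated MHCII-hi or LPS-stimulated MHCII-hi.
#'
#' @param intervals data.frame with columns `chrom` (character), `start`,
#'   `end` (integers, 0-based half-open) and optionally `name`.
#' @param state_label character scalar identifying the cell state.
#' @return An object of class `PeakSet`: a list with elements `state_label`
#'   and `intervals`.
#' @export
peak_set <- function(intervals, state_label = "unlabeled") {
    stopifnot(is.character(state_label), length(state_label) == 1L)
    if (is.null(intervals) || nrow(intervals) == 0L) {
        intervals <- data.frame(chrom = character(), start = integer(),
                                end = integer(), name = character(),
                                stringsAsFactors = FALSE)
    }
    if (!all(c("chrom", "start", "end") %in% names(intervals)))
        stop("intervals need columns chrom, start, end")
    if (!"name" %in% names(intervals)) intervals$name <- NA_character_
    intervals <- intervals[, c("chrom", "start", "end", "name")]
    intervals$chrom <- as.character(intervals$chrom)
    intervals$start <- as.integer(intervals$start)
    intervals$end <- as.integer(intervals$end)
    if (anyNA(intervals$start) || anyNA(intervals$end))
        stop("NA coordinates in peak set")
    if (any(intervals$start < 0L)) stop("negative start coordinate")
    if (any(intervals$start >= intervals$end))
        stop("interval with start >= end (BED is 0-based half-open)")
    structure(list(state_label = state_label, intervals = intervals),
              class = "PeakSet")
}

#' @export
print.PeakSet <- function(x, ...) {
    cat(sprintf("PeakSet '%s': %d intervals on %d chromosome(s)\n",
                x$state_label, nrow(x$intervals),
                length(unique(x$intervals$chrom))))
    invisible(x)
}

#' Read a BED file into a PeakSet
#'
#' Accepts BED3+; columns beyond the fourth are ignored, the fourth (if
#' present) is kept as the interval name.  Coordinates are taken as 0-based
#' half-open, the BED convention.
#'
#' @param path path to a tab-separated BED file.
#' @param state_label state label to attach to the resulting `PeakSet`.
#' @return A [peak_set()].
#' @export
read_bed <- function(path, state_label = "unlabeled") {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L)
        return(peak_set(NULL, state_label))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("line ", which(nf < 3L)[1L], ": fewer than 3 tab-separated columns")
    chrom <- vapply(fields, `[[`, "", 1L)
    start_c <- vapply(fields, `[[`, "", 2L)
    end_c <- vapply(fields, `[[`, "", 3L)
    bad <- !grepl("^[0-9]+$", start_c) | !grepl("^[0-9]+$", end_c)
    if (any(bad))
        stop("line ", which(bad)[1L], ": non-integer coordinate")
    start <- as.integer(start_c)
    end <- as.integer(end_c)
    if (any(start >= end))
        stop("line ", which(start >= end)[1L], ": start >= end")
    name <- ifelse(nf >= 4L,
                   vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_, ""),
                   NA_character_)
    peak_set(data.frame(chrom = chrom, start = start, end = end, name = name,
                        stringsAsFactors = FALSE), state_label)
}

#' Write a PeakSet to a BED file
#'
#' Writes BED3 when no interval has a name, BED4 otherwise, preserving
#' interval order, so `write_bed(read_bed(f))` round-trips a 3-column file
#' byte for byte.
#'
#' @param x a `PeakSet` (or bare intervals data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
    iv <- if (inherits(x, "PeakSet")) x$intervals else x
    if (nrow(iv) == 0L) {
        writeLines(character(), path)
        return(invisible(path))
    }
    if (all(is.na(iv$name))) {
        lines <- sprintf("%s\t%d\t%d", iv$chrom, iv$start, iv$end)
    } else {
        lines <- sprintf("%s\t%d\t%d\t%s", iv$chrom, iv$start, iv$end,
                         ifelse(is.na(iv$name), ".", iv$name))
    }
    writeLines(lines, path)
    invisible(path)
}
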