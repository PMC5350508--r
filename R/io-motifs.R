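#' Construct a motif PWM
#'
#' A position probability matrix over (A, C, G, T) with a log-odds detection
#' threshold in bits, the unit of motif scanning and enrichment.  Rows are
#' floored (see [pwm_floor()]) so log-odds scores are always finite.
#'
#' @param motif_id character id.
#' @param matrix L x 4 numeric matrix of per-position base probabilities;
#'   rows must sum to 1 within 0.01 (they are renormalized after flooring).
#' @param detection_threshold log-odds score threshold in bits.
#' @param consensus consensus string of length L (derived from the matrix if
#'   missing).
#' @param floor pseudo-probability floor.
#' @return An object of class `MotifPWM`.
#' @export
motif_pwm <- function(motif_id, matrix, detection_threshold, consensus = NULL,
                      floor = 0.001) {
    matrix <- as.matrix(matrix)
    if (ncol(matrix) != 4L) stop("PWM must have 4 columns (A,C,G,T)")
    if (nrow(matrix) < 4L) stop("PWM for '", motif_id, "' has fewer than 4 rows")
    rs <- rowSums(matrix)
    if (any(abs(rs - 1) > 0.01)) {
        warning("PWM '", motif_id, "' row(s) ",
                paste(which(abs(rs - 1) > 0.01), collapse = ","),
                " do not sum to 1; renormalizing")
        matrix <- matrix / rs
    }
    matrix <- pwm_floor(matrix, floor = floor)
    colnames(matrix) <- c("A", "C", "G", "T")
    if (is.null(consensus))
        consensus <- paste(c("A", "C", "G", "T")[max.col(matrix, "first")],
                           collapse = "")
    stopifnot(nchar(consensus) == nrow(matrix))
    structure(list(motif_id = motif_id, matrix = matrix,
                   detection_threshold = as.numeric(detection_threshold),
                   consensus = consensus),
              class = "MotifPWM")
}

#' @export
print.MotifPWM <- function(x, ...) {
    cat(sprintf("MotifPWM '%s' (%s), L=%d, threshold=%.2f bits\n",
                x$motif_id, x$consensus, nrow(x$matrix),
                x$detection_threshold))
    invisible(x)
}

#' Floor and renormalize PWM probabilities
#'
#' Entries below `floor` are raised to `floor` and the remaining probability
#' mass is rescaled over the other entries of the row, so every entry stays
#' at or above the floor and each row sums to exactly 1.  Rows already at or
#' above the floor everywhere and summing to 1 pass through unchanged.
#'
#' @param matrix L x 4 probability matrix.
#' @param floor pseudo-probability floor (default 0.001).
#' @return Floored matrix with unit row sums.
#' @export
pwm_floor <- function(matrix, floor = 0.001) {
    t(apply(matrix, 1L, function(row) {
        low <- row < floor
        if (!any(low)) return(row / sum(row))
        row[low] <- floor
        keep <- !low
        row[keep] <- row[keep] * (1 - floor * sum(low)) / sum(row[keep])
        row
    }))
}

#' Read a known-motif library
#'
#' Parses the HOMER-style motif text dialect: each record starts with a
#' header line `>consensus<TAB>motif_id<TAB>threshold` followed by L lines of
#' 4 whitespace-separated base probabilities (A, C, G, T).  The three-field
#' header is mandatory; thresholds are log-odds scores in bits.
#'
#' @param path path to the motif library file.
#' @param floor pseudo-probability floor passed to [motif_pwm()].
#' @return List of `MotifPWM` objects in file order.
#' @export
read_motif_library <- function(path, floor = 0.001) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    starts <- grep("^>", lines)
    if (length(starts) == 0L) stop("no motif records in ", path)
    ends <- c(starts[-1L] - 1L, length(lines))
    lapply(seq_along(starts), function(i) {
        header <- strsplit(sub("^>", "", lines[starts[i]]), "\t", fixed = TRUE)[[1L]]
        if (length(header) < 3L)
            stop("motif header must have 3 tab-separated fields ",
                 "(consensus, id, threshold): ", lines[starts[i]])
        body <- lines[(starts[i] + 1L):ends[i]]
        if (length(body) < 4L)
            stop("motif '", header[2L], "' has fewer than 4 matrix rows")
        mat <- do.call(rbind, lapply(body, function(l)
            as.numeric(strsplit(trimws(l), "\\s+")[[1L]])))
        if (ncol(mat) != 4L || anyNA(mat))
            stop("malformed probability row in motif '", header[2L], "'")
        motif_pwm(motif_id = header[2L], matrix = mat,
                  detection_threshold = as.numeric(header[3L]),
                  consensus = header[1L], floor = floor)
    })
}

#' Write a motif library in the HOMER-style text dialect
#'
#' @param library list of `MotifPWM` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motif_library <- function(library, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (m in library) {
        writeLines(sprintf(">%s\t%s\t%.12g", m$consensus, m$motif_id,
                           m$detection_threshold), con)
        writeLines(apply(m$matrix, 1L, function(r)
            paste(sprintf("%.6f", r), collapse = "\t")), con)
    }
    invisible(path)
}
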