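#' Read a FASTA file of peak sequences
#'
#' Sequences are uppercased and validated against the alphabet A, C, G, T, N.
#' Record ids (the first whitespace-delimited token of each header) must be
#' unique.
#'
#' @param path path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    set <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(set))
    if (anyDuplicated(ids))
        stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
    seqs <- toupper(as.character(set))
    names(seqs) <- ids
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad))
        stop("illegal character in record '", ids[bad][1L],
             "' (alphabet is A/C/G/T/N)")
    seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
    stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
    set <- Biostrings::BStringSet(seqs)
    Biostrings::writeXStringSet(set, path, width = as.integer(width))
    invisible(path)
}

#' Reverse complement of DNA sequences
#'
#' @param seqs character vector over A/C/G/T/N.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seqs) {
    comp <- chartr("ACGTN", "TGCAN", seqs)
    vapply(strsplit(comp, "", fixed = TRUE),
           function(x) paste(rev(x), collapse = ""), "")
}
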