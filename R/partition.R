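#' Merge overlapping genomic intervals
#'
#' Intervals sharing at least one base pair are merged into maximal runs
#' (half-open overlap: `a.start < b.end && b.start < a.end`).  Bookended
#' intervals (`a.end == b.start`) share no base and are NOT merged.  Output
#' is sorted by (chrom, start, end).
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. the `intervals` of a [peak_set()].
#' @return data.frame of merged, sorted, pairwise non-overlapping intervals.
#' @export
merge_intervals <- function(intervals) {
    if (inherits(intervals, "PeakSet")) intervals <- intervals$intervals
    if (nrow(intervals) == 0L)
        return(data.frame(chrom = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE))
    gr <- GenomicRanges::GRanges(
        intervals$chrom,
        IRanges::IRanges(start = intervals$start + 1L, end = intervals$end))
    red <- GenomicRanges::reduce(GenomicRanges::sort(gr), min.gapwidth = 0L)
    out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                      start = GenomicRanges::start(red) - 1L,
                      end = GenomicRanges::end(red),
                      stringsAsFactors = FALSE)
    out <- out[order(out$chrom, out$start, out$end), ]
    rownames(out) <- NULL
    out
}

#' Three-way Venn partition of peak sets into consensus regions
#'
#' Consensus regions are the maximal merged runs of overlapping peaks pooled
#' over the three states ([merge_intervals()]); each region's membership
#' signature is the set of states with at least one peak overlapping it by
#' >= 1 bp.  "Unique to X" regions have signature exactly `{X}`; "common"
#' regions carry all three states — the partition behind the common/unique
#' Venn of regulatory regions.
#'
#' @param set_a,set_b,set_c [peak_set()] objects with distinct state labels.
#' @return List with `regions` (data.frame: chrom, start, end, signature,
#'   plus one logical column per state) and `venn_counts` (data.frame:
#'   signature, n, covering all 7 non-empty signatures).
#' @export
venn_partition <- function(set_a, set_b, set_c) {
    sets <- list(set_a, set_b, set_c)
    labels <- vapply(sets, function(s) s$state_label, "")
    if (anyDuplicated(labels)) stop("state labels must be distinct")
    pooled <- do.call(rbind, lapply(sets, function(s)
        s$intervals[, c("chrom", "start", "end")]))
    regions <- merge_intervals(pooled)
    member <- matrix(FALSE, nrow(regions), 3L,
                     dimnames = list(NULL, labels))
    if (nrow(regions) > 0L) {
        reg_gr <- GenomicRanges::GRanges(
            regions$chrom,
            IRanges::IRanges(regions$start + 1L, regions$end))
        for (i in 1:3) {
            iv <- sets[[i]]$intervals
            if (nrow(iv) == 0L) next
            gr <- GenomicRanges::GRanges(
                iv$chrom, IRanges::IRanges(iv$start + 1L, iv$end))
            hit <- GenomicRanges::countOverlaps(reg_gr, gr,
                                                minoverlap = 1L) > 0L
            member[, i] <- hit
        }
    }
    signature <- if (nrow(regions) == 0L) character() else
        apply(member, 1L, function(m) paste(labels[m], collapse = "&"))
    all_sigs <- unlist(lapply(1:3, function(k)
        utils::combn(labels, k, paste, collapse = "&")))
    venn_counts <- data.frame(
        signature = all_sigs,
        n = as.integer(table(factor(signature, levels = all_sigs))),
        stringsAsFactors = FALSE)
    regions <- cbind(regions, as.data.frame(member), signature = signature,
                     stringsAsFactors = FALSE)
    list(regions = regions, venn_counts = venn_counts)
}

#' Extract the regions unique to one state
#'
#' @param partition result of [venn_partition()].
#' @param label state label.
#' @return data.frame of regions whose signature is exactly `label`.
#' @export
unique_regions <- function(partition, label) {
    r <- partition$regions
    r[r$signature == label, c("chrom", "start", "end"), drop = FALSE]
}
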