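#' Names of peaks overlapping a region set
#'
#' @param pset a [peak_set()].
#' @param regions data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [unique_regions()].
#' @return Character vector of peak names overlapping any region by >= 1 bp.
#' @export
peaks_in_regions <- function(pset, regions) {
    iv <- pset$intervals
    if (nrow(iv) == 0L || nrow(regions) == 0L) return(character())
    peaks_gr <- GenomicRanges::GRanges(
        iv$chrom, IRanges::IRanges(iv$start + 1L, iv$end))
    reg_gr <- GenomicRanges::GRanges(
        regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end))
    hit <- GenomicRanges::countOverlaps(peaks_gr, reg_gr, minoverlap = 1L) > 0L
    iv$name[hit]
}

#' Run the three-state differential motif pipeline
#'
#' End-to-end chromatin arm of the analysis: Venn-partition the three
#' states' peak sets into consensus regions, take each state's unique
#' regions, enrich the corresponding peak sequences against seeded
#' dinucleotide-shuffled backgrounds, and rank differential motifs with the
#' Deming-residual statistic.
#'
#' @param peak_sets named list of three [peak_set()] objects, in the order
#'   MHCII-lo unstimulated, MHCII-hi unstimulated, MHCII-hi LPS.
#' @param sequences named list (same names) of per-state named sequence
#'   vectors covering the state's peaks.
#' @param library motif library.
#' @param seed seed for the shuffled backgrounds.
#' @param lambda,decile passed to [run_differential_analysis()].
#' @return List of class `regstate_pipeline`: `partition`, `enrichments`
#'   (per state), `diff`.
#' @export
run_motif_pipeline <- function(peak_sets, sequences, library, seed = 1L,
                               lambda = 1, decile = 0.10) {
    stopifnot(length(peak_sets) == 3L, length(sequences) == 3L)
    part <- venn_partition(peak_sets[[1L]], peak_sets[[2L]], peak_sets[[3L]])
    labels <- vapply(peak_sets, function(s) s$state_label, "")
    enrichments <- lapply(seq_along(peak_sets), function(i) {
        uniq <- unique_regions(part, labels[i])
        ids <- peaks_in_regions(peak_sets[[i]], uniq)
        target <- sequences[[i]][ids]
        enrich_motif_library(target, library, seed = seed + i,
                             label = labels[i])
    })
    names(enrichments) <- labels
    diff <- run_differential_analysis(enrichments[[1L]], enrichments[[2L]],
                                      enrichments[[3L]],
                                      lambda = lambda, decile = decile)
    structure(list(partition = part, enrichments = enrichments, diff = diff),
              class = "regstate_pipeline")
}
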