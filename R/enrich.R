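#' Hypergeometric over-representation p-value
#'
#' With `N = n_target + n_background` sequences of which
#' `K = k_target + k_background` contain the motif, the p-value is the upper
#' tail `P(X >= k_target)` for `X ~ Hypergeometric(N, K, n_target)` — the
#' chance of seeing at least as many motif-bearing sequences in a random
#' draw of `n_target` sequences.  Over-representation only.
#'
#' @param n_target,k_target number of target sequences and how many contain
#'   the motif.
#' @param n_background,k_background same for the background set.
#' @return List with `p_value` (may underflow to 0 at extreme enrichment)
#'   and `neg_log10_p` (computed on the log scale, exact even when `p_value`
#'   underflows).
#' @export
hypergeom_enrichment <- function(n_target, k_target, n_background,
                                 k_background) {
    stopifnot(n_target >= 0, k_target >= 0, n_background >= 0,
              k_background >= 0, k_target <= n_target,
              k_background <= n_background)
    N <- n_target + n_background
    K <- k_target + k_background
    if (N == 0) stop("empty contrast: no sequences on either side")
    if (K == 0) return(list(p_value = 1, neg_log10_p = 0))
    log_p <- phyper(k_target - 1, K, N - K, n_target,
                    lower.tail = FALSE, log.p = TRUE)
    list(p_value = exp(log_p), neg_log10_p = -log_p / log(10))
}

#' Known-motif enrichment of a target sequence set
#'
#' Scans target and background sequences with every motif in the library and
#' scores per-motif over-representation with [hypergeom_enrichment()], using
#' the per-sequence presence indicator (a sequence counts once per motif).
#' When no background is supplied, a seeded dinucleotide-shuffled background
#' is built from the target sequences (`shuffle_copies` shuffles per target
#' sequence), preserving length and approximate composition.
#'
#' @param target_seqs named character vector of target sequences.
#' @param library list of [motif_pwm()] objects.
#' @param background_seqs optional named character vector; must not share
#'   ids with the target (a degenerate contrast).
#' @param shuffle_copies number of shuffled copies per target sequence used
#'   when `background_seqs` is NULL.
#' @param background base composition for log-odds scoring (default
#'   uniform).
#' @param seed seed for the shuffle.
#' @param label region-set label stored in the result.
#' @return data.frame of class `EnrichmentResult` rows, one per motif,
#'   ordered by ascending p (ties by motif id): `motif_id`,
#'   `region_set_label`, `n_target`, `k_target`, `n_background`,
#'   `k_background`, `p_value`, `neg_log10_p`.
#' @export
enrich_motif_library <- function(target_seqs, library,
                                 background_seqs = NULL,
                                 shuffle_copies = 2L,
                                 background = rep(0.25, 4),
                                 seed = 1L,
                                 label = "target") {
    if (length(target_seqs) == 0L) stop("empty target sequence set")
    if (length(library) == 0L) stop("empty motif library")
    if (is.null(background_seqs)) {
        background_seqs <- unlist(lapply(seq_len(shuffle_copies), function(k) {
            b <- dinucleotide_shuffle(target_seqs, seed = seed + k - 1L)
            names(b) <- paste0(names(b), k)
            b
        }))
    } else {
        if (length(background_seqs) == 0L) stop("empty background sequence set")
        shared <- intersect(names(target_seqs), names(background_seqs))
        if (length(shared))
            stop("background identical to target for ids: ",
                 paste(head(shared, 5L), collapse = ", "),
                 " (degenerate contrast)")
    }
    hit_t <- scan_presence_matrix(target_seqs, library, background)
    hit_b <- scan_presence_matrix(background_seqs, library, background)
    res <- do.call(rbind, lapply(seq_along(library), function(i) {
        hg <- hypergeom_enrichment(nrow(hit_t), sum(hit_t[, i]),
                                   nrow(hit_b), sum(hit_b[, i]))
        data.frame(motif_id = library[[i]]$motif_id,
                   region_set_label = label,
                   n_target = nrow(hit_t), k_target = sum(hit_t[, i]),
                   n_background = nrow(hit_b),
                   k_background = sum(hit_b[, i]),
                   p_value = hg$p_value, neg_log10_p = hg$neg_log10_p,
                   stringsAsFactors = FALSE)
    }))
    res <- res[order(-res$neg_log10_p, res$motif_id), ]
    rownames(res) <- NULL
    class(res) <- c("EnrichmentResult", "data.frame")
    res
}
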