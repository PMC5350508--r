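BASES <- c("A", "C", "G", "T")

# Encode sequences as 0-based integer codes (A=0,C=1,G=2,T=3, N=-1) for the
# compiled scanner.
encode_dna <- function(seqs) {
    lapply(strsplit(toupper(seqs), "", fixed = TRUE), function(ch) {
        code <- match(ch, BASES) - 1L
        code[ch == "N"] <- -1L
        if (anyNA(code)) stop("illegal character in sequence")
        code
    })
}

# L x 4 log2-odds matrix for a MotifPWM against a base-composition background.
pwm_log_odds <- function(pwm, background = rep(0.25, 4)) {
    stopifnot(length(background) == 4L, all(background > 0),
              abs(sum(background) - 1) < 1e-6)
    log2(sweep(pwm$matrix, 2L, background, "/"))
}

#' Scan a sequence with a PWM on both strands
#'
#' Every window of length L on the plus strand, and the reverse complement of
#' every window for the minus strand, is scored as the sum of per-position
#' log2-odds `log2(p_i[base] / q[base])` against the background composition
#' `q`.  All windows scoring at or above the motif's detection threshold are
#' reported; windows containing N are skipped.
#'
#' @param sequence DNA string (A/C/G/T/N).
#' @param pwm a [motif_pwm()].
#' @param background background base composition over (A,C,G,T); strictly
#'   positive, summing to 1.  Default uniform.
#' @return data.frame of hits: `motif_id`, `offset` (0-based start within the
#'   sequence), `strand` ("+"/"-"), `score` (bits).  Zero rows when nothing
#'   reaches threshold.
#' @export
pwm_log_odds_scan <- function(sequence, pwm, background = rep(0.25, 4)) {
    stopifnot(length(sequence) == 1L)
    lo <- pwm_log_odds(pwm, background)
    hits <- scan_pwm_cpp(encode_dna(sequence)[[1L]], lo,
                         pwm$detection_threshold)
    data.frame(motif_id = rep(pwm$motif_id, nrow(hits)),
               offset = hits$offset,
               strand = c("+", "-")[hits$strand + 1L],
               score = hits$score,
               stringsAsFactors = FALSE)
}

#' Scan a sequence set and report per-sequence motif presence
#'
#' The counting unit of known-motif enrichment: a sequence counts once per
#' motif no matter how many windows reach threshold.
#'
#' @param seqs named character vector of sequences.
#' @param library list of [motif_pwm()] objects.
#' @param background background base composition for scoring.
#' @return Logical matrix, sequences x motifs: does the sequence contain at
#'   least one hit?
#' @export
scan_presence_matrix <- function(seqs, library, background = rep(0.25, 4)) {
    enc <- encode_dna(seqs)
    out <- vapply(library, function(pwm) {
        as.logical(any_hit_cpp(enc, pwm_log_odds(pwm, background),
                               pwm$detection_threshold))
    }, logical(length(seqs)))
    out <- matrix(out, nrow = length(seqs),
                  dimnames = list(names(seqs),
                                  vapply(library, `[[`, "", "motif_id")))
    out
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Random Eulerian-walk shuffle (Altschul–Erikson): each shuffled sequence
#' has exactly the original's dinucleotide (and hence mononucleotide)
#' composition with the same first and last base.  Used to build enrichment
#' background sets that preserve length and approximate composition.
#'
#' @param seqs character vector of sequences.
#' @param seed integer seed; the shuffle is deterministic given `seqs` and
#'   `seed`.
#' @return Character vector of shuffled sequences (names suffixed
#'   `"_shuf<k>"` when `seqs` is named).
#' @export
dinucleotide_shuffle <- function(seqs, seed = 1L) {
    set.seed(as.integer(seed))
    out <- vapply(seqs, shuffle_one_dinuc, "", USE.NAMES = FALSE)
    if (!is.null(names(seqs))) names(out) <- paste0(names(seqs), "_shuf")
    out
}

shuffle_one_dinuc <- function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    n <- length(ch)
    if (n <= 3L) return(s)
    from <- ch[-n]
    to <- ch[-1L]
    verts <- unique(ch)
    last <- ch[n]
    edges <- split(to, factor(from, levels = verts))
    for (try in 1:500) {
        # pick a candidate terminal edge for every non-terminal vertex
        last_edge <- vapply(verts, function(v) {
            if (v == last) NA_character_ else {
                e <- edges[[v]]
                e[sample.int(length(e), 1L)]
            }
        }, "")
        # the terminal-edge graph must lead every vertex to the last base
        ok <- TRUE
        for (v in verts) {
            if (v == last) next
            cur <- v
            for (step in seq_along(verts)) {
                cur <- last_edge[[cur]]
                if (identical(cur, last)) break
            }
            if (!identical(cur, last)) { ok <- FALSE; break }
        }
        if (!ok) next
        walk_edges <- lapply(verts, function(v) {
            e <- edges[[v]]
            if (v == last) return(e[sample.int(length(e))])
            le <- last_edge[[v]]
            idx <- which(e == le)[1L]
            rest <- e[-idx]
            c(rest[sample.int(length(rest))], le)
        })
        names(walk_edges) <- verts
        ptr <- setNames(rep(1L, length(verts)), verts)
        res <- character(n)
        res[1L] <- ch[1L]
        cur <- ch[1L]
        for (i in 2:n) {
            nxt <- walk_edges[[cur]][ptr[[cur]]]
            ptr[[cur]] <- ptr[[cur]] + 1L
            res[i] <- nxt
            cur <- nxt
        }
        return(paste(res, collapse = ""))
    }
    # unreachable in practice; fall back to a mononucleotide shuffle
    paste(ch[sample.int(n)], collapse = "")
}
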