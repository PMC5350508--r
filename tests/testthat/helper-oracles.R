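# Independent brute-force oracles used across the suite.  Each re-derives a
# result from first principles (per-bp coverage, window enumeration, exact
# combinatorics, geometric minimization) without touching the code path it
# checks.

options(regstate.quiet = TRUE)

# --- intervals ---------------------------------------------------------------

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 200L,
                             max_len = 30L) {
    start <- sample.int(max_pos, n, replace = TRUE) - 1L
    data.frame(chrom = sample(chroms, n, replace = TRUE),
               start = start,
               end = start + sample.int(max_len, n, replace = TRUE),
               stringsAsFactors = FALSE)
}

# merge via connected components of the pairwise >= 1 bp overlap graph
# (a per-bp coverage oracle cannot express the bookended-intervals-stay-apart
# rule: coverage is contiguous across a shared half-open boundary)
oracle_merge <- function(iv) {
    out <- list()
    for (ch in sort(unique(iv$chrom))) {
        sub <- iv[iv$chrom == ch, , drop = FALSE]
        n <- nrow(sub)
        comp <- seq_len(n)
        repeat {
            changed <- FALSE
            for (i in seq_len(n)) for (j in seq_len(n)) {
                if (comp[i] != comp[j] &&
                    overlaps_1bp(sub$start[i], sub$end[i],
                                 sub$start[j], sub$end[j])) {
                    comp[comp == comp[j]] <- comp[i]
                    changed <- TRUE
                }
            }
            if (!changed) break
        }
        merged <- do.call(rbind, lapply(unique(comp), function(cc)
            data.frame(chrom = ch, start = min(sub$start[comp == cc]),
                       end = max(sub$end[comp == cc]),
                       stringsAsFactors = FALSE)))
        out[[ch]] <- merged[order(merged$start, merged$end), , drop = FALSE]
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

overlaps_1bp <- function(a_start, a_end, b_start, b_end)
    a_start < b_end & b_start < a_end

# membership signatures by testing every merged region against every raw peak
oracle_venn_signatures <- function(regions, sets) {
    labels <- vapply(sets, function(s) s$state_label, "")
    vapply(seq_len(nrow(regions)), function(i) {
        memb <- vapply(sets, function(s) {
            iv <- s$intervals
            any(iv$chrom == regions$chrom[i] &
                overlaps_1bp(iv$start, iv$end,
                             regions$start[i], regions$end[i]))
        }, logical(1))
        paste(labels[memb], collapse = "&")
    }, "")
}

# --- PWM scanning ------------------------------------------------------------

rc_string <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

score_window <- function(window, mat, background) {
    ch <- strsplit(window, "")[[1]]
    if (any(ch == "N")) return(NA_real_)
    idx <- match(ch, c("A", "C", "G", "T"))
    sum(log2(mat[cbind(seq_along(idx), idx)] / background[idx]))
}

# enumerate every window x strand and score it directly
oracle_scan <- function(sequence, pwm, background = rep(0.25, 4)) {
    L <- nrow(pwm$matrix)
    n <- nchar(sequence)
    hits <- list()
    for (off in 0:(n - L)) {
        w <- substr(sequence, off + 1L, off + L)
        sp <- score_window(w, pwm$matrix, background)
        sm <- score_window(rc_string(w), pwm$matrix, background)
        if (!is.na(sp) && sp >= pwm$detection_threshold)
            hits[[length(hits) + 1L]] <- data.frame(
                offset = off, strand = "+", score = sp)
        if (!is.na(sm) && sm >= pwm$detection_threshold)
            hits[[length(hits) + 1L]] <- data.frame(
                offset = off, strand = "-", score = sm)
    }
    if (!length(hits))
        return(data.frame(offset = integer(), strand = character(),
                          score = numeric()))
    do.call(rbind, hits)
}

random_pwm <- function(L = NULL, id = "m") {
    if (is.null(L)) L <- sample(4:8, 1)
    mat <- matrix(runif(L * 4), L, 4)
    mat <- mat / rowSums(mat)
    motif_pwm(id, mat, detection_threshold = runif(1, 1, 4))
}

# --- exact hypergeometric tail ----------------------------------------------

oracle_hyper_tail <- function(N, K, n, k) {
    js <- k:min(K, n)
    js <- js[n - js <= N - K]
    sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# --- Deming fit: geometric minimizer ----------------------------------------

# For lambda = 1 the optimal line passes through the centroid; minimize the
# orthogonal SS over the line angle by grid search plus local refinement.
oracle_deming_orth <- function(x, y) {
    xc <- x - mean(x); yc <- y - mean(y)
    ss <- function(theta) sum((yc * cos(theta) - xc * sin(theta))^2)
    grid <- seq(-pi / 2 + 1e-6, pi / 2 - 1e-6, length.out = 20000)
    th0 <- grid[which.min(vapply(grid, ss, 0))]
    opt <- optimize(ss, c(th0 - 2e-4, th0 + 2e-4), tol = 1e-14)
    slope <- tan(opt$minimum)
    list(slope = slope, intercept = mean(y) - slope * mean(x))
}

# --- naive average-linkage agglomeration ------------------------------------

oracle_average_linkage_heights <- function(mat) {
    d <- as.matrix(dist(mat))
    clusters <- as.list(seq_len(nrow(mat)))
    heights <- numeric()
    while (length(clusters) > 1L) {
        best <- c(NA, NA); best_d <- Inf
        for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
            avg <- mean(d[clusters[[i]], clusters[[j]]])
            if (avg < best_d) { best_d <- avg; best <- c(j, i) }
        }
        heights <- c(heights, best_d)
        clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
        clusters[[best[2]]] <- NULL
    }
    heights
}

# --- misc --------------------------------------------------------------------

# straightforward step-up: q_(i) = min_{j >= i} m p_(j) / j
manual_bh <- function(p) {
    m <- length(p)
    ord <- order(p)
    ps <- p[ord]
    q <- numeric(m)
    for (i in seq_len(m)) q[i] <- min(1, min(m * ps[i:m] / (i:m)))
    out <- numeric(m)
    out[ord] <- q
    out
}
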