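TIMEPOINTS_H <- c(0, 1, 6, 24)

# Pull values + per-sample time annotation out of the supported input types.
timecourse_values <- function(expr, time_h = NULL) {
    if (inherits(expr, "ExpressionMatrix")) {
        if (!"time_h" %in% names(expr$sample_meta))
            stop("sample_meta lacks a time_h column")
        time_h <- expr$sample_meta$time_h
        values <- expr$values
    } else {
        values <- as.matrix(expr)
        if (is.null(time_h) || length(time_h) != ncol(values))
            stop("need one time_h per sample")
    }
    if (!setequal(unique(time_h), TIMEPOINTS_H))
        stop("time course must cover exactly t = 0, 1, 6, 24 h")
    list(values = values, time_h = time_h)
}

#' Per-gene one-way ANOVA across the stimulation time course
#'
#' For each gene, a one-way F statistic across the four time-point groups on
#' log2 values, p from `F(3, N-4)`, and BH-adjusted q-values.  A gene that
#' is constant everywhere (zero between- and within-group variance) gets
#' `F = 0, p = 1`.
#'
#' @param expr [expression_matrix()] whose samples carry `time_h` in
#'   `{0, 1, 6, 24}` (>= 2 replicates each), or a bare matrix with `time_h`
#'   supplied.
#' @param time_h per-sample time annotation for bare-matrix input.
#' @return data.frame of class `DEResult`: `gene_id`, `F`, `p`, `q`,
#'   `max_abs_log2fc_vs_t0`.
#' @export
timecourse_f_test <- function(expr, time_h = NULL) {
    tc <- timecourse_values(expr, time_h)
    values <- tc$values
    groups <- factor(tc$time_h, levels = TIMEPOINTS_H)
    if (any(table(groups) < 2L)) stop("need >= 2 replicates per time point")
    N <- ncol(values)
    k <- nlevels(groups)
    group_means <- matrix(
        vapply(levels(groups), function(g)
            rowMeans(values[, groups == g, drop = FALSE]),
            numeric(nrow(values))),
        nrow = nrow(values), dimnames = list(rownames(values),
                                             levels(groups)))
    grand <- rowMeans(values)
    n_per <- as.vector(table(groups))
    ssb <- as.vector((group_means - grand)^2 %*% n_per)
    fitted <- group_means[, as.integer(groups), drop = FALSE]
    ssw <- rowSums((values - fitted)^2)
    Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
    p <- pf(Fstat, k - 1, N - k, lower.tail = FALSE)
    # degenerate genes: no within- or between-group variance
    flat <- ssw == 0 & ssb == 0
    Fstat[flat] <- 0; p[flat] <- 1
    # perfect separation with zero noise
    p[ssw == 0 & ssb > 0] <- 0
    Fstat[ssw == 0 & ssb > 0] <- Inf
    fc <- abs(group_means[, -1L, drop = FALSE] - group_means[, 1L])
    res <- data.frame(gene_id = rownames(values), F = Fstat, p = p,
                      q = bh_adjust(p),
                      max_abs_log2fc_vs_t0 = apply(fc, 1L, max),
                      stringsAsFactors = FALSE)
    rownames(res) <- NULL
    class(res) <- c("DEResult", "data.frame")
    res
}

#' Select LPS-responsive genes
#'
#' A gene is selected when its BH-adjusted q-value is below `q_threshold`
#' AND the largest absolute log2 difference of any stimulated time-point
#' mean versus t = 0 reaches the linear fold-change gate
#' (`log2(fc_threshold)`).
#'
#' @param de `DEResult` from [timecourse_f_test()].
#' @param q_threshold adjusted-p threshold (default 0.001).
#' @param fc_threshold minimum linear fold change versus t = 0 (default 1.5).
#' @return The `DEResult` with a logical `selected` column added.
#' @export
select_de_genes <- function(de, q_threshold = 0.001, fc_threshold = 1.5) {
    stopifnot(q_threshold > 0, fc_threshold > 0)
    de$selected <- de$q < q_threshold &
        de$max_abs_log2fc_vs_t0 >= log2(fc_threshold)
    de
}

#' Kinetic clustering of selected time-course genes
#'
#' Per-gene time-point mean profiles are standardized to mean 0, SD 1 across
#' the four time points (so clusters group by kinetic shape, not amplitude
#' or baseline) and clustered by k-means with Euclidean distance and seeded
#' restarts, keeping the best inertia.  Constant profiles cannot be
#' standardized (and cannot pass the fold gate); they are rejected.
#'
#' @param profiles gene x 4 matrix of time-point means (columns t = 0, 1, 6,
#'   24 h) for the selected genes.
#' @param k number of clusters (default 12).
#' @param seed integer seed controlling the restarts.
#' @param nstart number of k-means restarts (default 50).
#' @return List of class `KineticClustering`: `k`, `assignments` (named
#'   integer vector), `centroids` (k x 4 standardized profiles), `sizes`,
#'   `totss_within`.
#' @export
kinetic_clusters <- function(profiles, k = 12L, seed = 1L, nstart = 50L) {
    profiles <- as.matrix(profiles)
    if (ncol(profiles) != 4L) stop("profiles must have 4 time-point columns")
    if (nrow(profiles) < k)
        stop("fewer genes (", nrow(profiles), ") than clusters (", k,
             "); choose a smaller k")
    sds <- apply(profiles, 1L, sd)
    if (any(sds == 0))
        stop("constant profile(s): ",
             paste(head(rownames(profiles)[sds == 0], 5L), collapse = ", "))
    z <- t(scale(t(profiles)))
    # k-means++ seeding per restart (D^2 sampling never re-picks a covered
    # profile, so k clean archetypes are always recovered exactly), keeping
    # the best inertia over the restarts
    set.seed(as.integer(seed))
    km <- NULL
    for (r in seq_len(nstart)) {
        centers <- kmeanspp_centers(z, k)
        cand <- tryCatch(
            suppressWarnings(kmeans(z, centers = centers, iter.max = 100L)),
            error = function(e) NULL)
        if (!is.null(cand) &&
            (is.null(km) || cand$tot.withinss < km$tot.withinss)) km <- cand
    }
    if (is.null(km)) stop("k-means failed for every restart")
    structure(list(k = k,
                   assignments = setNames(km$cluster, rownames(profiles)),
                   centroids = km$centers,
                   sizes = as.integer(km$size),
                   totss_within = km$tot.withinss),
              class = "KineticClustering")
}

# k-means++ initial centers: first uniform, then each next center sampled
# with probability proportional to squared distance from the nearest chosen
# center; rows at distance 0 can never be re-picked.  Falls back to uniform
# sampling of unused rows if every remaining row coincides with a center.
kmeanspp_centers <- function(z, k) {
    n <- nrow(z)
    idx <- integer(k)
    idx[1L] <- sample.int(n, 1L)
    d2 <- rowSums((z - matrix(z[idx[1L], ], n, ncol(z), byrow = TRUE))^2)
    for (j in seq_len(k - 1L)) {
        if (sum(d2) > 0) {
            idx[j + 1L] <- sample.int(n, 1L, prob = d2)
        } else {
            idx[j + 1L] <- sample(setdiff(seq_len(n), idx[seq_len(j)]), 1L)
        }
        nd <- rowSums((z - matrix(z[idx[j + 1L], ], n, ncol(z),
                                  byrow = TRUE))^2)
        d2 <- pmin(d2, nd)
    }
    z[idx, , drop = FALSE]
}

#' Time-point mean profiles of a time-course matrix
#'
#' @param expr as in [timecourse_f_test()].
#' @param time_h per-sample times for bare-matrix input.
#' @return Gene x 4 matrix of per-time means (columns "0", "1", "6", "24").
#' @export
timepoint_means <- function(expr, time_h = NULL) {
    tc <- timecourse_values(expr, time_h)
    groups <- factor(tc$time_h, levels = TIMEPOINTS_H)
    out <- vapply(levels(groups), function(g)
        rowMeans(tc$values[, groups == g, drop = FALSE]),
        numeric(nrow(tc$values)))
    matrix(out, nrow = nrow(tc$values),
           dimnames = list(rownames(tc$values), levels(groups)))
}
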