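#' Deming (errors-in-variables) regression
#'
#' Closed-form fit minimizing the sum of squared perpendicular (for
#' `lambda = 1`, orthogonal) distances.  With sample (co)variances
#' `s_xx, s_yy, s_xy`:
#' \deqn{slope = \frac{s_{yy} - \lambda s_{xx} +
#'   \sqrt{(s_{yy} - \lambda s_{xx})^2 + 4 \lambda s_{xy}^2}}{2 s_{xy}}}
#' and `intercept = mean(y) - slope * mean(x)`.  `R` is the Pearson
#' correlation of (x, y).
#'
#' @param x,y numeric vectors of equal length >= 3 (here, paired -log10
#'   enrichment p-values of the same motifs in two states).
#' @param lambda ratio of error variances (y over x); 1 = orthogonal
#'   regression, the default since both axes come from the same enrichment
#'   procedure.
#' @return List with `slope`, `intercept`, `R`, `lambda`, `n`.
#' @export
deming_fit <- function(x, y, lambda = 1) {
    stopifnot(length(x) == length(y), lambda > 0)
    n <- length(x)
    if (n < 3L) stop("Deming fit needs at least 3 points")
    if (var(x) == 0 && var(y) == 0)
        stop("both x and y are constant; fit undefined")
    s_xx <- var(x); s_yy <- var(y); s_xy <- cov(x, y)
    if (s_xy == 0) {
        if (s_yy == lambda * s_xx)
            stop("degenerate input: s_xy = 0 and s_yy = lambda * s_xx; ",
                 "fit undefined")
        # orthogonal SS is minimized by a horizontal (s_yy < lambda*s_xx) or
        # vertical line; the vertical case has no finite slope
        if (s_yy > lambda * s_xx)
            stop("s_xy = 0 with s_yy > lambda * s_xx: best line is vertical")
        slope <- 0
    } else {
        slope <- (s_yy - lambda * s_xx +
                  sqrt((s_yy - lambda * s_xx)^2 + 4 * lambda * s_xy^2)) /
                 (2 * s_xy)
    }
    intercept <- mean(y) - slope * mean(x)
    R <- if (var(x) == 0 || var(y) == 0) NA_real_ else cor(x, y)
    list(slope = slope, intercept = intercept, R = R, lambda = lambda, n = n)
}

#' Signed orthogonal residuals of a Deming fit
#'
#' `residual_i = (y_i - slope * x_i - intercept) / sqrt(1 + slope^2)`: the
#' signed perpendicular distance from each point to the fitted line,
#' positive above the line.  Normalized residuals divide by the sample SD
#' (ddof = 1) of the residuals; when every point is on the line (SD = 0) the
#' normalized residuals are defined as all zero.
#'
#' @param x,y the fitted vectors.
#' @param fit result of [deming_fit()] on the same vectors (or a list with
#'   `slope` and `intercept`).
#' @return List with `residual` and `normalized_residual`.
#' @export
orthogonal_residuals <- function(x, y, fit) {
    res <- (y - fit$slope * x - fit$intercept) / sqrt(1 + fit$slope^2)
    s <- sd(res)
    norm <- if (s == 0 || !is.finite(s)) rep(0, length(res)) else res / s
    list(residual = res, normalized_residual = norm)
}

#' Select the top decile of motifs by normalized residual
#'
#' Motifs are ranked by absolute normalized residual, descending (the sign —
#' which state the motif is enriched toward — is retained for display); ties
#' are broken by lexicographic motif id.  The first `ceiling(decile * n)`
#' motifs are selected.
#'
#' @param normalized_residual numeric vector.
#' @param motif_ids aligned character vector of motif ids.
#' @param decile selected fraction (default 0.10).
#' @return Logical mask aligned with the input.
#' @export
select_top_decile <- function(normalized_residual, motif_ids, decile = 0.10) {
    stopifnot(length(normalized_residual) == length(motif_ids))
    n <- length(normalized_residual)
    if (n == 0L) return(logical())
    k <- ceiling(decile * n)
    ord <- order(-abs(normalized_residual), motif_ids)
    mask <- logical(n)
    mask[ord[seq_len(k)]] <- TRUE
    mask
}

#' Jackknife 90% confidence band for a Deming fit
#'
#' Leave-one-out refits give jackknife standard errors of the predicted line
#' at each grid point; the half-width is `1.645 * SE`, evaluated on a
#' 100-point grid spanning the range of x.
#'
#' @param x,y fitted vectors, length >= 5.
#' @param fit result of [deming_fit()] on (x, y).
#' @param grid_n number of grid points.
#' @return data.frame with `x0`, `fit` (predicted y) and `half_width`.
#' @export
ci90_band <- function(x, y, fit, grid_n = 100L) {
    n <- length(x)
    if (n < 5L) stop("confidence band needs at least 5 points")
    grid <- seq(min(x), max(x), length.out = grid_n)
    preds <- vapply(seq_len(n), function(i) {
        f <- deming_fit(x[-i], y[-i], lambda = fit$lambda)
        f$intercept + f$slope * grid
    }, numeric(grid_n))
    pred_mean <- rowMeans(preds)
    se <- sqrt((n - 1) / n * rowSums((preds - pred_mean)^2))
    data.frame(x0 = grid,
               fit = fit$intercept + fit$slope * grid,
               half_width = 1.645 * se)
}

#' Average-linkage hierarchical clustering of a residual matrix
#'
#' Agglomerative clustering with Euclidean distance and average (mean)
#' linkage; the heatmap row order is the dendrogram leaf order, which
#' [stats::hclust()] resolves deterministically (ties by smallest original
#' row index).
#'
#' @param mat numeric matrix (rows = motifs, columns = comparisons), no
#'   missing values.
#' @return List with `linkage` (an `hclust` object, or NULL for a single
#'   row) and `row_order` (integer leaf order).
#' @export
hcluster_mean_linkage <- function(mat) {
    mat <- as.matrix(mat)
    if (anyNA(mat)) stop("missing values in clustering input")
    if (nrow(mat) < 2L)
        return(list(linkage = NULL, row_order = seq_len(nrow(mat))))
    hc <- hclust(dist(mat, method = "euclidean"), method = "average")
    list(linkage = hc, row_order = hc$order)
}

#' Differential motif enrichment across three chromatin states
#'
#' The pipeline's differential statistic: for each of the three state
#' pairings — MHCII-lo vs unstimulated MHCII-hi, MHCII-lo vs LPS-stimulated
#' MHCII-hi, and unstimulated MHCII-hi vs LPS-stimulated MHCII-hi — the
#' motif-aligned -log10 enrichment p-values are fitted by Deming regression,
#' normalized orthogonal residuals are ranked, and the top decile of motifs
#' is selected.  The union of selected motifs over the three comparisons
#' forms a residual heatmap clustered with Euclidean distance and average
#' linkage.
#'
#' @param enrich_lo,enrich_hi,enrich_lps `EnrichmentResult` data.frames from
#'   [enrich_motif_library()] for the three states, over the same motif
#'   library.
#' @param lambda Deming error-variance ratio (default 1 = orthogonal).
#' @param decile selected fraction per comparison (default 0.10).
#' @return List of class `regstate_motifdiff` with `comparisons` (named list
#'   of `DemingComparison` lists: `label_x`, `label_y`, `x`, `y`, `fit`,
#'   `residual`, `normalized_residual`, `top_decile`, `band`) and `heatmap`
#'   (list with `motifs`, `matrix`, `row_order`, `linkage`).
#' @export
run_differential_analysis <- function(enrich_lo, enrich_hi, enrich_lps,
                                      lambda = 1, decile = 0.10) {
    tabs <- list(lo = enrich_lo, hi = enrich_hi, lps = enrich_lps)
    ids <- lapply(tabs, function(t) sort(t$motif_id))
    for (i in 2:3) {
        diff <- c(setdiff(ids[[1L]], ids[[i]]), setdiff(ids[[i]], ids[[1L]]))
        if (length(diff))
            stop("motif sets differ between inputs: ",
                 paste(head(diff, 10L), collapse = ", "))
    }
    motifs <- ids[[1L]]
    vec <- lapply(tabs, function(t)
        setNames(t$neg_log10_p, t$motif_id)[motifs])
    pairs <- list(lo_vs_hi = c("lo", "hi"),
                  lo_vs_lps = c("lo", "lps"),
                  hi_vs_lps = c("hi", "lps"))
    comparisons <- lapply(pairs, function(p) {
        x <- vec[[p[1L]]]; y <- vec[[p[2L]]]
        fit <- deming_fit(x, y, lambda = lambda)
        ores <- orthogonal_residuals(x, y, fit)
        band <- if (length(x) >= 5L) ci90_band(x, y, fit) else NULL
        list(label_x = p[1L], label_y = p[2L], x = x, y = y, fit = fit,
             residual = ores$residual,
             normalized_residual = ores$normalized_residual,
             top_decile = select_top_decile(ores$normalized_residual,
                                            motifs, decile),
             band = band)
    })
    selected <- sort(unique(unlist(lapply(comparisons, function(cmp)
        motifs[cmp$top_decile]))))
    hm <- vapply(comparisons, function(cmp)
        cmp$normalized_residual[match(selected, motifs)],
        numeric(length(selected)))
    hm <- matrix(hm, nrow = length(selected),
                 dimnames = list(selected, names(pairs)))
    clust <- hcluster_mean_linkage(hm)
    structure(list(comparisons = comparisons,
                   heatmap = list(motifs = selected, matrix = hm,
                                  row_order = clust$row_order,
                                  linkage = clust$linkage)),
              class = "regstate_motifdiff")
}
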