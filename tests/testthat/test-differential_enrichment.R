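test_that("colinear points give an exact fit with zero residuals", {
    x <- c(0, 1, 2, 3, 4)
    y <- 2 * x + 1
    fit <- deming_fit(x, y)
    expect_equal(fit$slope, 2, tolerance = 1e-12)
    expect_equal(fit$intercept, 1, tolerance = 1e-12)
    expect_equal(fit$R, 1, tolerance = 1e-12)
    res <- orthogonal_residuals(x, y, fit)
    expect_equal(res$residual, rep(0, 5), tolerance = 1e-12)
    expect_equal(res$normalized_residual, rep(0, 5))
})

test_that("lambda = 1 fits obey the axis-swap identity", {
    set.seed(2)
    for (i in 1:25) {
        x <- rnorm(20); y <- 0.8 * x + rnorm(20, sd = 0.5)
        expect_equal(deming_fit(x, y)$slope * deming_fit(y, x)$slope, 1,
                     tolerance = 1e-9)
    }
})

test_that("the closed form matches the geometric orthogonal-SS minimizer", {
    set.seed(3)
    for (i in 1:40) {
        x <- rnorm(20, sd = runif(1, 0.5, 3))
        y <- runif(1, -2, 2) * x + rnorm(20, sd = runif(1, 0.2, 2))
        fit <- deming_fit(x, y)
        want <- oracle_deming_orth(x, y)
        expect_equal(fit$slope, want$slope, tolerance = 1e-6)
        expect_equal(fit$intercept, want$intercept, tolerance = 1e-6)
    }
})

test_that("the fitted line is a local optimum of the orthogonal SS", {
    set.seed(13)
    x <- rnorm(30); y <- x + rnorm(30, sd = 0.4)
    fit <- deming_fit(x, y)
    oss <- function(b, a) sum((y - b * x - a)^2) / (1 + b^2)
    base <- oss(fit$slope, fit$intercept)
    for (eps in c(1e-3, -1e-3)) {
        expect_gt(oss(fit$slope + eps, fit$intercept), base)
        expect_gt(oss(fit$slope, fit$intercept + eps), base)
    }
})

test_that("degenerate and undersized inputs are rejected", {
    expect_error(deming_fit(c(1, 2), c(1, 2)), "at least 3")
    expect_error(deming_fit(rep(1, 5), rep(2, 5)), "constant")
    # s_xy = 0 with s_yy = lambda * s_xx
    x <- c(-1, 0, 1, 0); y <- c(0, 1, 0, -1)
    expect_error(deming_fit(x, y), "undefined")
})

test_that("orthogonal residuals measure signed perpendicular distance", {
    # slope 1, intercept 0: point (0, 2) lies sqrt(2) above the line
    fit <- list(slope = 1, intercept = 0)
    res <- orthogonal_residuals(c(0, 1, 4), c(2, 1, 4), fit)
    expect_equal(res$residual[1], sqrt(2), tolerance = 1e-12)
    expect_equal(res$residual[2:3], c(0, 0))
    # normalized residuals have unit sample SD whenever SD > 0
    set.seed(4)
    x <- rnorm(30); y <- x + rnorm(30)
    f2 <- deming_fit(x, y)
    nr <- orthogonal_residuals(x, y, f2)$normalized_residual
    expect_equal(sd(nr), 1, tolerance = 1e-12)
    expect_lt(abs(mean(orthogonal_residuals(x, y, f2)$residual)),
              1e-8 * sd(orthogonal_residuals(x, y, f2)$residual))
})

test_that("top-decile selection sizes and tie-breaks are deterministic", {
    ids <- sprintf("m%02d", 1:10)
    mask <- select_top_decile(9:0, ids)
    expect_equal(sum(mask), 1L)              # ceil(0.1 * 10)
    expect_true(mask[1])

    ids405 <- sprintf("m%03d", 1:405)
    expect_equal(sum(select_top_decile(rnorm(405), ids405)), 41L)

    # all-equal residuals fall back to lexicographic ids
    tied <- select_top_decile(rep(1, 10), rev(ids))
    expect_equal(rev(ids)[tied], sort(ids)[1])
    expect_equal(select_top_decile(numeric(), character()), logical())
})

test_that("ranking is by absolute residual with sign retained", {
    nr <- c(a = -5, b = 4, c = 0.1, d = -0.2, e = 1, f = 0, g = 0.3,
            h = -0.4, i = 0.2, j = 0.25)
    mask <- select_top_decile(nr, names(nr))
    expect_equal(names(nr)[mask], "a")
})

test_that("jackknife 90% band collapses on colinear input and grows with noise", {
    x <- 1:10
    band0 <- ci90_band(x, 2 * x + 3, deming_fit(x, 2 * x + 3))
    expect_equal(band0$half_width, rep(0, 100), tolerance = 1e-9)
    expect_true(all(band0$half_width >= 0))

    set.seed(6)
    widths <- vapply(c(0.1, 0.5, 1.0), function(s) {
        mean(vapply(1:20, function(i) {
            x <- rnorm(25); y <- x + rnorm(25, sd = s)
            mean(ci90_band(x, y, deming_fit(x, y))$half_width)
        }, 0))
    }, 0)
    expect_true(all(diff(widths) > 0))
    expect_error(ci90_band(1:4, 1:4, list(slope = 1, intercept = 0, lambda = 1)),
                 "at least 5")
})

test_that("average-linkage clustering matches the naive agglomeration oracle", {
    set.seed(7)
    for (i in 1:30) {
        m <- matrix(rnorm(18), 6, 3)
        got <- hcluster_mean_linkage(m)
        expect_equal(sort(got$linkage$height),
                     sort(oracle_average_linkage_heights(m)),
                     tolerance = 1e-9)
    }
    # identical rows merge first at height 0
    m <- rbind(c(1, 1, 1), c(5, 0, 2), c(1, 1, 1), c(9, 9, 9))
    hc <- hcluster_mean_linkage(m)$linkage
    expect_equal(hc$height[1], 0)
    expect_equal(sort(abs(hc$merge[1, ])), c(1, 3))
    # permutation invariance of the merge-height multiset
    perm <- c(3, 1, 4, 2)
    expect_equal(sort(hcluster_mean_linkage(m[perm, ])$linkage$height),
                 sort(hc$height), tolerance = 1e-12)
    # single row: trivial result
    expect_equal(hcluster_mean_linkage(m[1, , drop = FALSE])$row_order, 1L)
})

fake_enrich <- function(ids, nlp, label) {
    data.frame(motif_id = ids, region_set_label = label,
               n_target = 10L, k_target = 1L, n_background = 10L,
               k_background = 1L, p_value = 10^(-nlp), neg_log10_p = nlp,
               stringsAsFactors = FALSE)
}

test_that("identical enrichment vectors yield an all-zero heatmap via the tie rule", {
    ids <- sprintf("m%02d", 1:20)
    nlp <- seq(0.5, 10, length.out = 20)
    res <- run_differential_analysis(fake_enrich(ids, nlp, "lo"),
                                     fake_enrich(ids, nlp, "hi"),
                                     fake_enrich(ids, nlp, "lps"))
    for (cmp in res$comparisons) {
        expect_equal(cmp$residual, setNames(rep(0, 20), ids), tolerance = 1e-9)
        expect_equal(sum(cmp$top_decile), 2L)  # ceil(0.1 * 20)
        # tie rule: lexicographically first ids
        expect_equal(sort(ids)[1:2], ids[cmp$top_decile])
    }
    expect_true(all(res$heatmap$matrix == 0))
})

test_that("mismatched motif sets are rejected with the symmetric difference", {
    ids <- sprintf("m%02d", 1:10)
    e1 <- fake_enrich(ids, 1:10, "lo")
    e2 <- fake_enrich(ids[-3], (1:10)[-3], "hi")
    expect_error(run_differential_analysis(e1, e2, e1), "m03")
})

test_that("a differentially planted motif is recovered toward the LPS state", {
    hits <- 0L
    for (s in 1:4) {
        bench <- simulate_motif_benchmark(n_motifs = 30, peaks_per_state = 200,
                                          seed = s)
        pipe <- run_motif_pipeline(bench$data$peak_sets, bench$data$sequences,
                                   bench$library, seed = s + 50)
        ids <- sort(vapply(bench$library, `[[`, "", "motif_id"))
        f <- match(bench$focal_motif, ids)
        ok <- vapply(pipe$diff$comparisons[c("lo_vs_lps", "hi_vs_lps")],
                     function(cmp) cmp$top_decile[f] &&
                         cmp$normalized_residual[f] > 0, logical(1))
        if (all(ok)) hits <- hits + 1L
    }
    expect_gte(hits, 3L)
})

test_that("removing a non-selected motif leaves the selection stable", {
    set.seed(31)
    ids <- sprintf("m%02d", 1:30)
    x <- rexp(30); y <- x + rnorm(30, sd = 0.2); z <- x + rnorm(30, sd = 0.2)
    res <- run_differential_analysis(fake_enrich(ids, x, "lo"),
                                     fake_enrich(ids, y, "hi"),
                                     fake_enrich(ids, z, "lps"))
    drop <- setdiff(ids, res$heatmap$motifs)[1]
    keep <- ids != drop
    res2 <- run_differential_analysis(fake_enrich(ids[keep], x[keep], "lo"),
                                      fake_enrich(ids[keep], y[keep], "hi"),
                                      fake_enrich(ids[keep], z[keep], "lps"))
    expect_gte(length(intersect(res$heatmap$motifs, res2$heatmap$motifs)),
               length(res$heatmap$motifs) - 1L)
})
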