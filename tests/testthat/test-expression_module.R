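test_that("quantile normalization matches rank means, is idempotent, and a fixed point", {
    m <- cbind(s1 = c(2, 4, 6), s2 = c(1, 5, 9), s3 = c(0, 6, 12))
    rownames(m) <- paste0("g", 1:3)
    qn <- quantile_normalize(m)
    # rank means: (2+1+0)/3, (4+5+6)/3, (6+9+12)/3
    for (j in 1:3) expect_equal(unname(qn[, j]), c(1, 5, 9))

    # defining property: sorted columns identical
    set.seed(1)
    r <- matrix(rnorm(200), 40, 5,
                dimnames = list(paste0("g", 1:40), paste0("s", 1:5)))
    qr <- quantile_normalize(r)
    for (j in 2:5)
        expect_equal(sort(qr[, j]), sort(qr[, 1]), tolerance = 1e-12,
                     ignore_attr = TRUE)
    # idempotent
    expect_equal(quantile_normalize(qr), qr, tolerance = 1e-12)
    # identical columns are a fixed point
    same <- matrix(rep(c(3, 1, 7, 5), 3), 4, 3,
                   dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
    expect_equal(quantile_normalize(same), same, tolerance = 1e-12)
    expect_error(quantile_normalize(r[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("ties within a column receive the mean of their tied reference values", {
    m <- cbind(s1 = c(1, 1, 10), s2 = c(2, 4, 6))
    rownames(m) <- paste0("g", 1:3)
    qn <- quantile_normalize(m)
    ref <- c(mean(c(1, 2)), mean(c(1, 4)), mean(c(10, 6)))
    expect_equal(unname(qn[1:2, "s1"]), rep(mean(ref[1:2]), 2))
})

test_that("probe summarization takes element-wise medians per gene id", {
    m <- matrix(c(1, 3, 11, 5,
                  2, 2, 2, 2), ncol = 2,
                dimnames = list(c("gA", "gA", "gA", "gB"), c("s1", "s2")))
    out <- summarize_probes(m)
    expect_equal(out["gA", "s1"], 3)       # odd count
    expect_equal(out["gB", "s1"], 5)
    m2 <- matrix(c(1, 3), 2, 1, dimnames = list(c("gA", "gA"), "s1"))
    expect_equal(unname(summarize_probes(m2)["gA", 1]), 2)  # even count midpoint
    # single probe per gene: identity
    solo <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
    expect_equal(summarize_probes(solo), solo)
})

test_that("replicate averaging equals a per-cell loop oracle", {
    set.seed(2)
    m <- matrix(rnorm(35), 5, 7,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:7)))
    pops <- c("a", "a", "b", "b", "b", "c", "c")
    out <- average_replicates(m, pops)
    for (g in 1:5) for (p in unique(pops))
        expect_equal(out[g, p], mean(m[g, pops == p]))
    # trivial cases
    expect_equal(unname(average_replicates(cbind(x = c(2, 1)),
                                           "p1")[, 1]), c(2, 1))
    expect_equal(unname(average_replicates(rbind(g = c(2, 4)),
                                           c("p", "p"))[1, 1]), 3)
    expect_error(average_replicates(m, pops[1:3]), "one population")
})

pearson_p_from_r_test <- function(r, n) regstate:::pearson_p_from_r(r, n)

test_that("Pearson p-values match cor.test and the t-tail quadrature", {
    x <- c(1, 2, 4, 3, 6, 5, 8, 7, 10, 9)
    set.seed(3)
    y <- x + rnorm(10, sd = 2)
    got <- pearson_with_p(x, y)
    ct <- cor.test(x, y)
    expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(got$p, ct$p.value, tolerance = 1e-12)

    # quadrature oracle for the two-sided t(n-2) tail at r = 0.6, n = 10
    r <- 0.6; n <- 10
    tobs <- r * sqrt((n - 2) / (1 - r^2))
    tail <- integrate(function(t) dt(t, df = n - 2), tobs, Inf,
                      rel.tol = 1e-12)$value
    expect_equal(pearson_p_from_r_test(r, n), 2 * tail, tolerance = 1e-8)

    expect_equal(pearson_with_p(x, x), list(r = 1, p = 0))
    expect_equal(pearson_with_p(x, -x), list(r = -1, p = 0))
    expect_error(pearson_with_p(1:3, 1:3), "at least 4")
    expect_error(pearson_with_p(1:5, rep(1, 5)), "constant")
})

test_that("BH adjustment follows the step-up formula", {
    expect_equal(bh_adjust(0.03), 0.03)
    expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    set.seed(4)
    p <- runif(50)^2
    q <- bh_adjust(p)
    expect_equal(q, manual_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    # the smallest p attains the smallest q (ties permitted)
    expect_equal(q[which.min(p)], min(q))
    ord <- order(p)
    expect_true(!is.unsorted(q[ord]))
    expect_error(bh_adjust(c(0.5, 1.2)))
})

test_that("seed-module extraction finds duplicates, skips constants, honors alpha", {
    set.seed(5)
    pops <- sprintf("p%02d", 1:10)
    seed_prof <- rnorm(10)
    vals <- rbind(seed = seed_prof,
                  dup = seed_prof,
                  flat = rep(2, 10),
                  noise1 = rnorm(10), noise2 = rnorm(10))
    colnames(vals) <- pops
    mod <- extract_seed_module(vals, "seed", alpha = 0.0005)
    expect_true("dup" %in% mod$members)
    expect_equal(mod$skipped, "flat")
    expect_false("flat" %in% mod$table$gene_id)     # outside the BH family
    expect_false("seed" %in% mod$table$gene_id)     # seed excluded
    r_dup <- mod$table$r[mod$table$gene_id == "dup"]
    expect_equal(r_dup, 1, tolerance = 1e-12)
    expect_equal(mod$table$q[mod$table$gene_id == "dup"], 0)

    # alpha = 1 admits every tested gene; alpha = 0 only exact q = 0
    expect_setequal(extract_seed_module(vals, "seed", alpha = 1)$members,
                    c("dup", "noise1", "noise2"))
    expect_equal(extract_seed_module(vals, "seed", alpha = 0)$members, "dup")
    expect_error(extract_seed_module(vals, "flat"),
                 "not present|constant")
    vals2 <- vals; rownames(vals2)[3] <- "flat2"
    expect_error(extract_seed_module(vals2[, 1:3], "seed"), "4 populations")
})

test_that("module members are Z-transformed across populations for display", {
    set.seed(6)
    pops <- sprintf("p%02d", 1:8)
    seed_prof <- rnorm(8)
    vals <- rbind(seed = seed_prof, dup = 3 * seed_prof + 10,
                  n1 = rnorm(8))
    colnames(vals) <- pops
    mod <- extract_seed_module(vals, "seed", alpha = 0.05)
    z <- mod$zscore_matrix["dup", ]
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("planted co-expression modules are recovered with high sensitivity", {
    sens <- fdp <- numeric(4)
    for (s in 1:4) {
        cfg <- coexpr_sim_config(n_genes = 1500, n_populations = 27,
                                 module_size = 50, module_rho = 0.9, seed = s)
        dat <- gen_coexpression_data(cfg)
        mod <- extract_seed_module(dat$expr, "seed_gene", alpha = 0.0005)
        sens[s] <- mean(dat$truth %in% mod$members)
        fdp[s] <- if (length(mod$members))
            mean(!mod$members %in% dat$truth) else 0
    }
    expect_gte(mean(sens), 0.9)
    expect_lte(mean(fdp), 0.1)
})

test_that("self-comparison across platforms is symmetric with unit diagonal", {
    set.seed(7)
    m <- matrix(rnorm(60 * 4), 60, 4,
                dimnames = list(paste0("g", 1:60), paste0("s", 1:4)))
    res <- cross_platform_compare(m, m)
    expect_equal(res$correlation, t(res$correlation), tolerance = 1e-12)
    expect_equal(unname(diag(res$correlation)), rep(1, 8), tolerance = 1e-12)
    # a sample duplicated across platforms correlates at exactly 1
    expect_equal(unname(res$correlation[1, 5]), 1, tolerance = 1e-12)
    expect_error(cross_platform_compare(m[1:10, ], m[1:10, ]),
                 "10 shared genes")
})

test_that("Z-scoring makes cross-platform comparison affine-invariant", {
    recovered <- 0L
    for (s in 1:10) {
        set.seed(s)
        signal <- matrix(rnorm(80 * 5), 80, 5,
                         dimnames = list(paste0("G", 1:80),
                                         paste0("pop", 1:5)))
        a <- signal + matrix(rnorm(400, sd = 0.2), 80)
        b <- 3.1 * (signal + matrix(rnorm(400, sd = 0.2), 80)) - 7
        colnames(a) <- paste0("A_", colnames(signal))
        colnames(b) <- paste0("B_", colnames(signal))
        rownames(b) <- tolower(rownames(signal))  # case-insensitive matching
        res <- cross_platform_compare(a, b, min_shared = 50)
        cc <- res$correlation[1:5, 6:10]
        if (all(apply(cc, 1, which.max) == 1:5)) recovered <- recovered + 1L
    }
    expect_gte(recovered, 9L)
})
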