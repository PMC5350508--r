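#' Quantile normalization of an expression matrix
#'
#' Forces every sample (column) onto the common reference distribution of
#' rank means: each column's sorted values are replaced by the across-column
#' mean of sorted values at that rank, reassigned by the column's original
#' ranks; ties within a column receive the mean of their tied reference
#' values.  Idempotent, and a fixed point when all columns are already
#' identical.  Delegates to [limma::normalizeQuantiles()] with tie
#' averaging.
#'
#' @param mat numeric gene x sample matrix (>= 2 samples, no missing
#'   values), or an [expression_matrix()].
#' @return Normalized object of the same type as the input.
#' @export
quantile_normalize <- function(mat) {
    em <- inherits(mat, "ExpressionMatrix")
    values <- if (em) mat$values else as.matrix(mat)
    if (ncol(values) < 2L) stop("quantile normalization needs >= 2 samples")
    if (anyNA(values)) stop("missing values in expression matrix")
    norm <- limma::normalizeQuantiles(values, ties = TRUE)
    dimnames(norm) <- dimnames(values)
    if (em) { mat$values <- norm; mat } else norm
}

#' Collapse duplicate gene ids by element-wise median
#'
#' Microarray probe-level summarization: every gene id maps to the per-sample
#' median over its probes (midpoint convention for even counts).  Row order
#' follows the first occurrence of each gene id.
#'
#' @param x [expression_matrix()] (possibly flagged with duplicate gene ids)
#'   or bare matrix.
#' @return Object of the input type with one row per gene id.
#' @export
summarize_probes <- function(x) {
    em <- inherits(x, "ExpressionMatrix")
    values <- if (em) x$values else as.matrix(x)
    genes <- rownames(values)
    if (anyDuplicated(genes) == 0L) {
        if (em) x$duplicated_genes <- FALSE
        return(x)
    }
    uniq <- unique(genes)
    out <- matrix(NA_real_, length(uniq), ncol(values),
                  dimnames = list(uniq, colnames(values)))
    for (g in uniq) {
        rows <- values[genes == g, , drop = FALSE]
        out[g, ] <- apply(rows, 2L, median)
    }
    if (em) expression_matrix(out, x$sample_meta) else out
}

#' Average biological replicates into population means
#'
#' One output column per population, the arithmetic mean of its replicate
#' columns.
#'
#' @param x [expression_matrix()] whose `sample_meta` has a `population`
#'   column, or a bare matrix with `populations` supplied.
#' @param populations character vector aligned with the columns of `x`
#'   (ignored for an `ExpressionMatrix`).
#' @return Gene x population matrix of means, populations in first-seen
#'   order.
#' @export
average_replicates <- function(x, populations = NULL) {
    if (inherits(x, "ExpressionMatrix")) {
        if (!"population" %in% names(x$sample_meta))
            stop("sample_meta lacks a population column")
        populations <- x$sample_meta$population
        values <- x$values
    } else values <- as.matrix(x)
    if (is.null(populations) || length(populations) != ncol(values))
        stop("need one population label per sample")
    if (anyNA(populations)) stop("population with no label")
    pops <- unique(populations)
    out <- vapply(pops, function(p)
        rowMeans(values[, populations == p, drop = FALSE]),
        numeric(nrow(values)))
    matrix(out, nrow = nrow(values), dimnames = list(rownames(values), pops))
}

#' Pearson correlation with a two-sided t-test p-value
#'
#' `p` is the two-sided tail of `t = r * sqrt((n-2) / (1-r^2))` on `n - 2`
#' degrees of freedom; perfectly (anti)correlated input gives `p = 0`.
#'
#' @param x,y numeric vectors, length >= 4, neither constant.
#' @return List with `r` and `p`.
#' @export
pearson_with_p <- function(x, y) {
    n <- length(x)
    stopifnot(length(y) == n)
    if (n < 4L) stop("need at least 4 observations")
    if (sd(x) == 0 || sd(y) == 0) stop("constant vector: correlation undefined")
    r <- cor(x, y)
    list(r = r, p = pearson_p_from_r(r, n))
}

pearson_p_from_r <- function(r, n) {
    p <- numeric(length(r))
    exact <- abs(r) >= 1 - 1e-15
    p[exact] <- 0
    t <- r[!exact] * sqrt((n - 2) / (1 - r[!exact]^2))
    p[!exact] <- 2 * pt(-abs(t), df = n - 2)
    p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (`q_(i) = min_{j>=i} m p_(j) / j`, clipped at 1,
#' returned in input order) via [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Vector of adjusted p-values (q-values).
#' @export
bh_adjust <- function(p) {
    stopifnot(all(p >= 0 & p <= 1))
    p.adjust(p, method = "BH")
}

#' Seed-gene co-expression module discovery
#'
#' Correlates every other gene with a seed gene (e.g. *Aldh1a2*) across
#' population-mean expression profiles, BH-adjusts the two-sided correlation
#' p-values over all tested genes, and reports the module of genes with
#' `q <= alpha`.  Constant (zero-variance) genes cannot be tested and are
#' recorded as skipped, outside the BH family; the seed itself is excluded.
#' A per-gene Z-scored member matrix (across populations) is returned for
#' heatmap display.
#'
#' @param expr gene x population matrix of means (see
#'   [average_replicates()]) or an `ExpressionMatrix` thereof.
#' @param seed_gene gene id present in `expr`; must not be constant.
#' @param alpha module q-value threshold (default 0.0005).
#' @return List of class `ModuleResult`: `seed_gene`, `alpha`, `table`
#'   (gene_id, r, p, q, member), `members`, `skipped`, `zscore_matrix`
#'   (members x populations).
#' @export
extract_seed_module <- function(expr, seed_gene, alpha = 0.0005) {
    values <- if (inherits(expr, "ExpressionMatrix")) expr$values else
        as.matrix(expr)
    if (ncol(values) < 4L) stop("need at least 4 populations")
    if (!seed_gene %in% rownames(values))
        stop("seed gene '", seed_gene, "' not present")
    seed_profile <- values[seed_gene, ]
    if (sd(seed_profile) == 0) stop("seed gene is constant")
    others <- values[setdiff(rownames(values), seed_gene), , drop = FALSE]
    sds <- apply(others, 1L, sd)
    skipped <- rownames(others)[sds == 0]
    tested <- others[sds > 0, , drop = FALSE]
    n <- ncol(values)
    r <- as.vector(cor(t(tested), seed_profile))
    p <- pearson_p_from_r(r, n)
    q <- bh_adjust(p)
    tab <- data.frame(gene_id = rownames(tested), r = r, p = p, q = q,
                      member = q <= alpha, stringsAsFactors = FALSE)
    tab <- tab[order(tab$q, tab$p, tab$gene_id), ]
    rownames(tab) <- NULL
    members <- tab$gene_id[tab$member]
    zmat <- if (length(members)) {
        m <- values[members, , drop = FALSE]
        t(scale(t(m)))
    } else matrix(numeric(), 0L, ncol(values),
                  dimnames = list(NULL, colnames(values)))
    structure(list(seed_gene = seed_gene, alpha = alpha, table = tab,
                   members = members, skipped = skipped,
                   zscore_matrix = zmat),
              class = "ModuleResult")
}

#' Cross-platform expression comparison via per-platform Z-scores
#'
#' Restricts two platforms' matrices to their shared genes (case-insensitive
#' symbol matching), Z-scores each gene within each platform (across that
#' platform's samples) to strip platform-specific affine distortions, then
#' correlates all sample pairs on the concatenated matrix and clusters the
#' samples with average linkage.
#'
#' @param expr_a,expr_b gene x sample matrices (or `ExpressionMatrix`
#'   objects) from two platforms.
#' @param min_shared minimum number of shared genes (default 50).
#' @return List of class `CrossPlatformResult`: `shared_genes`,
#'   `correlation` (sample x sample Pearson matrix), `platform` (per-sample
#'   labels), `linkage`, `sample_order`.
#' @export
cross_platform_compare <- function(expr_a, expr_b, min_shared = 50L) {
    va <- if (inherits(expr_a, "ExpressionMatrix")) expr_a$values else
        as.matrix(expr_a)
    vb <- if (inherits(expr_b, "ExpressionMatrix")) expr_b$values else
        as.matrix(expr_b)
    key_a <- toupper(rownames(va)); key_b <- toupper(rownames(vb))
    shared <- intersect(key_a, key_b)
    if (length(shared) < min_shared)
        stop("only ", length(shared), " shared genes (need >= ", min_shared, ")")
    za <- zscore_rows(va[match(shared, key_a), , drop = FALSE])
    zb <- zscore_rows(vb[match(shared, key_b), , drop = FALSE])
    combined <- cbind(za, zb)
    rownames(combined) <- shared
    correlation <- cor(combined)
    clust <- hcluster_mean_linkage(t(combined))
    structure(list(shared_genes = shared, correlation = correlation,
                   platform = rep(c("A", "B"), c(ncol(za), ncol(zb))),
                   linkage = clust$linkage,
                   sample_order = clust$row_order),
              class = "CrossPlatformResult")
}

# Per-gene Z-score across samples; constant rows map to 0.
zscore_rows <- function(m) {
    mu <- rowMeans(m)
    s <- apply(m, 1L, sd)
    s[s == 0] <- 1
    (m - mu) / s
}
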