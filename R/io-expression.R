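#' Construct an expression matrix
#'
#' Gene x sample numeric table (log2 scale unless stated otherwise) with
#' per-sample metadata, shared by module discovery, the time course and
#' cross-platform comparison.
#'
#' @param values numeric matrix, rownames = gene ids, colnames = sample ids.
#' @param sample_meta data.frame with a `sample_id` column and optionally
#'   `population`, `replicate`, `time_h`, `platform`; one row per sample.
#'   Defaults to a bare frame of the sample ids.
#' @return Object of class `ExpressionMatrix`: list with `values`,
#'   `sample_meta` and `duplicated_genes` (TRUE when gene ids repeat,
#'   flagging the matrix for [summarize_probes()]).
#' @export
expression_matrix <- function(values, sample_meta = NULL) {
    values <- as.matrix(values)
    if (!is.numeric(values)) stop("expression values must be numeric")
    if (any(!is.finite(values))) stop("expression values must be finite")
    if (is.null(rownames(values))) stop("values need gene ids as rownames")
    if (is.null(colnames(values))) stop("values need sample ids as colnames")
    if (is.null(sample_meta))
        sample_meta <- data.frame(sample_id = colnames(values),
                                  stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(sample_meta))
        stop("sample_meta needs a sample_id column")
    missing <- setdiff(colnames(values), sample_meta$sample_id)
    if (length(missing))
        stop("samples without metadata: ", paste(missing, collapse = ", "))
    sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ,
                               drop = FALSE]
    rownames(sample_meta) <- NULL
    structure(list(values = values, sample_meta = sample_meta,
                   duplicated_genes = anyDuplicated(rownames(values)) > 0L),
              class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
    cat(sprintf("ExpressionMatrix: %d genes x %d samples%s\n",
                nrow(x$values), ncol(x$values),
                if (x$duplicated_genes) " (duplicate gene ids present)" else ""))
    invisible(x)
}

#' Read a gene x sample expression TSV
#'
#' First column gene ids, header row sample ids.  Duplicate gene ids are
#' retained and flagged (they are collapsed later by [summarize_probes()]);
#' non-numeric cells are an error naming the offending (row, column).
#'
#' @param path path to the TSV.
#' @param sample_meta optional sample metadata; samples present in the table
#'   but absent from the metadata are rejected.
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, sample_meta = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character")
    if (ncol(tab) < 2L) stop("expression table needs gene ids plus >=1 sample")
    genes <- tab[[1L]]
    raw <- as.matrix(tab[, -1L, drop = FALSE])
    num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
    if (anyNA(num)) {
        idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
        stop("non-numeric cell at gene '", genes[idx[1L]], "', sample '",
             colnames(raw)[idx[2L]], "'")
    }
    dimnames(num) <- list(genes, colnames(raw))
    expression_matrix(num, sample_meta)
}

#' Write an expression matrix as TSV
#'
#' @param x an `ExpressionMatrix` or bare numeric matrix with dimnames.
#' @param path output path.
#' @param gene_col header for the gene-id column.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, gene_col = "gene_id") {
    values <- if (inherits(x, "ExpressionMatrix")) x$values else as.matrix(x)
    df <- data.frame(gene = rownames(values),
                     format(values, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(df)[1L] <- gene_col
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
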