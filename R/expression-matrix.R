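#' Construct a cells x genes expression matrix
#'
#' The basic data container of the package: a numeric matrix with cells in
#' rows and genes in columns, plus a flag recording whether the values are
#' natural-log transformed counts. All downstream functions (filtering,
#' augmentation, model fitting) consume this class.
#'
#' @param values Numeric matrix, `n` cells x `m` genes, nonnegative, no
#'   missing values.
#' @param gene_names Character vector of `m` unique gene names. Defaults to
#'   `colnames(values)`.
#' @param cell_ids Character vector of `n` unique cell identifiers. Defaults
#'   to `rownames(values)`, or `cell_1 ... cell_n` when absent.
#' @param log_transformed Logical flag; `TRUE` when values are ln(count + 1).
#'
#' @return An `expression_matrix`: a numeric matrix with dimnames and a
#'   `log_transformed` attribute.
#' @export
#' @examples
#' x <- expression_matrix(matrix(0:5, 2, 3), gene_names = c("g1", "g2", "g3"))
#' n_cells(x)
#' n_genes(x)
expression_matrix <- function(values, gene_names = NULL, cell_ids = NULL,
                              log_transformed = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  m <- ncol(values)
  if (is.null(gene_names)) gene_names <- colnames(values)
  if (is.null(gene_names)) {
    stop("gene names are required (supply `gene_names` or matrix colnames)",
         call. = FALSE)
  }
  if (is.null(cell_ids)) cell_ids <- rownames(values)
  if (is.null(cell_ids)) {
    cell_ids <- if (n > 0) paste0("cell_", seq_len(n)) else character(0)
  }
  gene_names <- as.character(gene_names)
  cell_ids <- as.character(cell_ids)
  if (length(gene_names) != m) {
    stop("length of gene_names (", length(gene_names),
         ") does not match number of columns (", m, ")", call. = FALSE)
  }
  if (length(cell_ids) != n) {
    stop("length of cell_ids (", length(cell_ids),
         ") does not match number of rows (", n, ")", call. = FALSE)
  }
  if (anyDuplicated(gene_names)) {
    dups <- unique(gene_names[duplicated(gene_names)])
    stop("duplicate gene names: ", paste(utils::head(dups, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(cell_ids)) {
    stop("duplicate cell ids", call. = FALSE)
  }
  if (anyNA(values)) stop("expression values contain missing entries", call. = FALSE)
  if (m > 0 && n > 0 && min(values) < 0) {
    stop("expression values must be nonnegative", call. = FALSE)
  }
  dimnames(values) <- list(cell_ids, gene_names)
  structure(values,
            log_transformed = isTRUE(log_transformed),
            class = c("expression_matrix", "matrix", "array"))
}

#' @rdname expression_matrix
#' @param x An `expression_matrix`.
#' @export
n_cells <- function(x) nrow(x)

#' @rdname expression_matrix
#' @export
n_genes <- function(x) ncol(x)

#' @rdname expression_matrix
#' @export
gene_names <- function(x) colnames(x)

#' @rdname expression_matrix
#' @export
cell_ids <- function(x) rownames(x)

#' @rdname expression_matrix
#' @export
is_log_transformed <- function(x) isTRUE(attr(x, "log_transformed"))

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d cells x %d genes (%s)\n",
              nrow(x), ncol(x),
              if (is_log_transformed(x)) "log-transformed" else "raw counts"))
  if (nrow(x) > 0 && ncol(x) > 0) {
    k <- min(5L, nrow(x)); l <- min(5L, ncol(x))
    print(unclass(x)[seq_len(k), seq_len(l), drop = FALSE])
    if (nrow(x) > k || ncol(x) > l) cat("...\n")
  }
  invisible(x)
}

# internal: plain matrix view (drops class, keeps dimnames)
expr_values <- function(x) {
  y <- unclass(x)
  attr(y, "log_transformed") <- NULL
  y
}

# internal: rebuild an expression_matrix from a subset of an existing one
expr_like <- function(values, template, log_transformed = is_log_transformed(template)) {
  expression_matrix(values, gene_names = colnames(values),
                    cell_ids = rownames(values),
                    log_transformed = log_transformed)
}

#' Convert an expression matrix to a long tibble
#'
#' @param x An `expression_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `cell`, `gene`, `value`.
#' @export
as_tibble.expression_matrix <- function(x, ...) {
  tibble::tibble(
    cell = rep(rownames(x), times = ncol(x)),
    gene = rep(colnames(x), each = nrow(x)),
    value = as.vector(unclass(x))
  )
}
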