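#' Read an expression matrix from delimited text or MatrixMarket files
#'
#' Delimited input must have a header row of gene names and one row of
#' values per cell (comma or tab separated, auto-detected from the header).
#' MatrixMarket input is a coordinate-format `.mtx` triplet file with
#' plain-text sidecar files giving gene names and cell ids, one per line.
#' Matrices are always returned cells-in-rows, genes-in-columns; inputs
#' stored genes x cells must be read with `transpose = TRUE` — orientation
#' is never guessed.
#'
#' @param path Path to the delimited file or `.mtx` file.
#' @param format One of `"auto"`, `"delimited"`, `"mtx"`. `"auto"` picks
#'   `"mtx"` for a `.mtx` extension, `"delimited"` otherwise.
#' @param gene_file,cell_file Sidecar paths for MTX input. Default to
#'   `<path minus .mtx>_genes.txt` and `_cells.txt`.
#' @param transpose If `TRUE` the file stores genes in rows and is
#'   transposed after reading.
#'
#' @return An [expression_matrix()] with `is_log_transformed = FALSE`.
#' @export
read_expression <- function(path, format = c("auto", "delimited", "mtx"),
                            gene_file = NULL, cell_file = NULL,
                            transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "delimited"
  }
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    if (is.null(gene_file)) gene_file <- paste0(stem, "_genes.txt")
    if (is.null(cell_file)) cell_file <- paste0(stem, "_cells.txt")
    for (f in c(gene_file, cell_file)) {
      if (!file.exists(f)) stop("sidecar file not found: ", f, call. = FALSE)
    }
    mm <- as.matrix(Matrix::readMM(path))
    genes <- readLines(gene_file)
    cells <- readLines(cell_file)
    if (transpose) mm <- t(mm)
    if (nrow(mm) != length(cells) || ncol(mm) != length(genes)) {
      stop(sprintf(
        "MTX dimensions (%d x %d) do not match sidecars (%d cells, %d genes)",
        nrow(mm), ncol(mm), length(cells), length(genes)), call. = FALSE)
    }
    dimnames(mm) <- list(cells, genes)
    return(expression_matrix(mm, log_transformed = FALSE))
  }

  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path, call. = FALSE)
  delim <- if (grepl("\t", header)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_double()), progress = FALSE,
    show_col_types = FALSE, name_repair = "minimal")
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    stop(sprintf("malformed delimited file %s: parse failure at line %d (%s)",
                 path, probs$row[1], probs$expected[1]), call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("no data rows in ", path, call. = FALSE)
  genes <- names(tab)
  if (anyDuplicated(genes)) {
    stop("duplicate gene names in header of ", path, call. = FALSE)
  }
  mm <- as.matrix(tab)
  if (transpose) {
    # file is genes x cells: header holds cell ids, rows are genes
    cells <- genes
    mm <- t(mm)
    dimnames(mm) <- list(cells, paste0("gene_", seq_len(ncol(mm))))
  } else {
    dimnames(mm) <- list(paste0("cell_", seq_len(nrow(mm))), genes)
  }
  expression_matrix(mm, log_transformed = FALSE)
}

#' Write an expression matrix to delimited text or MatrixMarket files
#'
#' Inverse of [read_expression()]: `read_expression(write_expression(x, p))`
#' reproduces `x` for both formats.
#'
#' @param x An [expression_matrix()].
#' @param path Output path (`.mtx` implies MatrixMarket with sidecars).
#' @param format As in [read_expression()].
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("auto", "delimited", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "delimited"
  }
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    Matrix::writeMM(Matrix::Matrix(expr_values(x), sparse = TRUE), path)
    writeLines(gene_names(x), paste0(stem, "_genes.txt"))
    writeLines(cell_ids(x), paste0(stem, "_cells.txt"))
  } else {
    df <- as.data.frame(expr_values(x))
    readr::write_csv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' Natural-log transform raw counts
#'
#' Replaces every raw count v by ln(v + 1), the normalization the model
#' expects. Zeros map to zero, so dropout events keep the value 0 in log
#' space. Refuses to run twice on the same matrix.
#'
#' @param x An [expression_matrix()] of raw counts.
#' @return The transformed [expression_matrix()] with
#'   `is_log_transformed = TRUE`.
#' @export
log_transform <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (is_log_transformed(x)) {
    stop("matrix is already log-transformed; refusing to transform twice",
         call. = FALSE)
  }
  y <- log1p(expr_values(x))
  expression_matrix(y, log_transformed = TRUE)
}

#' Quality-control filter on cells
#'
#' Retains cells whose number of detected genes (raw count > 0) lies in
#' `[min_genes, max_genes]`, whose total UMI count is at most `max_umi`,
#' and whose fraction of counts on mitochondrial genes is at most
#' `max_mito_frac`. Defaults follow common practice for droplet data:
#' 400--3000 detected genes, <= 10000 UMIs, <= 3% mitochondrial reads.
#' All bounds are inclusive.
#'
#' @param x An [expression_matrix()] of raw counts (not log-transformed).
#' @param min_genes,max_genes Bounds on unique detected genes per cell.
#' @param max_umi Maximum total raw counts per cell.
#' @param max_mito_frac Maximum fraction of counts on mitochondrial genes.
#' @param mito_predicate Function mapping gene names to logical, marking
#'   mitochondrial genes. Default: case-insensitive prefix `"mt-"`.
#' @return The filtered [expression_matrix()].
#' @export
filter_cells <- function(x, min_genes = 400, max_genes = 3000,
                         max_umi = 10000, max_mito_frac = 0.03,
                         mito_predicate = default_mito_predicate) {
  stopifnot(inherits(x, "expression_matrix"))
  if (is_log_transformed(x)) {
    stop("filter_cells expects raw counts, not a log-transformed matrix",
         call. = FALSE)
  }
  v <- expr_values(x)
  detected <- rowSums(v > 0)
  total <- rowSums(v)
  mito <- mito_predicate(colnames(v))
  if (!is.logical(mito) || length(mito) != ncol(v)) {
    stop("mito_predicate must return one logical per gene", call. = FALSE)
  }
  mito_frac <- if (any(mito)) {
    rowSums(v[, mito, drop = FALSE]) / pmax(total, 1)
  } else {
    rep(0, nrow(v))
  }
  ok_genes <- detected >= min_genes & detected <= max_genes
  ok_umi <- total <= max_umi
  ok_mito <- mito_frac <= max_mito_frac
  keep <- ok_genes & ok_umi & ok_mito
  if (!any(keep)) {
    stop(sprintf(paste0(
      "all %d cells removed by QC (gene-count bound removed %d, ",
      "UMI bound removed %d, mitochondrial bound removed %d)"),
      nrow(v), sum(!ok_genes), sum(!ok_umi), sum(!ok_mito)), call. = FALSE)
  }
  expr_like(v[keep, , drop = FALSE], x)
}

#' @rdname filter_cells
#' @param names Character vector of gene names.
#' @export
default_mito_predicate <- function(names) {
  startsWith(tolower(names), "mt-")
}

#' Filter genes by zero-expression and name patterns
#'
#' Drops genes with zero raw counts in every cell (when `drop_all_zero`)
#' and genes matching any of the supplied name predicates (regular
#' expressions matched case-insensitively, or functions mapping names to
#' logical). Column order of the survivors is preserved.
#'
#' @param x An [expression_matrix()].
#' @param drop_all_zero Drop genes whose column is entirely zero.
#' @param drop_name_patterns List (or vector) of regular expressions and/or
#'   predicate functions; a gene matching any is removed.
#' @return The filtered [expression_matrix()].
#' @export
filter_genes <- function(x, drop_all_zero = TRUE, drop_name_patterns = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  v <- expr_values(x)
  drop <- rep(FALSE, ncol(v))
  if (isTRUE(drop_all_zero)) drop <- drop | colSums(v != 0) == 0
  for (pat in drop_name_patterns) {
    hit <- if (is.function(pat)) {
      pat(colnames(v))
    } else {
      grepl(pat, colnames(v), ignore.case = TRUE)
    }
    if (!is.logical(hit) || length(hit) != ncol(v)) {
      stop("each name predicate must yield one logical per gene", call. = FALSE)
    }
    drop <- drop | hit
  }
  if (all(drop)) stop("all genes removed by gene filter", call. = FALSE)
  expr_like(v[, !drop, drop = FALSE], x)
}

#' Read a ground-truth network (edge list + TF list)
#'
#' Reads a headerless two-column edge list (regulator, target; comma or tab
#' separated) and a one-name-per-line transcription-factor list, restricts
#' edges to a gene universe (typically the genes of the expression matrix),
#' and collapses duplicates. Matching is exact after case-folding, since
#' public benchmarks mix upper/lower case across species. A regulator
#' missing from the TF list raises a warning but the edge is kept (the TF
#' list may be the looser set).
#'
#' @param edge_path Path to the 2-column edge list.
#' @param tf_path Path to the TF list.
#' @param gene_universe Character vector of admissible gene names.
#' @return A `grn_truth` object: list with `edges` (tibble of `regulator`,
#'   `target`), `tf_names`, `gene_universe`, and `n_dropped` (edges removed
#'   because an endpoint fell outside the universe).
#' @export
read_ground_truth <- function(edge_path, tf_path, gene_universe) {
  for (f in c(edge_path, tf_path)) {
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  }
  header <- readLines(edge_path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  edges <- utils::read.table(edge_path, sep = delim, header = FALSE,
                             col.names = c("regulator", "target"),
                             colClasses = "character")
  tfs <- readLines(tf_path)
  tfs <- tfs[nzchar(tfs)]
  ground_truth(edges, tfs, gene_universe)
}

#' Construct a ground-truth network from in-memory pieces
#'
#' @param edges Data frame with columns `regulator` and `target`.
#' @param tf_names Character vector of regulator-eligible genes.
#' @param gene_universe Character vector of admissible gene names.
#' @return A `grn_truth` object; see [read_ground_truth()].
#' @export
ground_truth <- function(edges, tf_names, gene_universe) {
  edges <- tibble::as_tibble(edges)[, c("regulator", "target")]
  edges$regulator <- tolower(as.character(edges$regulator))
  edges$target <- tolower(as.character(edges$target))
  tf_names <- unique(tolower(as.character(tf_names)))
  gene_universe <- unique(tolower(as.character(gene_universe)))
  edges <- dplyr::distinct(edges)
  inside <- edges$regulator %in% gene_universe & edges$target %in% gene_universe
  n_dropped <- sum(!inside)
  edges <- edges[inside, , drop = FALSE]
  if (nrow(edges) == 0L) {
    stop("no ground-truth edges fall inside the gene universe", call. = FALSE)
  }
  missing_tf <- setdiff(unique(edges$regulator), tf_names)
  if (length(missing_tf) > 0) {
    warning(length(missing_tf),
            " regulator(s) absent from the TF list; edges kept: ",
            paste(utils::head(missing_tf, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(edges = edges, tf_names = tf_names,
                 gene_universe = gene_universe, n_dropped = n_dropped),
            class = "grn_truth")
}

#' @export
print.grn_truth <- function(x, ...) {
  cat(sprintf("<grn_truth> %d edges, %d TFs, %d genes in universe (%d edges dropped)\n",
              nrow(x$edges), length(x$tf_names), length(x$gene_universe),
              x$n_dropped))
  invisible(x)
}

#' Write a ground-truth network to files readable by [read_ground_truth()]
#'
#' @param truth A `grn_truth` object.
#' @param edge_path,tf_path Output paths.
#' @return `edge_path`, invisibly.
#' @export
write_ground_truth <- function(truth, edge_path, tf_path) {
  utils::write.table(truth$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(truth$tf_names, tf_path)
  invisible(edge_path)
}
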