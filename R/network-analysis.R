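# Post-inference analyses: per-gene regulation scores, local neighborhoods
# around a gene of interest, and min-max scaling of edge weights across
# conditions (e.g. developmental time points analyzed as independent runs).

#' Per-gene regulation score
#'
#' For each gene, the sum of absolute incoming edge weights that survive
#' the extraction threshold — a measure of how strongly the gene is
#' regulated in the inferred network. Magnitudes are used throughout: the
#' model does not sign its regulatory effects.
#'
#' @param adjacency An [adjacency_matrix()], `dazzle_fit` or
#'   `dazzle_ensemble`.
#' @param threshold Minimum absolute edge weight (default 0.001).
#' @return Tibble with columns `gene` and `score`, sorted by decreasing
#'   score.
#' @export
regulation_score <- function(adjacency, threshold = 0.001) {
  if (inherits(adjacency, c("dazzle_fit", "dazzle_ensemble"))) {
    adjacency <- get_adjacency(adjacency)
  }
  A <- abs(unclass(adjacency))
  A[A <= threshold] <- 0
  out <- tibble::tibble(gene = colnames(A), score = unname(colSums(A)))
  dplyr::arrange(out, dplyr::desc(.data$score), .data$gene)
}

#' Top regulated genes
#'
#' @inheritParams regulation_score
#' @param n Number of genes to return (default 10).
#' @return The first `n` rows of [regulation_score()].
#' @export
top_regulated <- function(adjacency, n = 10, threshold = 0.001) {
  utils::head(regulation_score(adjacency, threshold), n)
}

#' Local network around a gene
#'
#' The strongest `top_k` incoming and `top_k` outgoing edges of a center
#' gene, by absolute weight among threshold-surviving edges, with a
#' deterministic lexicographic tie-break.
#'
#' @inheritParams regulation_score
#' @param center Gene name at the center of the neighborhood.
#' @param top_k Edges to keep in each direction.
#' @return Tibble with `regulator`, `target`, `weight`, `abs_weight`,
#'   `direction` (`"in"` or `"out"`).
#' @export
local_network <- function(adjacency, center, top_k = 10, threshold = 0.001) {
  if (inherits(adjacency, c("dazzle_fit", "dazzle_ensemble"))) {
    adjacency <- get_adjacency(adjacency)
  }
  genes <- rownames(adjacency)
  if (!center %in% genes) {
    near <- utils::head(agrep(center, genes, value = TRUE,
                              ignore.case = TRUE, max.distance = 2), 5)
    stop("gene '", center, "' not in the network",
         if (length(near)) paste0("; did you mean: ",
                                  paste(near, collapse = ", ")),
         call. = FALSE)
  }
  edges <- extract_edges(adjacency, threshold)
  take <- function(df, dir) {
    df <- dplyr::arrange(df, dplyr::desc(.data$abs_weight), .data$regulator,
                         .data$target)
    df <- utils::head(df, top_k)
    if (nrow(df)) df$direction <- dir else df$direction <- character(0)
    df
  }
  dplyr::bind_rows(
    take(dplyr::filter(edges, .data$target == center,
                       .data$regulator != center), "in"),
    take(dplyr::filter(edges, .data$regulator == center,
                       .data$target != center), "out")
  )
}

#' Bundle per-condition networks into a series
#'
#' @param networks Named list of adjacency matrices (or fits), one per
#'   condition (names are the condition labels and must be unique).
#' @return A `network_series` object.
#' @export
network_series <- function(networks) {
  if (is.null(names(networks)) || anyDuplicated(names(networks)) ||
      any(!nzchar(names(networks)))) {
    stop("networks must be a named list with unique condition labels",
         call. = FALSE)
  }
  nets <- lapply(networks, function(x) {
    if (inherits(x, c("dazzle_fit", "dazzle_ensemble"))) get_adjacency(x) else x
  })
  structure(list(networks = nets, labels = names(networks)),
            class = "network_series")
}

#' Min-max scale selected edge weights across conditions
#'
#' For a fixed set of edges, takes the absolute weight of each edge in each
#' condition and rescales within each condition to \[0, 1\] via
#' (w - min) / (max - min), over the selected edge set only. A condition
#' where all selected edges share one weight maps to 0. An edge whose
#' endpoint genes are missing from a condition's network gets weight 0
#' there and is flagged.
#'
#' @param series A [network_series()].
#' @param edges Data frame with columns `regulator` and `target` selecting
#'   the edges to compare.
#' @return Tibble with `condition`, `regulator`, `target`, `weight`
#'   (absolute), `scaled`, `present`.
#' @export
minmax_scale <- function(series, edges) {
  stopifnot(inherits(series, "network_series"))
  if (length(series$networks) < 1) stop("empty series", call. = FALSE)
  edges <- tibble::as_tibble(edges)[, c("regulator", "target")]
  rows <- purrr::map(series$labels, function(lbl) {
    A <- unclass(series$networks[[lbl]])
    genes <- rownames(A)
    i <- match(edges$regulator, genes)
    j <- match(edges$target, genes)
    present <- !is.na(i) & !is.na(j)
    w <- numeric(nrow(edges))
    w[present] <- abs(A[cbind(i[present], j[present])])
    rng <- range(w)
    scaled <- if (rng[2] > rng[1]) (w - rng[1]) / (rng[2] - rng[1]) else
      numeric(length(w))
    tibble::tibble(condition = lbl, regulator = edges$regulator,
                   target = edges$target, weight = w, scaled = scaled,
                   present = present)
  })
  dplyr::bind_rows(rows)
}

#' Plot a cross-condition scaled weight table
#'
#' Heat-map style tile plot of [minmax_scale()] output: conditions on the
#' x axis, edges on the y axis, fill = scaled weight.
#'
#' @param scaled Output of [minmax_scale()].
#' @return A ggplot object.
#' @export
plot_network_series <- function(scaled) {
  scaled$edge <- paste(scaled$regulator, scaled$target, sep = " → ")
  ggplot2::ggplot(scaled, ggplot2::aes(x = .data$condition, y = .data$edge,
                                       fill = .data$scaled)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "scaled |w|")
}
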