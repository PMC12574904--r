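# Synthetic worlds with exactly the statistical structure the model assumes:
# a sparse weighted adjacency A (spectral radius < 1), expression generated
# by the linear SEM X = Z (I - A)^-1 with Gaussian noise Z, and one-time
# Bernoulli dropout on the observed matrix. Everything is deterministic from
# a single seed, so training, evaluation and recovery tests need no external
# data.

#' Sample a sparse random gene regulatory network
#'
#' Each off-diagonal entry is nonzero independently with probability
#' `density`; nonzero weights have magnitude uniform in
#' `[0.5, 1] * weight_scale` with random sign. The matrix is then rescaled
#' so its spectral radius is at most 0.8, which guarantees (I - A) is
#' invertible and the generated expression is stable. Transcription factors
#' are the genes with at least one outgoing edge. Cycles are allowed — the
#' inference method imposes no DAG constraint, so neither does the
#' simulator.
#'
#' @param m Number of genes.
#' @param density Probability of each directed off-diagonal edge, in (0, 1).
#' @param weight_scale Magnitude scale of the raw weights.
#' @param seed Optional integer seed (caller's RNG preserved).
#' @return List with `adjacency` (an [adjacency_matrix()]) and `tf_names`.
#' @export
sample_grn <- function(m, density, weight_scale = 1, seed = NULL) {
  if (density <= 0 || density >= 1) {
    stop("density must be in (0, 1)", call. = FALSE)
  }
  run <- function() {
    genes <- paste0("g", seq_len(m))
    draw <- function() {
      A <- matrix(0, m, m)
      off <- which(row(A) != col(A))
      hit <- off[stats::runif(length(off)) < density]
      A[hit] <- stats::runif(length(hit), 0.5, 1) * weight_scale *
        sample(c(-1, 1), length(hit), replace = TRUE)
      A
    }
    A <- draw()
    if (!any(A != 0)) A <- draw()  # one resample for unlucky sparse draws
    if (!any(A != 0)) {
      stop("no edges drawn; density too low for this gene count",
           call. = FALSE)
    }
    rho <- max(Mod(eigen(A, only.values = TRUE)$values))
    if (rho > 0.8) A <- A * (0.8 / rho)
    adj <- adjacency_matrix(A, genes)
    list(adjacency = adj, tf_names = genes[rowSums(A != 0) > 0])
  }
  if (is.null(seed)) run() else with_preserved_seed(seed, run())
}

#' Simulate expression from a linear structural equation model
#'
#' Draws cell-level noise Z ~ Normal(0, noise_scale^2) and solves the SEM
#' X = XA + Z, i.e. X = Z (I - A)^-1. To make the values nonnegative like
#' log-transformed counts, the matrix is shifted up by `shift_sigma` noise
#' standard deviations and floored at zero. The floor creates a mass of
#' exact zeros (the "biological" zeros of real data, about 16% at the
#' default one-sigma shift), zero is the minimum value, and a dropout event
#' lands on that same minimum roughly one standard deviation below the
#' mean — the geometry of real ln(count + 1) matrices. The result is
#' generated directly in log space (`is_log_transformed = TRUE`): the model
#' consumes log space and the SEM is stated on the modeled matrix, so no
#' count-level round trip is simulated.
#'
#' @param adjacency An [adjacency_matrix()] with spectral radius < 1.
#' @param n Number of cells.
#' @param noise_scale Standard deviation of the SEM noise.
#' @param shift_sigma Upward shift, in units of `noise_scale`, applied
#'   before flooring at zero.
#' @param seed Optional integer seed.
#' @return An [expression_matrix()] marked log-transformed.
#' @export
simulate_expression <- function(adjacency, n, noise_scale = 1,
                                shift_sigma = 1, seed = NULL) {
  A <- unclass(adjacency)
  m <- ncol(A)
  rho <- if (m > 0) max(Mod(eigen(A, only.values = TRUE)$values)) else 0
  if (rho >= 1) {
    stop("spectral radius of the adjacency must be < 1", call. = FALSE)
  }
  run <- function() {
    Z <- matrix(stats::rnorm(n * m, sd = noise_scale), n, m)
    B <- diag(m) - A
    X <- if (n > 0) t(solve(t(B), t(Z))) else Z
    if (n > 0) X <- pmax(X + shift_sigma * noise_scale, 0)
    dimnames(X) <- list(if (n > 0) paste0("cell_", seq_len(n)), rownames(A))
    expression_matrix(X, gene_names = rownames(A), log_transformed = TRUE)
  }
  if (is.null(seed)) run() else with_preserved_seed(seed, run())
}

#' Generate a complete synthetic study world
#'
#' Composes [sample_grn()], [simulate_expression()] and one-time Bernoulli
#' dropout into a fully specified, seed-deterministic dataset: the true
#' network, the clean expression matrix, the observed (dropout-corrupted)
#' matrix, and the dropout mask. The defaults define the package's standard
#' recovery benchmark: 50 genes, 500 cells, edge density 0.05, unit noise,
#' 20% dropout.
#'
#' @param m Number of genes.
#' @param n Number of cells.
#' @param density Edge density of the true network.
#' @param weight_scale,noise_scale Generator scales (see [sample_grn()] and
#'   [simulate_expression()]).
#' @param dropout_rate One-time Bernoulli dropout rate on the observed
#'   matrix.
#' @param seed Integer seed; the whole world is deterministic in it.
#' @param dir Optional directory: when given, fixture files readable by
#'   [read_expression()] and [read_ground_truth()] are written there
#'   (`expression.csv`, `edges.tsv`, `tfs.txt`).
#' @return A `synthetic_world`: list with `adjacency`, `tf_names`,
#'   `expression_clean`, `expression_observed`, `mask`, and `config`.
#' @export
#' @examples
#' world <- make_world(m = 20, n = 100, seed = 42)
#' world$adjacency
make_world <- function(m = 50, n = 500, density = 0.05, weight_scale = 1,
                       noise_scale = 1, dropout_rate = 0.2, seed = 1,
                       dir = NULL) {
  if (dropout_rate < 0 || dropout_rate > 1) {
    stop("dropout_rate must be in [0, 1]", call. = FALSE)
  }
  world <- with_preserved_seed(seed, {
    grn <- sample_grn(m, density, weight_scale)
    clean <- simulate_expression(grn$adjacency, n, noise_scale)
    mask <- sample_mask(n, m, dropout_rate)
    observed <- apply_mask(clean, mask)$x_aug
    list(adjacency = grn$adjacency, tf_names = grn$tf_names,
         expression_clean = clean, expression_observed = observed,
         mask = mask,
         config = list(m = m, n = n, density = density,
                       weight_scale = weight_scale,
                       noise_scale = noise_scale,
                       dropout_rate = dropout_rate, seed = seed))
  })
  class(world) <- "synthetic_world"
  if (!is.null(dir)) write_world(world, dir)
  world
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> %d genes x %d cells, %d true edges, dropout %.0f%% (seed %d)\n",
    x$config$m, x$config$n, sum(unclass(x$adjacency) != 0),
    100 * x$config$dropout_rate, x$config$seed))
  invisible(x)
}

#' Ground truth of a synthetic world
#'
#' @param world A `synthetic_world`.
#' @return A `grn_truth` usable by [evaluate_grn()].
#' @export
world_truth <- function(world) {
  ed <- extract_edges(world$adjacency, threshold = 0)
  ground_truth(ed[, c("regulator", "target")], world$tf_names,
               gene_names(world$expression_clean))
}

#' Write a synthetic world as plain-text fixtures
#'
#' Emits `expression.csv` (observed matrix, delimited format),
#' `expression_clean.csv`, `edges.tsv` (true edge list) and `tfs.txt` in
#' the formats the package readers consume.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(world$expression_observed, file.path(dir, "expression.csv"))
  write_expression(world$expression_clean, file.path(dir, "expression_clean.csv"))
  write_ground_truth(world_truth(world), file.path(dir, "edges.tsv"),
                     file.path(dir, "tfs.txt"))
  invisible(dir)
}
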