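#' Sample a Bernoulli dropout-augmentation mask
#'
#' Draws an n x m boolean mask whose entries are i.i.d. Bernoulli(p); `TRUE`
#' marks an entry to be zeroed. During training a fresh mask is drawn at
#' every optimizer step, so the model only ever sees augmented data.
#'
#' @param n,m Mask dimensions (cells, genes).
#' @param p Dropout-augmentation probability in \[0, 1\].
#' @param seed Optional integer; when supplied the draw is made under this
#'   seed and the caller's RNG state is left untouched. When `NULL` the
#'   current RNG stream is used (this is how the training loop draws its
#'   per-step masks from one root seed).
#' @return A `dropout_mask`: logical matrix with attributes `p` and `seed`.
#' @export
sample_mask <- function(n, m, p, seed = NULL) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    stop("p must be a single value in [0, 1]", call. = FALSE)
  }
  draw <- function() matrix(stats::runif(n * m) < p, n, m)
  mask <- if (is.null(seed)) draw() else with_preserved_seed(seed, draw())
  structure(mask, p = p, seed = seed, class = c("dropout_mask", "matrix", "array"))
}

# run code under a temporary seed, restoring the caller's RNG state
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' @export
print.dropout_mask <- function(x, ...) {
  cat(sprintf("<dropout_mask> %d x %d, p = %g, observed rate = %.4f\n",
              nrow(x), ncol(x), attr(x, "p"), mean(x)))
  invisible(x)
}

#' Apply a dropout mask to an expression matrix
#'
#' Zeroes the masked entries, leaving all others bit-identical. Returns both
#' the augmented matrix X' and the additive noise term E = -X (.) M, so that
#' X' = X + E holds exactly.
#'
#' @param x An [expression_matrix()].
#' @param mask A [sample_mask()] result of the same dimensions.
#' @return List with `x_aug` (the augmented [expression_matrix()]) and
#'   `noise` (the numeric matrix E).
#' @export
apply_mask <- function(x, mask) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!all(dim(x) == dim(mask))) {
    stop(sprintf("mask dimensions (%d x %d) do not match matrix (%d x %d)",
                 nrow(mask), ncol(mask), nrow(x), ncol(x)), call. = FALSE)
  }
  v <- expr_values(x)
  noise <- -v
  noise[!mask] <- 0
  aug <- v + noise
  list(x_aug = expr_like(aug, x), noise = noise)
}

#' Inject permanent background dropout
#'
#' One-time masking at rate `q`, used by ablation experiments to simulate
#' additional background dropout noise in the observed data before the
#' model ever sees it. Unlike per-iteration augmentation masks, this is
#' applied once and never resampled.
#'
#' @param x An [expression_matrix()].
#' @param q Background dropout rate in \[0, 1\].
#' @param seed Optional integer seed (see [sample_mask()]).
#' @return The masked [expression_matrix()].
#' @export
inject_background_dropout <- function(x, q, seed = NULL) {
  mask <- sample_mask(nrow(x), ncol(x), q, seed = seed)
  apply_mask(x, mask)$x_aug
}
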