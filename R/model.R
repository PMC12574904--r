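#' Construct a gene-gene adjacency matrix
#'
#' An m x m real matrix of directed regulatory weights: entry (i, j) is the
#' weight of regulator gene i acting on target gene j. The diagonal is
#' forced to zero on construction — a self-loop would let each gene
#' reconstruct itself and trivialize the structural equation model.
#'
#' @param weights Numeric m x m matrix.
#' @param gene_names Character vector of m unique gene names (defaults to
#'   `rownames(weights)`).
#' @return An `adjacency_matrix` (numeric matrix with dimnames, zero diag).
#' @export
adjacency_matrix <- function(weights, gene_names = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    stop("adjacency matrix must be square", call. = FALSE)
  }
  if (any(!is.finite(weights))) {
    stop("adjacency matrix contains non-finite entries", call. = FALSE)
  }
  if (is.null(gene_names)) gene_names <- rownames(weights)
  if (is.null(gene_names)) gene_names <- paste0("g", seq_len(nrow(weights)))
  if (length(gene_names) != nrow(weights) || anyDuplicated(gene_names)) {
    stop("gene_names must be unique and match the matrix dimension",
         call. = FALSE)
  }
  diag(weights) <- 0
  dimnames(weights) <- list(gene_names, gene_names)
  structure(weights, class = c("adjacency_matrix", "matrix", "array"))
}

#' @export
print.adjacency_matrix <- function(x, ...) {
  nz <- sum(abs(unclass(x)) > 0)
  cat(sprintf("<adjacency_matrix> %d genes, %d nonzero weights\n", nrow(x), nz))
  invisible(x)
}

# ---- shared entrywise nets -------------------------------------------------
# Each "net" maps a scalar to a scalar with weights shared across all n x m
# entries. mode "mlp" is a residual one-hidden-layer tanh net initialized at
# the identity (w2 = 0); mode "identity" has no parameters and is used by the
# algebraic contract tests.

new_entry_net <- function(mode, hidden) {
  if (mode == "identity") return(list(mode = "identity"))
  list(mode = "mlp",
       w1 = stats::runif(hidden, -0.5, 0.5),
       b1 = numeric(hidden),
       w2 = numeric(hidden),
       b2 = 0)
}

net_forward <- function(net, x) {
  if (net$mode == "identity") return(list(out = x, cache = NULL))
  act <- tanh(outer(x, net$w1) + rep(net$b1, each = length(x)))
  out <- x + drop(act %*% net$w2) + net$b2
  list(out = out, cache = list(x = x, act = act))
}

net_backward <- function(net, cache, g) {
  if (net$mode == "identity") return(list(gx = g, grads = NULL))
  d <- 1 - cache$act^2
  gpre <- (g %o% net$w2) * d          # N x h
  list(gx = g + drop(gpre %*% net$w1),
       grads = list(w1 = drop(crossprod(gpre, cache$x)),
                    b1 = colSums(gpre),
                    w2 = drop(crossprod(cache$act, g)),
                    b2 = sum(g)))
}

# 3-layer tanh MLP + sigmoid head, shared across entries; final layer is
# zero-initialized so the classifier starts at probability 0.5 everywhere.
new_classifier <- function(hidden) {
  list(w1 = stats::runif(hidden, -1, 1),
       b1 = numeric(hidden),
       W2 = matrix(stats::runif(hidden * hidden, -1, 1) / sqrt(hidden),
                   hidden, hidden),
       b2 = numeric(hidden),
       w3 = numeric(hidden),
       b3 = 0)
}

classifier_forward <- function(clf, x) {
  n <- length(x)
  a1 <- tanh(outer(x, clf$w1) + rep(clf$b1, each = n))
  a2 <- tanh(a1 %*% clf$W2 + rep(clf$b2, each = n))
  logit <- drop(a2 %*% clf$w3) + clf$b3
  list(prob = stats::plogis(logit), logit = logit,
       cache = list(x = x, a1 = a1, a2 = a2))
}

classifier_backward <- function(clf, cache, glogit) {
  ga2 <- (glogit %o% clf$w3) * (1 - cache$a2^2)
  ga1 <- (ga2 %*% t(clf$W2)) * (1 - cache$a1^2)
  list(gx = drop(ga1 %*% clf$w1),
       grads = list(w1 = drop(crossprod(ga1, cache$x)),
                    b1 = colSums(ga1),
                    W2 = crossprod(cache$a1, ga2),
                    b2 = colSums(ga2),
                    w3 = drop(crossprod(cache$a2, glogit)),
                    b3 = sum(glogit)))
}

#' Initialize a DAZZLE model
#'
#' The model is a variational autoencoder whose encoder and decoder share a
#' trainable m x m adjacency matrix A. The encoder lifts each expression
#' value through a small shared per-gene net, multiplies along the gene axis
#' by (I - A) to produce the latent posterior mean (one latent channel per
#' gene), and a shared affine head produces the log-variance. The decoder
#' multiplies the latent sample by (I - A)^-1 (via a linear solve) and maps
#' back through a shared per-gene net. A 3-layer tanh MLP followed by a
#' sigmoid classifies each latent entry as augmented dropout or not.
#'
#' With `net = "identity"` the per-gene nets are the identity, so the
#' encoder mean equals X'(I - A) exactly and the decoder is X' = Z'(I - A)^-1;
#' this mode backs the algebraic contract tests. The default `"mlp"` nets
#' are residual and initialized at the identity.
#'
#' The model also carries a fixed per-gene centering vector (zero here;
#' [dazzle_train()] sets it to the gene means of the training data). The
#' structural equation model has no intercept term, so it is fit to
#' deviations from the gene means: the encoder subtracts the centering
#' vector and the decoder adds it back. A dropout zero then appears as a
#' large negative deviation — precisely the signal the dropout classifier
#' reads from the latent.
#'
#' @param gene_names Character vector of gene names (defines m).
#' @param hidden Hidden width of the shared per-gene nets and classifier.
#' @param net `"mlp"` (default) or `"identity"`.
#' @param adjacency Optional initial adjacency (defaults to all zeros).
#' @return A `dazzle_model` object.
#' @export
new_dazzle_model <- function(gene_names, hidden = 64,
                             net = c("mlp", "identity"), adjacency = NULL) {
  net <- match.arg(net)
  m <- length(gene_names)
  if (m < 2) stop("need at least 2 genes", call. = FALSE)
  A <- if (is.null(adjacency)) matrix(0, m, m) else as.matrix(adjacency)
  stopifnot(all(dim(A) == m))
  diag(A) <- 0
  dimnames(A) <- list(gene_names, gene_names)
  structure(list(
    A = A,
    enc = new_entry_net(net, hidden),
    dec = new_entry_net(net, hidden),
    lv = list(s = 0, b = 0),
    clf = new_classifier(hidden),
    center = stats::setNames(numeric(m), gene_names),
    gene_names = gene_names,
    hidden = hidden,
    net_mode = net
  ), class = "dazzle_model")
}

#' @export
print.dazzle_model <- function(x, ...) {
  cat(sprintf("<dazzle_model> %d genes, %s per-gene nets (hidden %d)\n",
              length(x$gene_names), x$net_mode, x$hidden))
  invisible(x)
}

#' Extract the adjacency matrix of a model or fit
#'
#' @param object A `dazzle_model`, `dazzle_fit`, or `dazzle_ensemble`.
#' @return An [adjacency_matrix()] (zero diagonal enforced).
#' @export
get_adjacency <- function(object) {
  if (inherits(object, "dazzle_fit")) object <- object$model
  if (inherits(object, "dazzle_ensemble")) {
    return(object$adjacency)
  }
  adjacency_matrix(object$A, object$gene_names)
}

# ---- forward passes --------------------------------------------------------

#' Encode expression into the latent posterior
#'
#' Computes the posterior q(Z' | X'): the per-gene net lifts each entry,
#' the result is right-multiplied by (I - A) along the gene axis giving the
#' posterior mean, and the shared affine head gives the log-variance. In
#' stochastic mode the sample is mean + exp(log_var / 2) * eps with eps
#' drawn from the current RNG stream; in deterministic mode sample = mean.
#'
#' @param x_aug Augmented log-space [expression_matrix()] (or plain matrix).
#' @param model A `dazzle_model`.
#' @param stochastic Draw a reparameterized sample (default `TRUE`).
#' @return A `latent_state`: list with `mean`, `log_var`, `sample`, `eps`.
#' @export
encode <- function(x_aug, model, stochastic = TRUE) {
  v <- if (inherits(x_aug, "expression_matrix")) expr_values(x_aug) else as.matrix(x_aug)
  if (ncol(v) != length(model$gene_names)) {
    stop("matrix width does not match the model's gene set", call. = FALSE)
  }
  v <- sweep(v, 2, model$center)
  B <- diag(ncol(v)) - unname(unclass(model$A))
  h <- net_forward(model$enc, as.vector(v))
  H <- matrix(h$out, nrow(v), ncol(v))
  mean <- H %*% B
  dimnames(mean) <- NULL
  log_var <- model$lv$s * mean + model$lv$b
  if (any(!is.finite(mean))) stop("non-finite encoder mean", call. = FALSE)
  eps <- if (stochastic) matrix(stats::rnorm(length(mean)), nrow(mean)) else NULL
  smp <- if (stochastic) mean + exp(log_var / 2) * eps else mean
  structure(list(mean = mean, log_var = log_var, sample = smp, eps = eps),
            class = "latent_state")
}

#' Decode a latent state back to expression space
#'
#' Right-multiplies the latent sample by (I - A)^-1 along the gene axis
#' (computed with a linear solve, never an explicit inverse) and maps each
#' entry back through the shared decoder net.
#'
#' @param z A `latent_state` from [encode()].
#' @param model A `dazzle_model`.
#' @return Numeric matrix of reconstructed expression.
#' @export
decode <- function(z, model) {
  B <- diag(ncol(z$sample)) - unname(unclass(model$A))
  W <- tryCatch(t(solve(t(B), t(z$sample))), error = function(e) {
    stop(paste0("(I - A) is singular; training has likely diverged — ",
                "try a stronger sparsity penalty (alpha) or a smaller ",
                "adjacency learning rate"), call. = FALSE)
  })
  g <- net_forward(model$dec, as.vector(W))
  sweep(matrix(g$out, nrow(W), ncol(W)), 2, model$center, `+`)
}

#' Classify latent entries as augmented dropout
#'
#' Applies the shared 3-layer tanh MLP + sigmoid to each latent entry,
#' returning the probability that the entry was zeroed by dropout
#' augmentation. Uses the latent sample during training and the posterior
#' mean at evaluation.
#'
#' @param z A `latent_state`.
#' @param model A `dazzle_model`.
#' @param use_mean Classify the posterior mean instead of the sample.
#' @return Numeric matrix of probabilities in (0, 1).
#' @export
classify_dropout <- function(z, model, use_mean = FALSE) {
  input <- if (use_mean || is.null(z$sample)) z$mean else z$sample
  cf <- classifier_forward(model$clf, as.vector(input))
  matrix(cf$prob, nrow(input), ncol(input))
}

# ---- loss components -------------------------------------------------------

#' Binary cross-entropy of the dropout classifier
#'
#' Mean binary cross entropy between the true augmentation mask and the
#' predicted dropout probabilities, over all n x m entries. Probabilities
#' are clamped to \[1e-8, 1 - 1e-8\].
#'
#' @param mask Logical matrix (the true augmentation mask).
#' @param mask_prob Numeric matrix of predicted probabilities.
#' @return Scalar loss.
#' @export
bce_loss <- function(mask, mask_prob) {
  if (!all(dim(mask) == dim(mask_prob))) stop("shape mismatch", call. = FALSE)
  p <- pmin(pmax(mask_prob, 1e-8), 1 - 1e-8)
  m <- as.numeric(mask)
  -mean(m * log(p) + (1 - m) * log(1 - p))
}

#' KL divergence of the latent posterior from the standard-normal prior
#'
#' Mean over cells of the sum over gene channels of
#' (exp(log_var) + mean^2 - 1 - log_var) / 2. Always nonnegative; zero iff
#' the posterior equals the prior.
#'
#' @param z A `latent_state`.
#' @return Scalar divergence.
#' @export
kl_divergence <- function(z) {
  per_entry <- 0.5 * (exp(z$log_var) + z$mean^2 - 1 - z$log_var)
  mean(rowSums(per_entry))
}

#' Gaussian reconstruction loss
#'
#' Mean squared error between the augmented input and its reconstruction —
#' the negative Gaussian log-likelihood with fixed unit variance, up to
#' constants.
#'
#' @param x_aug Augmented input ([expression_matrix()] or matrix).
#' @param x_hat Reconstruction from [decode()].
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(x_aug, x_hat) {
  v <- if (inherits(x_aug, "expression_matrix")) expr_values(x_aug) else as.matrix(x_aug)
  if (!all(dim(v) == dim(x_hat))) stop("shape mismatch", call. = FALSE)
  mean((v - x_hat)^2)
}

#' Compose the training loss with the delayed sparsity schedule
#'
#' Total loss = reconstruction + alpha * sum|A| + beta * KL + gamma * BCE,
#' where the L1 term on the adjacency matrix is withheld (effective alpha
#' = 0) for the first `sparse_delay` training iterations. Introducing the
#' sparsity penalty only after the adjacency weights have stabilized avoids
#' the failure mode where L1 optimization is prioritized early and all
#' weights collapse to near zero.
#'
#' @param reconstruction,kl,bce Scalar loss components.
#' @param adjacency The current adjacency matrix (for the L1 term).
#' @param alpha,beta,gamma Nonnegative coefficients.
#' @param iteration Zero-based training iteration.
#' @param sparse_delay Number of initial iterations with no L1 term.
#' @return A `loss_components` list: the four components, the coefficients,
#'   `alpha_effective`, and `total`.
#' @export
compose_loss <- function(reconstruction, kl, bce, adjacency,
                         alpha = 1, beta = 1, gamma = 1,
                         iteration = 0, sparse_delay = 5) {
  if (any(c(alpha, beta, gamma) < 0)) {
    stop("loss coefficients must be nonnegative", call. = FALSE)
  }
  A <- unclass(adjacency)
  diag(A) <- 0
  l1 <- sum(abs(A))
  alpha_eff <- if (iteration < sparse_delay) 0 else alpha
  total <- reconstruction + alpha_eff * l1 + beta * kl + gamma * bce
  structure(list(reconstruction = reconstruction, kl = kl,
                 l1_sparse = l1, bce = bce,
                 alpha = alpha, beta = beta, gamma = gamma,
                 alpha_effective = alpha_eff, total = total),
            class = "loss_components")
}

#' Extract thresholded, ranked edges from an adjacency matrix
#'
#' Keeps every directed edge whose weight exceeds `threshold` in absolute
#' value and ranks edges by |weight| descending, with a deterministic
#' lexicographic (regulator, target) tie-break.
#'
#' @param adjacency An [adjacency_matrix()] (or any named square matrix),
#'   or a `dazzle_fit` / `dazzle_ensemble`.
#' @param threshold Minimum absolute weight; default 0.001.
#' @return Tibble with columns `regulator`, `target`, `weight`,
#'   `abs_weight`, sorted by decreasing `abs_weight`.
#' @export
extract_edges <- function(adjacency, threshold = 0.001) {
  if (inherits(adjacency, c("dazzle_fit", "dazzle_ensemble"))) {
    adjacency <- get_adjacency(adjacency)
  }
  A <- unclass(adjacency)
  genes <- rownames(A)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(A)))
  keep <- which(abs(A) > threshold, arr.ind = TRUE)
  out <- tibble::tibble(
    regulator = genes[keep[, 1]],
    target = genes[keep[, 2]],
    weight = A[keep],
    abs_weight = abs(A[keep])
  )
  dplyr::arrange(out, dplyr::desc(.data$abs_weight), .data$regulator,
                 .data$target)
}
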