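# Training: full backward pass through the SEM-VAE, a hand-rolled Adam with
# two learning-rate groups (adjacency vs. everything else), per-step dropout
# augmentation, and the delayed L1 schedule.

# ---- gradient of the composite loss on one mini-batch ----------------------
# Returns loss components and gradients for every parameter tensor.
# Derivations (right-multiplications along the gene axis, B = I - A):
#   M = H B          =>  dL/dH = G B^T,        dL/dB += H^T G
#   W = z B^{-1}     =>  dL/dz = G B^{-T},     dL/dB += -W^T (G B^{-T})
# B^{-T} products are computed with linear solves.
dazzle_backward <- function(model, xb, mask, alpha_eff, beta, gamma,
                            stochastic = TRUE) {
  b <- nrow(xb); m <- ncol(xb); nm <- b * m
  A <- model$A
  B <- diag(m) - A
  xa <- xb
  xa[mask] <- 0                       # augmentation acts in data space
  xa <- sweep(xa, 2, model$center)    # the SEM is fit to deviations

  # forward
  hf <- net_forward(model$enc, as.vector(xa))
  H <- matrix(hf$out, b, m)
  M <- H %*% B
  lv <- model$lv$s * M + model$lv$b
  eps <- if (stochastic) matrix(stats::rnorm(nm), b, m) else matrix(0, b, m)
  sd_ <- exp(lv / 2)
  z <- M + sd_ * eps

  cf <- classifier_forward(model$clf, as.vector(z))
  prob <- pmin(pmax(cf$prob, 1e-8), 1 - 1e-8)

  W <- t(solve(t(B), t(z)))
  gf <- net_forward(model$dec, as.vector(W))
  xhat <- matrix(gf$out, b, m)

  mnum <- as.numeric(mask)
  recon <- mean((xa - xhat)^2)
  kl <- mean(rowSums(0.5 * (exp(lv) + M^2 - 1 - lv)))
  bce <- -mean(mnum * log(prob) + (1 - mnum) * log(1 - prob))
  l1 <- sum(abs(A))
  total <- recon + alpha_eff * l1 + beta * kl + gamma * bce
  if (!is.finite(total)) {
    stop("non-finite training loss", call. = FALSE)
  }

  # backward: reconstruction -> decoder net -> solve
  gxhat <- 2 * (xhat - xa) / nm
  db <- net_backward(model$dec, gf$cache, as.vector(gxhat))
  GW <- matrix(db$gx, b, m)
  Gz_dec <- t(solve(B, t(GW)))                   # G B^{-T}
  GB <- -crossprod(W, Gz_dec)

  # classifier branch
  glogit <- gamma * (cf$prob - mnum) / nm
  cb <- classifier_backward(model$clf, cf$cache, glogit)
  Gz <- Gz_dec + matrix(cb$gx, b, m)

  # reparameterization + KL
  Gmean <- Gz + beta * M / b
  Glv <- Gz * eps * sd_ * 0.5 + beta * (exp(lv) - 1) / (2 * b)
  Gm <- Gmean + Glv * model$lv$s
  gs <- sum(Glv * M)
  gb <- sum(Glv)

  # encoder multiply and net
  GH <- Gm %*% t(B)
  GB <- GB + crossprod(H, Gm)
  eb <- net_backward(model$enc, hf$cache, as.vector(GH))

  GA <- -GB
  diag(GA) <- 0
  if (alpha_eff > 0) GA <- GA + alpha_eff * sign(A)

  list(
    components = list(reconstruction = recon, kl = kl, l1_sparse = l1,
                      bce = bce, alpha_effective = alpha_eff, total = total),
    grads = list(A = GA, enc = eb$grads, dec = db$grads,
                 lv = list(s = gs, b = gb), clf = cb$grads)
  )
}

# ---- Adam over nested parameter lists --------------------------------------

adam_new_state <- function(params) {
  walk <- function(p) {
    if (is.list(p)) return(lapply(p, walk))
    if (!is.numeric(p)) return(NULL)   # e.g. a net's "mode" tag
    list(m = p * 0, v = p * 0)
  }
  lapply(params, walk)
}

adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  step <- function(p, g, s) {
    if (is.null(s) || is.null(g)) return(list(p = p, s = s))
    if (is.list(p)) {
      out_p <- p; out_s <- s
      for (k in names(p)) {
        r <- step(p[[k]], g[[k]], s[[k]])
        out_p[[k]] <- r$p; out_s[[k]] <- r$s
      }
      return(list(p = out_p, s = out_s))
    }
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
  }
  step(params, grads, state)
}

#' Default training configuration
#'
#' The defaults follow the method's recommended settings: 120 training
#' iterations (full passes over the cells in mini-batches), dropout
#' augmentation probability 0.1 resampled at every optimizer step, the L1
#' sparsity term withheld for the first 5 iterations, one Adam optimizer
#' with learning rate 1e-4 on the neural nets and 2e-5 on the adjacency
#' matrix, and batch size 64.
#'
#' `alpha` scales the L1 penalty `sum|A|` after the delay. Because the
#' penalty is a sum over all m^2 entries while the data terms are averaged,
#' a per-entry subgradient of order `alpha` competes with data gradients of
#' order covariance/cells; the default 0.01 keeps the penalty active without
#' letting it dominate (see the package vignette). For cell-type-specific
#' benchmarks a much smaller value is recommended (`alpha_small` preset).
#'
#' @param n_iterations Full passes over the data.
#' @param da_prob Dropout-augmentation probability per optimizer step.
#' @param sparse_delay Iterations before the L1 term switches on.
#' @param alpha,beta,gamma Coefficients of the L1, KL and classifier terms.
#' @param lr_nn,lr_adj Learning rates for the nets and the adjacency.
#' @param batch_size Mini-batch size (full batch when cells < batch size).
#' @param hidden Hidden width of the shared per-gene nets.
#' @param net `"mlp"` or `"identity"` per-gene nets.
#' @param stochastic Sample the latent (TRUE) or use the posterior mean.
#' @param seed Root RNG seed; every random draw in a run derives from it.
#' @param ensemble_runs Number of independently seeded runs to aggregate.
#' @return A named list of class `dazzle_config`.
#' @export
dazzle_config <- function(n_iterations = 120, da_prob = 0.1, sparse_delay = 5,
                          alpha = 0.01, beta = 1, gamma = 1,
                          lr_nn = 1e-4, lr_adj = 2e-5, batch_size = 64,
                          hidden = 64, net = "mlp", stochastic = TRUE,
                          seed = 1, ensemble_runs = 1) {
  cfg <- list(n_iterations = n_iterations, da_prob = da_prob,
              sparse_delay = sparse_delay, alpha = alpha, beta = beta,
              gamma = gamma, lr_nn = lr_nn, lr_adj = lr_adj,
              batch_size = batch_size, hidden = hidden, net = net,
              stochastic = stochastic, seed = seed,
              ensemble_runs = ensemble_runs)
  validate_config(cfg)
  structure(cfg, class = c("dazzle_config", "list"))
}

validate_config <- function(cfg) {
  if (cfg$n_iterations < 1) stop("n_iterations must be >= 1", call. = FALSE)
  if (cfg$sparse_delay >= cfg$n_iterations) {
    stop("sparse_delay must be smaller than n_iterations", call. = FALSE)
  }
  if (cfg$lr_nn <= 0 || cfg$lr_adj <= 0) {
    stop("learning rates must be positive", call. = FALSE)
  }
  if (cfg$da_prob < 0 || cfg$da_prob > 1) {
    stop("da_prob must be in [0, 1]", call. = FALSE)
  }
  if (any(c(cfg$alpha, cfg$beta, cfg$gamma) < 0)) {
    stop("loss coefficients must be nonnegative", call. = FALSE)
  }
  invisible(cfg)
}

#' Fit the DAZZLE model to an expression matrix
#'
#' Runs the training loop: each iteration is one full pass over the cells
#' in shuffled mini-batches; at every optimizer step a fresh dropout-
#' augmentation mask is sampled and applied, the batch is encoded, decoded
#' and classified, the composite loss (with the delayed L1 schedule) is
#' backpropagated, and a single Adam step updates all parameters — the
#' adjacency matrix with `lr_adj`, everything else with `lr_nn`. Runs are
#' fully reproducible from `seed`.
#'
#' @param x A log-transformed [expression_matrix()].
#' @param ... Configuration overrides passed to [dazzle_config()].
#' @param config A ready-made [dazzle_config()] (overrides `...`).
#' @param eval_truth Optional `grn_truth` (or list with `edges`, `tf_names`);
#'   when supplied, the AUPRC ratio against it is recorded every
#'   `eval_every` iterations in the trace.
#' @param eval_every Evaluation stride for `eval_truth`.
#' @return A `dazzle_fit`: list with the trained `model`, a `trace` tibble
#'   (one row per iteration: loss components, wall time, optional metric),
#'   and the resolved `config`.
#' @export
#' @examples
#' world <- make_world(m = 10, n = 60, seed = 1)
#' fit <- dazzle_train(world$expression_observed, n_iterations = 6,
#'                     batch_size = 30, seed = 1)
#' tidy(fit)
dazzle_train <- function(x, ..., config = NULL, eval_truth = NULL,
                         eval_every = 1) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!is_log_transformed(x)) {
    stop("dazzle_train expects log-transformed input; call log_transform() first",
         call. = FALSE)
  }
  cfg <- if (is.null(config)) dazzle_config(...) else config
  validate_config(cfg)
  n <- nrow(x); m <- ncol(x)
  if (m < 2) stop("need at least 2 genes", call. = FALSE)
  v <- expr_values(x)

  set.seed(cfg$seed)
  model <- new_dazzle_model(gene_names(x), hidden = cfg$hidden, net = cfg$net)
  model$center[] <- colMeans(v)
  opt <- adam_new_state(model[c("A", "enc", "dec", "lv", "clf")])
  t_adam <- 0L
  lr_of <- function(name) if (name == "A") cfg$lr_adj else cfg$lr_nn

  batch_size <- min(cfg$batch_size, n)
  trace <- vector("list", cfg$n_iterations)

  for (it in seq_len(cfg$n_iterations) - 1L) {
    t0 <- proc.time()[["elapsed"]]
    alpha_eff <- if (it < cfg$sparse_delay) 0 else cfg$alpha
    order_ <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    comp_sum <- c(reconstruction = 0, kl = 0, l1_sparse = 0, bce = 0, total = 0)

    for (s in starts) {
      idx <- order_[s:min(s + batch_size - 1L, n)]
      xb <- v[idx, , drop = FALSE]
      mask <- matrix(stats::runif(length(xb)) < cfg$da_prob,
                     nrow(xb), ncol(xb))
      res <- tryCatch(
        dazzle_backward(model, xb, mask, alpha_eff, cfg$beta, cfg$gamma,
                        stochastic = cfg$stochastic),
        error = function(e) {
          e$trace <- dplyr::bind_rows(trace[seq_len(it)])
          stop(e)
        })
      t_adam <- t_adam + 1L
      for (name in c("A", "enc", "dec", "lv", "clf")) {
        if (is.null(res$grads[[name]])) next
        upd <- adam_update(model[[name]], res$grads[[name]], opt[[name]],
                           lr_of(name), t_adam)
        model[[name]] <- upd$p
        opt[[name]] <- upd$s
      }
      diag(model$A) <- 0
      cc <- res$components
      comp_sum <- comp_sum + c(cc$reconstruction, cc$kl, cc$l1_sparse,
                               cc$bce, cc$total)
    }

    comp <- comp_sum / length(starts)
    row <- tibble::tibble(
      iteration = it + 1L,
      reconstruction = comp[["reconstruction"]],
      kl = comp[["kl"]],
      l1_sparse = comp[["l1_sparse"]],
      bce = comp[["bce"]],
      alpha_effective = alpha_eff,
      l1_contribution = alpha_eff * comp[["l1_sparse"]],
      total = comp[["total"]],
      seconds = proc.time()[["elapsed"]] - t0,
      auprc_ratio = NA_real_
    )
    if (!is.null(eval_truth) && (it %% eval_every == 0 ||
                                 it == cfg$n_iterations - 1L)) {
      metrics <- evaluate_grn(adjacency_matrix(model$A, gene_names(x)),
                              eval_truth)
      row$auprc_ratio <- metrics$auprc_ratio
    }
    trace[[it + 1L]] <- row
  }

  structure(list(model = model,
                 trace = dplyr::bind_rows(trace),
                 config = cfg,
                 n_cells = n, n_genes = m),
            class = "dazzle_fit")
}

#' @export
print.dazzle_fit <- function(x, ...) {
  cat(sprintf(
    "<dazzle_fit> %d genes x %d cells, %d iterations (seed %d)\n",
    x$n_genes, x$n_cells, nrow(x$trace), x$config$seed))
  cat(sprintf("  final loss %.4f (recon %.4f, kl %.4f, bce %.4f, |A|_1 %.4f)\n",
              utils::tail(x$trace$total, 1),
              utils::tail(x$trace$reconstruction, 1),
              utils::tail(x$trace$kl, 1),
              utils::tail(x$trace$bce, 1),
              utils::tail(x$trace$l1_sparse, 1)))
  invisible(x)
}

#' Ensemble training over independently seeded runs
#'
#' Trains `ensemble_runs` models with seeds `seed + 0 ... seed + k - 1` and
#' aggregates them as the elementwise mean of the absolute adjacency
#' matrices (rankings use magnitudes, so the aggregate is on |A|).
#'
#' @inheritParams dazzle_train
#' @return A `dazzle_ensemble`: list with `adjacency` (the aggregated
#'   [adjacency_matrix()]), `fits` (the individual `dazzle_fit`s), and
#'   `config`.
#' @export
dazzle_ensemble <- function(x, ..., config = NULL) {
  cfg <- if (is.null(config)) dazzle_config(...) else config
  k <- cfg$ensemble_runs
  if (k < 1) stop("ensemble_runs must be >= 1", call. = FALSE)
  fits <- vector("list", k)
  for (i in seq_len(k)) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i - 1L
    fits[[i]] <- tryCatch(
      dazzle_train(x, config = cfg_i),
      error = function(e) {
        stop(sprintf("ensemble member with seed %d failed: %s",
                     cfg_i$seed, conditionMessage(e)), call. = FALSE)
      })
  }
  acc <- Reduce(`+`, lapply(fits, function(f) abs(f$model$A))) / k
  structure(list(adjacency = adjacency_matrix(acc, gene_names(x)),
                 fits = fits, config = cfg),
            class = "dazzle_ensemble")
}

#' @export
print.dazzle_ensemble <- function(x, ...) {
  cat(sprintf("<dazzle_ensemble> %d runs, %d genes\n",
              length(x$fits), nrow(x$adjacency)))
  invisible(x)
}

# ---- broom-style methods ---------------------------------------------------

#' Tidy a fitted network into an edge tibble
#'
#' @param x A `dazzle_fit` or `dazzle_ensemble`.
#' @param threshold Minimum absolute edge weight (default 0.001).
#' @param ... Unused.
#' @return Tibble of ranked edges; see [extract_edges()].
#' @export
tidy.dazzle_fit <- function(x, threshold = 0.001, ...) {
  extract_edges(get_adjacency(x), threshold = threshold)
}

#' @rdname tidy.dazzle_fit
#' @export
tidy.dazzle_ensemble <- function(x, threshold = 0.001, ...) {
  extract_edges(x$adjacency, threshold = threshold)
}

#' One-row summary of a fit
#'
#' @param x A `dazzle_fit`.
#' @param ... Unused.
#' @return One-row tibble: dimensions, iterations, final loss components,
#'   and the number of threshold-surviving edges.
#' @export
glance.dazzle_fit <- function(x, ...) {
  last <- utils::tail(x$trace, 1)
  tibble::tibble(
    n_cells = x$n_cells, n_genes = x$n_genes,
    n_iterations = nrow(x$trace),
    reconstruction = last$reconstruction, kl = last$kl,
    bce = last$bce, l1_sparse = last$l1_sparse, total = last$total,
    n_edges = nrow(extract_edges(x)), seed = x$config$seed
  )
}

#' Plot training diagnostics
#'
#' Loss components (and the AUPRC ratio when recorded) per iteration.
#'
#' @param object A `dazzle_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dazzle_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$trace,
    cols = dplyr::any_of(c("reconstruction", "kl", "bce", "l1_sparse",
                           "l1_contribution", "total", "auprc_ratio")),
    names_to = "component", values_to = "value")
  long <- dplyr::filter(long, !is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "training iteration", y = NULL,
                  title = "DAZZLE training trace")
}

#' @rdname autoplot.dazzle_fit
#' @param x A `dazzle_fit`.
#' @param y Unused.
#' @export
plot.dazzle_fit <- function(x, y, ...) print(autoplot.dazzle_fit(x, ...))
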