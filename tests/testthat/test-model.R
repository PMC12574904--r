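random_adjacency <- function(m, seed, scale = 0.5) {
  set.seed(seed)
  A <- matrix(rnorm(m * m, sd = scale / sqrt(m)), m, m)
  diag(A) <- 0
  rho <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (rho >= 0.9) A <- A * 0.8 / rho
  A
}

identity_model <- function(m, A = NULL) {
  mod <- new_dazzle_model(paste0("g", seq_len(m)), hidden = 4,
                          net = "identity")
  if (!is.null(A)) mod$A <- A
  mod
}

test_that("adjacency construction zeroes the diagonal and validates", {
  A <- matrix(1, 3, 3)
  adj <- adjacency_matrix(A, c("a", "b", "c"))
  expect_equal(unname(diag(unclass(adj))), c(0, 0, 0))
  expect_error(adjacency_matrix(matrix(1, 2, 3)), "square")
  expect_error(adjacency_matrix(matrix(c(1, Inf, 0, 0), 2)), "finite")
})

test_that("encoder mean equals X'(I - A) with identity nets", {
  m <- 5
  mod <- identity_model(m)
  x <- matrix(abs(rnorm(4 * m)), 4, m)

  # A = 0: mean = X'
  z0 <- encode(x, mod, stochastic = FALSE)
  expect_equal(z0$mean, x)
  expect_equal(z0$sample, z0$mean)

  # zero input maps to zero
  expect_equal(encode(matrix(0, 2, m), mod, stochastic = FALSE)$mean,
               matrix(0, 2, m))

  # random A: independent dense multiply oracle
  mod$A <- random_adjacency(m, seed = 3)
  z <- encode(x, mod, stochastic = FALSE)
  expect_equal(z$mean, x %*% (diag(m) - mod$A), tolerance = 1e-12)
})

test_that("decoder inverts the encoder with identity nets", {
  mod <- identity_model(3)
  z <- list(mean = matrix(1:6, 2), log_var = matrix(0, 2, 3),
            sample = matrix(1:6 / 2, 2))
  # A = 0: x_hat = z$sample
  expect_equal(decode(z, mod), z$sample)
  # zero latent decodes to zero
  z0 <- list(sample = matrix(0, 2, 3), mean = matrix(0, 2, 3),
             log_var = matrix(0, 2, 3))
  expect_equal(decode(z0, mod), matrix(0, 2, 3))

  # encode-decode round trip across random adjacencies, m up to 50
  for (m in c(5, 20, 50)) {
    mod <- identity_model(m, A = random_adjacency(m, seed = m))
    x <- matrix(abs(rnorm(10 * m)), 10, m)
    xr <- decode(encode(x, mod, stochastic = FALSE), mod)
    expect_lt(max(abs(xr - x)), 1e-5)
  }
})

test_that("singular (I - A) is reported with advice", {
  mod <- identity_model(2)
  mod$A <- matrix(c(0, 1, 1, 0), 2)  # (I - A) singular
  z <- list(sample = matrix(1, 1, 2), mean = matrix(1, 1, 2),
            log_var = matrix(0, 1, 2))
  expect_error(decode(z, mod), "singular")
})

test_that("dropout classifier starts at 0.5 and stays in (0,1)", {
  mod <- new_dazzle_model(paste0("g", 1:4), hidden = 8)
  z <- encode(matrix(abs(rnorm(20)), 5, 4), mod, stochastic = FALSE)
  p <- classify_dropout(z, mod)
  # zero-initialized final layer: sigmoid(0) = 0.5 everywhere
  expect_equal(p, matrix(0.5, 5, 4))

  mod$clf$w3 <- rnorm(8, sd = 3)
  mod$clf$b3 <- 1
  p2 <- classify_dropout(z, mod)
  expect_true(all(p2 > 0 & p2 < 1))
})

test_that("binary cross entropy matches closed forms and a scalar loop", {
  mask <- matrix(FALSE, 2, 2)
  expect_equal(bce_loss(mask, matrix(0.5, 2, 2)), log(2))
  # perfect classifier after clamping
  perfect <- matrix(c(1, 0, 0, 1), 2)
  expect_lt(bce_loss(perfect == 1, perfect), 1e-7)

  set.seed(11)
  m4 <- matrix(runif(16) < 0.4, 4, 4)
  p4 <- matrix(runif(16, 0.05, 0.95), 4, 4)
  loop <- 0
  for (i in 1:4) for (j in 1:4) {
    loop <- loop - (m4[i, j] * log(p4[i, j]) +
                      (1 - m4[i, j]) * log(1 - p4[i, j]))
  }
  expect_equal(bce_loss(m4, p4), loop / 16, tolerance = 1e-12)
  expect_error(bce_loss(m4, p4[1:2, ]), "shape")
})

test_that("KL divergence matches the Gaussian closed form", {
  z <- list(mean = matrix(0, 3, 2), log_var = matrix(0, 3, 2))
  expect_equal(kl_divergence(z), 0)
  z1 <- list(mean = matrix(1, 1, 1), log_var = matrix(0, 1, 1))
  expect_equal(kl_divergence(z1), 0.5)

  set.seed(2)
  mu <- matrix(rnorm(12), 3, 4)
  lv <- matrix(rnorm(12, sd = 0.5), 3, 4)
  loop <- mean(sapply(1:3, function(i) {
    sum(0.5 * (exp(lv[i, ]) + mu[i, ]^2 - 1 - lv[i, ]))
  }))
  expect_equal(kl_divergence(list(mean = mu, log_var = lv)), loop,
               tolerance = 1e-12)
})

test_that("KL divergence is nonnegative over random latent states", {
  set.seed(9)
  for (i in 1:50) {
    z <- list(mean = matrix(rnorm(20, sd = runif(1, 0, 3)), 4, 5),
              log_var = matrix(rnorm(20, sd = runif(1, 0, 2)), 4, 5))
    expect_gte(kl_divergence(z), 0)
  }
})

test_that("reconstruction loss is mean squared error", {
  x <- matrix(c(0, 1, 2, 3), 2)
  expect_equal(reconstruction_loss(x, x), 0)
  expect_equal(reconstruction_loss(matrix(0, 1, 1), matrix(2, 1, 1)), 4)
  set.seed(4)
  a <- matrix(rnorm(9), 3); b <- matrix(rnorm(9), 3)
  loop <- 0
  for (i in 1:3) for (j in 1:3) loop <- loop + (a[i, j] - b[i, j])^2
  expect_equal(reconstruction_loss(a, b), loop / 9, tolerance = 1e-12)
})

test_that("loss composition applies the delay schedule and recomposes", {
  A <- matrix(c(0, 2, -3, 0), 2)
  lc <- compose_loss(reconstruction = 1.5, kl = 0.25, bce = 0.7,
                     adjacency = A, alpha = 0.4, beta = 2, gamma = 3,
                     iteration = 0, sparse_delay = 5)
  expect_equal(lc$l1_sparse, 5)
  expect_equal(lc$alpha_effective, 0)   # withheld before the delay
  expect_equal(lc$total, 1.5 + 2 * 0.25 + 3 * 0.7)

  lc5 <- compose_loss(1.5, 0.25, 0.7, A, alpha = 0.4, beta = 2, gamma = 3,
                      iteration = 5, sparse_delay = 5)
  expect_equal(lc5$alpha_effective, 0.4)
  # exact recomposition from independently recomputed parts
  expect_equal(lc5$total,
               1.5 + 0.4 * sum(abs(A)) + 2 * 0.25 + 3 * 0.7,
               tolerance = 1e-10)

  # all-zero coefficients leave only the reconstruction
  expect_equal(compose_loss(1.5, 9, 9, A, 0, 0, 0, iteration = 9)$total, 1.5)
  expect_error(compose_loss(1, 1, 1, A, alpha = -1), "nonnegative")
})

test_that("edge extraction thresholds on |w| and ranks deterministically", {
  A <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  A["a", "b"] <- 0.5
  A["b", "c"] <- -0.7
  A["c", "a"] <- 0.0005
  ed <- extract_edges(adjacency_matrix(A), threshold = 0.001)
  expect_equal(nrow(ed), 2)                     # 0.0005 excluded
  expect_equal(ed$weight, c(-0.7, 0.5))         # sorted by |w| descending
  expect_equal(ed$regulator, c("b", "a"))

  expect_equal(nrow(extract_edges(adjacency_matrix(matrix(0, 2, 2)))), 0)

  # ties break lexicographically by (regulator, target)
  At <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  At["b", "a"] <- 0.3; At["a", "c"] <- 0.3; At["a", "b"] <- 0.3
  et <- extract_edges(adjacency_matrix(At))
  expect_equal(paste(et$regulator, et$target), c("a b", "a c", "b a"))
})
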