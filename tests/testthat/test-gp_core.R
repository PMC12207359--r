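# Deep kernel GP core: extractor contracts, kernel values, closed
# forms, analytic gradients and the DKL baseline.

test_that("extractor is a deterministic pointwise map", {
  net <- mlp_init(6, hidden = c(5, 4), latent_dim = 3, seed = 2)
  X <- matrix(rnorm(8 * 6), 8, 6)
  X[3, ] <- X[1, ]
  Z <- mlp_forward(net, X)$Z
  expect_equal(Z[3, ], Z[1, ])                       # identical rows
  expect_identical(Z, mlp_forward(net, X)$Z)         # determinism
  rowwise <- t(vapply(seq_len(8), function(i) {
    drop(mlp_forward(net, X[i, , drop = FALSE])$Z)
  }, numeric(3)))
  expect_equal(Z, rowwise)                           # batching equivalence
  expect_error(mlp_forward(net, matrix(NA_real_, 1, 6)), "non-finite")
})

test_that("kernel matrix matches the direct formula and its limits", {
  theta <- gp_hyper(0.3, log(1.7), log(0.1))
  Z <- matrix(rnorm(8), 4, 2)
  for (kern in c("rbf", "matern52")) {
    K <- kernel_matrix(theta, Z, kernel = kern)
    expect_equal(K, oracle_kernel(theta, Z, Z, kern), tolerance = 1e-10)
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_equal(unname(diag(K)), rep(1.7, 4))       # k(z, z) = outputscale
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
    # decay with distance
    far <- kernel_matrix(theta, matrix(c(0, 0), 1), matrix(c(50, 50), 1),
                         kernel = kern)
    expect_lt(far[1, 1], 1e-8)
  }
  expect_error(kernel_matrix(gp_hyper(), matrix(NaN, 1, 1)), "non-finite")
})

test_that("NLML reproduces the univariate closed form and is exchangeable", {
  # n = 1, y = 0, k(x,x) + noise = 1  ->  0.5 log(2 pi)
  model <- deep_kernel(NULL, gp_hyper(0, log(0.5), log(0.5)))
  expect_equal(nlml(model, matrix(0, 1, 1), 0), 0.5 * log(2 * pi),
               tolerance = 1e-12)
  # permuting rows leaves the joint Gaussian unchanged
  inst <- random_gp_instance(17)
  perm <- sample(inst$n)
  expect_equal(nlml(inst$model, inst$X, inst$y),
               nlml(inst$model, inst$X[perm, , drop = FALSE],
                    inst$y[perm]),
               tolerance = 1e-10)
})

test_that("analytic NLML gradients match finite differences", {
  for (seed in c(3, 11)) {
    inst <- random_gp_instance(seed)
    g <- dkmeta:::nlml_grad(inst$model, inst$X, inst$y)
    eps <- 1e-6
    fd_gp <- vapply(1:3, function(i) {
      m1 <- inst$model; m2 <- inst$model
      m1$theta_gp[i] <- m1$theta_gp[i] + eps
      m2$theta_gp[i] <- m2$theta_gp[i] - eps
      (nlml(m1, inst$X, inst$y) - nlml(m2, inst$X, inst$y)) / (2 * eps)
    }, 1)
    expect_equal(unname(g$g_gp), fd_gp, tolerance = 1e-5)
    v <- dkmeta:::nn_flatten(inst$model$nn)
    probe <- round(seq(1, length(v), length.out = 5))
    fd_nn <- vapply(probe, function(i) {
      v1 <- v; v2 <- v
      v1[i] <- v1[i] + eps; v2[i] <- v2[i] - eps
      m1 <- inst$model; m2 <- inst$model
      m1$nn <- dkmeta:::nn_unflatten(inst$model$nn, v1)
      m2$nn <- dkmeta:::nn_unflatten(inst$model$nn, v2)
      (nlml(m1, inst$X, inst$y) - nlml(m2, inst$X, inst$y)) / (2 * eps)
    }, 1)
    expect_equal(dkmeta:::nn_grad_flatten(g$g_nn)[probe], fd_nn,
                 tolerance = 1e-5)
  }
})

test_that("posterior limits: prior fallback and noise-free interpolation", {
  model <- deep_kernel(NULL, gp_hyper(0, log(1.2), log(0.3)))
  Xq <- matrix(rnorm(6), 3, 2)
  post <- predictive_posterior(model, NULL, NULL, Xq)
  expect_equal(post$mean, rep(0, 3))
  expect_equal(post$variance, rep(1.2 + 0.3, 3))
  # query on a support point with vanishing noise recovers its label
  model2 <- deep_kernel(NULL, gp_hyper(0, 0, log(1e-10)))
  Xs <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  post2 <- predictive_posterior(model2, Xs, c(1, -1),
                                Xs[1, , drop = FALSE])
  expect_equal(post2$mean, 1, tolerance = 1e-6)
  expect_lt(post2$variance, 1e-6)
})

test_that("classification link is symmetric, monotone and label-antisymmetric", {
  expect_equal(classify_prob(0, 2.5), 0.5)
  expect_gt(classify_prob(50, 1), 0.999)
  means <- seq(-3, 3, by = 0.5)
  expect_true(all(diff(classify_prob(means, 1.3)) > 0))
  # negating support labels negates the mean and flips probabilities
  inst <- random_gp_instance(23)
  Xq <- matrix(rnorm(3 * inst$d), 3, inst$d)
  p1 <- predictive_posterior(inst$model, inst$X, inst$y, Xq)
  p2 <- predictive_posterior(inst$model, inst$X, -inst$y, Xq)
  expect_equal(p2$mean, -p1$mean, tolerance = 1e-10)
  expect_equal(p2$probability, 1 - p1$probability, tolerance = 1e-10)
  expect_equal(classify(p1), p1$probability)
})

test_that("single-task DKL respects optimizer contracts", {
  suite <- generate_tasks(synthetic_spec(n_tasks = 1, n_per_task = 60,
                                         dim = 10, seed = 5))
  cfg0 <- dkl_config(n_iters = 3, lr = 0, hidden = 6, latent_dim = 3,
                     seed = 2)
  fit0 <- train_dkl(suite$X, suite$y, cfg0)
  init <- mlp_init(ncol(suite$X), 6, 3,
                   seed = dkmeta:::derive_seeds(2, 2)[1])
  # learning rate zero leaves every parameter at its initialization
  expect_equal(dkmeta:::nn_flatten(fit0$nn), dkmeta:::nn_flatten(init))
  expect_equal(fit0$theta_gp, gp_hyper())
  cfg <- dkl_config(n_iters = 15, lr = 0.05, hidden = 6, latent_dim = 3,
                    seed = 2)
  fit1 <- train_dkl(suite$X, suite$y, cfg)
  fit2 <- train_dkl(suite$X, suite$y, cfg)
  expect_identical(fit1$theta_gp, fit2$theta_gp)     # seed determinism
  expect_identical(dkmeta:::nn_flatten(fit1$nn),
                   dkmeta:::nn_flatten(fit2$nn))
  expect_equal(nrow(fit1$history), 15)
  expect_error(train_dkl(suite$X, rep(1, nrow(suite$X)), cfg),
               "both classes")
})
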