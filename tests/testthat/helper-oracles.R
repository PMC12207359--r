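# Independent brute-force oracles used to validate the fast paths.

# Dense GP oracle: explicit inverse and determinant, no Cholesky.
oracle_nlml <- function(Ky, y) {
  n <- length(y)
  0.5 * drop(t(y) %*% solve(Ky) %*% y) +
    0.5 * determinant(Ky, logarithm = TRUE)$modulus[1] +
    0.5 * n * log(2 * pi)
}

oracle_posterior <- function(Kss_noisy, Kqs, kqq_diag_noisy, ys) {
  Kinv <- solve(Kss_noisy)
  mean <- drop(Kqs %*% Kinv %*% ys)
  variance <- kqq_diag_noisy - diag(Kqs %*% Kinv %*% t(Kqs))
  list(mean = mean, variance = variance)
}

oracle_log_joint <- function(Kss_noisy, Kqs, Kqq_noisy, ys, yq) {
  Kinv <- solve(Kss_noisy)
  mu <- drop(Kqs %*% Kinv %*% ys)
  S <- Kqq_noisy - Kqs %*% Kinv %*% t(Kqs)
  r <- yq - mu
  -0.5 * drop(t(r) %*% solve(S) %*% r) -
    0.5 * determinant(S, logarithm = TRUE)$modulus[1] -
    0.5 * length(yq) * log(2 * pi)
}

# Direct elementwise kernel formula (no matrix shortcuts).
oracle_kernel <- function(theta_gp, Z1, Z2, kernel = "rbf") {
  ell <- exp(theta_gp[["log_lengthscale"]])
  s2 <- exp(theta_gp[["log_outputscale"]])
  K <- matrix(0, nrow(Z1), nrow(Z2))
  for (i in seq_len(nrow(Z1))) {
    for (j in seq_len(nrow(Z2))) {
      r <- sqrt(sum((Z1[i, ] - Z2[j, ])^2))
      K[i, j] <- if (kernel == "rbf") {
        s2 * exp(-r^2 / (2 * ell^2))
      } else {
        t5 <- sqrt(5) * r / ell
        s2 * (1 + t5 + t5^2 / 3) * exp(-t5)
      }
    }
  }
  K
}

# Exhaustive rank-walk average precision: walks the distinct score
# thresholds in descending order accumulating (recall step) x precision.
oracle_auprc <- function(labels, scores) {
  P <- sum(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  r_prev <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel])
    prec <- tp / sum(sel)
    rec <- tp / P
    ap <- ap + (rec - r_prev) * prec
    r_prev <- rec
  }
  ap
}

# Brute-force nearest-prototype classifier: explicit loops everywhere.
oracle_protonet <- function(net, Xs, ys, Xq) {
  Zs <- mlp_forward(net, Xs)$Z
  Zq <- mlp_forward(net, Xq)$Z
  classes <- sort(unique(ys))
  protos <- lapply(classes, function(c) {
    colMeans(Zs[ys == c, , drop = FALSE])
  })
  prob1 <- numeric(nrow(Zq))
  hard <- integer(nrow(Zq))
  for (q in seq_len(nrow(Zq))) {
    d2 <- vapply(protos, function(p) sum((Zq[q, ] - p)^2), 1)
    e <- exp(-d2 - max(-d2))
    p <- e / sum(e)
    prob1[q] <- p[classes == 1]
    hard[q] <- classes[which.max(p)]
  }
  list(probability = prob1, class = hard)
}

# Random tiny deep-kernel instances for oracle comparisons.
random_gp_instance <- function(seed, identity = FALSE, max_n = 8) {
  withr::with_seed(seed, {
    n <- sample(2:max_n, 1)
    d <- sample(2:4, 1)
    X <- matrix(rnorm(n * d), n, d)
    y <- sample(c(-1, 1), n, replace = TRUE)
    nn <- if (identity) NULL else
      mlp_init(d, hidden = 3, latent_dim = 2, seed = seed + 1)
    theta <- gp_hyper(runif(1, -0.5, 0.5), runif(1, -0.5, 0.5),
                      log(runif(1, 0.05, 0.5)))
    list(model = deep_kernel(nn, theta,
                             sample(c("rbf", "matern52"), 1)),
         X = X, y = y, n = n, d = d)
  })
}
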