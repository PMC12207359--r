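# Deep kernel Gaussian-process machinery.
#
# A deep kernel applies a stationary base kernel to the output of a
# learned feature extractor: k(x, x') = k'(f(x), f(x') | theta_GP).
# Classification is performed as GP label regression on targets {-1,+1}
# with a Gaussian likelihood, which keeps the marginal likelihood and
# the joint predictive density in closed form -- the quantities the
# meta-learning objectives are built from.  Class probabilities are
# obtained by squashing the predictive mean with its variance.

#' Base-kernel hyperparameters
#'
#' All three hyperparameters are stored in log space so the constrained
#' quantities (lengthscale, signal variance, noise variance) remain
#' strictly positive under unconstrained gradient updates.
#'
#' @param log_lengthscale log of the kernel lengthscale.
#' @param log_outputscale log of the signal variance.
#' @param log_noise log of the Gaussian observation-noise variance.
#' @return Named numeric vector of length 3.
#' @export
gp_hyper <- function(log_lengthscale = 0, log_outputscale = 0,
                     log_noise = log(0.1)) {
  out <- c(log_lengthscale = unname(log_lengthscale),
           log_outputscale = unname(log_outputscale),
           log_noise = unname(log_noise))
  stop_if_not_finite(out, "GP hyperparameters")
  out
}

#' Deep kernel parameter bundle
#'
#' @param nn feature extractor created by [mlp_init()], or `NULL` for the
#'   identity extractor (the base kernel then acts on the raw inputs).
#' @param theta_gp base-kernel hyperparameters from [gp_hyper()].
#' @param kernel base kernel: `"rbf"` (squared exponential, default) or
#'   `"matern52"`.
#' @return Object of class `deep_kernel`.
#' @export
deep_kernel <- function(nn = NULL, theta_gp = gp_hyper(),
                        kernel = c("rbf", "matern52")) {
  kernel <- match.arg(kernel)
  if (!is.null(nn)) stopifnot(inherits(nn, "dkmeta_mlp"))
  stop_if_not_finite(theta_gp, "GP hyperparameters")
  structure(list(nn = nn, theta_gp = theta_gp, kernel = kernel),
            class = "deep_kernel")
}

#' @export
print.deep_kernel <- function(x, ...) {
  cat("<deep_kernel>", x$kernel, "base kernel;",
      if (is.null(x$nn)) "identity extractor" else
        paste("extractor", paste(x$nn$dims, collapse = " -> ")), "\n")
  cat("  lengthscale", signif(exp(x$theta_gp[["log_lengthscale"]]), 4),
      " outputscale", signif(exp(x$theta_gp[["log_outputscale"]]), 4),
      " noise", signif(exp(x$theta_gp[["log_noise"]]), 4), "\n")
  invisible(x)
}

#' Map inputs to latent embeddings
#'
#' @param model a `deep_kernel`.
#' @param X numeric matrix of inputs (rows are examples).
#' @return Embedding matrix with one row per input row; `X` itself for
#'   the identity extractor.
#' @export
embed <- function(model, X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  stop_if_not_finite(X, "inputs")
  if (is.null(model$nn)) return(X)
  mlp_forward(model$nn, X)$Z
}

# Pairwise squared Euclidean distances (cross when Z2 given).
pairwise_sqdist <- function(Z1, Z2 = NULL) {
  if (is.null(Z2)) Z2 <- Z1
  D2 <- outer(rowSums(Z1^2), rowSums(Z2^2), "+") - 2 * tcrossprod(Z1, Z2)
  D2[D2 < 0] <- 0
  D2
}

# Base kernel as a function of u = D^2 / lengthscale^2, and its
# derivative with respect to u (shared by hyperparameter and embedding
# gradients).
kernel_shape <- function(u, s2, kernel) {
  switch(kernel,
    rbf = s2 * exp(-u / 2),
    matern52 = {
      t <- sqrt(5 * u)
      s2 * (1 + t + t^2 / 3) * exp(-t)
    },
    stop("unknown kernel: ", kernel))
}

kernel_shape_du <- function(u, s2, kernel) {
  switch(kernel,
    rbf = -s2 / 2 * exp(-u / 2),
    matern52 = {
      t <- sqrt(5 * u)
      -s2 * (5 / 6) * (1 + t) * exp(-t)
    },
    stop("unknown kernel: ", kernel))
}

#' Gram matrix of the base kernel on embeddings
#'
#' @param theta_gp hyperparameters from [gp_hyper()].
#' @param Z1,Z2 embedding matrices; `Z2 = NULL` gives the square Gram
#'   matrix of `Z1` (noise is never added here).
#' @param kernel `"rbf"` or `"matern52"`.
#' @return `nrow(Z1) x nrow(Z2)` covariance matrix.
#' @export
kernel_matrix <- function(theta_gp, Z1, Z2 = NULL,
                          kernel = c("rbf", "matern52")) {
  kernel <- match.arg(kernel)
  stop_if_not_finite(theta_gp, "GP hyperparameters")
  if (!is.matrix(Z1)) Z1 <- as.matrix(Z1)
  if (!is.null(Z2) && !is.matrix(Z2)) Z2 <- as.matrix(Z2)
  stop_if_not_finite(Z1, "embeddings")
  if (!is.null(Z2)) stop_if_not_finite(Z2, "embeddings")
  ell2 <- exp(2 * theta_gp[["log_lengthscale"]])
  s2 <- exp(theta_gp[["log_outputscale"]])
  u <- pairwise_sqdist(Z1, Z2) / ell2
  K <- kernel_shape(u, s2, kernel)
  if (is.null(Z2)) K <- (K + t(K)) / 2  # exact symmetry
  K
}

# Cholesky with escalating diagonal jitter (base 1e-6 * outputscale,
# at most 3 escalations of x10) and a conditioning diagnostic on failure.
safe_chol <- function(M, jitter0) {
  for (j in c(0, jitter0, 10 * jitter0, 100 * jitter0)) {
    Mj <- M
    if (j > 0) diag(Mj) <- diag(Mj) + j
    L <- tryCatch(chol(Mj), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = j))
  }
  ev <- range(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  stop(sprintf(
    "covariance not positive definite after jitter escalation (eigenvalue range [%.3e, %.3e])",
    ev[1], ev[2]), call. = FALSE)
}

chol_solve <- function(L, b) backsolve(L, backsolve(L, b, transpose = TRUE))

# Shared fit: embeddings, noisy Gram, Cholesky factor, alpha = Ky^{-1} y.
gp_prepare <- function(model, X, y, cache_nn = FALSE) {
  if (!is.matrix(X)) X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  stop_if_not_finite(y, "targets")
  tg <- model$theta_gp
  ell2 <- exp(2 * tg[["log_lengthscale"]])
  s2 <- exp(tg[["log_outputscale"]])
  noise <- exp(tg[["log_noise"]])
  fw <- if (is.null(model$nn)) list(Z = X) else
    mlp_forward(model$nn, X, cache = cache_nn)
  u <- pairwise_sqdist(fw$Z) / ell2
  K <- kernel_shape(u, s2, model$kernel)
  Ky <- K
  diag(Ky) <- diag(Ky) + noise
  ch <- safe_chol(Ky, 1e-6 * s2)
  alpha <- chol_solve(ch$L, y)
  list(Z = fw$Z, cache = fw$cache, u = u, K = K, L = ch$L, alpha = alpha,
       ell2 = ell2, s2 = s2, noise = noise)
}

#' Negative log marginal likelihood of a deep kernel GP
#'
#' Returns `-log N(y | 0, K + noise I)` where `K` is the deep-kernel Gram
#' matrix of `X`.  This is the training loss for single-task deep kernel
#' learning, the per-task term of the DKT objective, and (restricted to
#' a support set) the inner-loop loss of ADKF and ADKF-prior.
#'
#' @param model a [deep_kernel()].
#' @param X input matrix.
#' @param y numeric targets (class labels are encoded as -1/+1).
#' @return scalar negative log marginal likelihood.
#' @export
nlml <- function(model, X, y) {
  p <- gp_prepare(model, X, y)
  n <- length(y)
  0.5 * sum(y * p$alpha) + sum(log(diag(p$L))) + 0.5 * n * log(2 * pi)
}

# Value and analytic gradients of the NLML with respect to the GP
# hyperparameters (log-space) and, when an extractor is present, its
# weights.  dL/dKy = 0.5 (Ky^{-1} - alpha alpha^T).
nlml_grad <- function(model, X, y) {
  p <- gp_prepare(model, X, y, cache_nn = !is.null(model$nn))
  n <- length(y)
  value <- 0.5 * sum(y * p$alpha) + sum(log(diag(p$L))) +
    0.5 * n * log(2 * pi)
  Kinv <- chol2inv(p$L)
  G <- 0.5 * (Kinv - tcrossprod(p$alpha))
  dgdu <- kernel_shape_du(p$u, p$s2, model$kernel)
  g_gp <- c(
    log_lengthscale = sum(G * dgdu * (-2 * p$u)),
    log_outputscale = sum(G * p$K),
    log_noise = p$noise * sum(diag(G))
  )
  g_nn <- NULL
  if (!is.null(model$nn)) {
    A <- G * dgdu
    dZ <- (4 / p$ell2) * (rowSums(A) * p$Z - A %*% p$Z)
    g_nn <- mlp_backward(model$nn, p$cache, dZ)
  }
  list(value = value, g_gp = g_gp, g_nn = g_nn)
}

#' Predictive posterior on query points
#'
#' Standard Gaussian-process conditional given (noisy) support
#' observations.  With an empty support the prior is returned (zero mean,
#' variance = signal variance + noise).  The reported variance is the
#' predictive variance of a new observation (it includes the noise term),
#' and `probability` is the squashed class-1 probability used for AUPRC
#' scoring.
#'
#' @param model a [deep_kernel()].
#' @param support_X,support_y support inputs and targets (may be `NULL` /
#'   zero rows).
#' @param query_X query inputs.
#' @return Object of class `gp_posterior`: list of per-query `mean`,
#'   `variance` and `probability`.
#' @export
predictive_posterior <- function(model, support_X, support_y, query_X) {
  if (!is.matrix(query_X)) query_X <- as.matrix(query_X)
  tg <- model$theta_gp
  s2 <- exp(tg[["log_outputscale"]])
  noise <- exp(tg[["log_noise"]])
  m <- nrow(query_X)
  empty <- is.null(support_X) || NROW(support_X) == 0
  if (empty) {
    mean <- rep(0, m)
    variance <- rep(s2 + noise, m)
  } else {
    p <- gp_prepare(model, support_X, support_y)
    Zq <- embed(model, query_X)
    Kqs <- kernel_matrix(tg, Zq, p$Z, kernel = model$kernel)
    mean <- drop(Kqs %*% p$alpha)
    V <- backsolve(p$L, t(Kqs), transpose = TRUE)
    variance <- pmax(s2 + noise - colSums(V^2), 1e-12)
  }
  structure(list(mean = mean, variance = variance,
                 probability = classify_prob(mean, variance)),
            class = "gp_posterior")
}

#' @export
print.gp_posterior <- function(x, ...) {
  cat(sprintf("<gp_posterior> %d query points; mean in [%.3f, %.3f]\n",
              length(x$mean), min(x$mean), max(x$mean)))
  invisible(x)
}

#' Class probability from a Gaussian predictive
#'
#' Squashes a predictive mean/variance pair into a class-1 probability,
#' `plogis(mean / sqrt(1 + variance))`, so that more uncertain
#' predictions are pulled toward 0.5.
#'
#' @param mean,variance predictive moments (variance > 0).
#' @return probabilities in (0, 1).
#' @export
classify_prob <- function(mean, variance) {
  stopifnot(all(variance > 0))
  stats::plogis(mean / sqrt(1 + variance))
}

#' Class probabilities of a GP posterior
#'
#' @param posterior a `gp_posterior`.
#' @return numeric vector of class-1 probabilities.
#' @export
classify <- function(posterior) {
  stopifnot(inherits(posterior, "gp_posterior"))
  posterior$probability
}

#' Log joint predictive density of query targets given the support
#'
#' The log density of the query targets under the multivariate Gaussian
#' conditional of the GP given the support observations.  Its negation is
#' the outer-loop (meta) loss of ADKF and ADKF-prior.  Satisfies the
#' chain rule `log p(y_Q | y_S) = log p(y_{S+Q}) - log p(y_S)`.
#'
#' @inheritParams predictive_posterior
#' @param query_y query targets.
#' @return scalar log density.
#' @export
log_joint_predictive <- function(model, support_X, support_y, query_X,
                                 query_y) {
  if (!is.matrix(query_X)) query_X <- as.matrix(query_X)
  stopifnot(nrow(query_X) >= 1, nrow(query_X) == length(query_y))
  if (is.null(support_X) || NROW(support_X) == 0) {
    return(-nlml(model, query_X, query_y))
  }
  tg <- model$theta_gp
  noise <- exp(tg[["log_noise"]])
  p <- gp_prepare(model, support_X, support_y)
  Zq <- embed(model, query_X)
  Kqs <- kernel_matrix(tg, Zq, p$Z, kernel = model$kernel)
  Kqq <- kernel_matrix(tg, Zq, kernel = model$kernel)
  mu <- drop(Kqs %*% p$alpha)
  V <- backsolve(p$L, t(Kqs), transpose = TRUE)
  S <- Kqq - crossprod(V)
  diag(S) <- diag(S) + noise
  ch <- safe_chol(S, 1e-6 * p$s2)
  r <- query_y - mu
  beta <- chol_solve(ch$L, r)
  -0.5 * sum(r * beta) - sum(log(diag(ch$L))) -
    0.5 * length(query_y) * log(2 * pi)
}

# Encode class labels as GP regression targets.  Accepts {0,1} or
# {-1,+1}; other numeric vectors are passed through as-is.
labels_to_targets <- function(y) {
  u <- unique(y)
  if (all(u %in% c(0, 1))) return(2 * y - 1)
  y
}

#' Configuration for single-task deep kernel learning
#'
#' @param n_iters number of optimizer iterations.
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size (full batch when `n <= batch_size`).
#' @param hidden,latent_dim extractor architecture (ignored when
#'   `identity_extractor = TRUE`).
#' @param identity_extractor use the raw inputs as embeddings (plain GP
#'   hyperparameter fitting)?
#' @param kernel base kernel.
#' @param theta_gp_init initial hyperparameters.
#' @param seed integer seed (weights, mini-batches).
#' @return list of class `dkl_config`.
#' @export
dkl_config <- function(n_iters = 200, lr = 0.05, batch_size = 512,
                       hidden = c(256, 128), latent_dim = 64,
                       identity_extractor = FALSE,
                       kernel = c("rbf", "matern52"),
                       theta_gp_init = gp_hyper(), seed = 1) {
  structure(list(n_iters = n_iters, lr = lr, batch_size = batch_size,
                 hidden = hidden, latent_dim = latent_dim,
                 identity_extractor = identity_extractor,
                 kernel = match.arg(kernel),
                 theta_gp_init = theta_gp_init, seed = seed),
            class = "dkl_config")
}

#' Train a single-task deep kernel GP (DKL baseline)
#'
#' Jointly fits the extractor weights and base-kernel hyperparameters by
#' gradient-based minimization of the negative log marginal likelihood on
#' one dataset (mini-batched when `n` exceeds the batch size).
#'
#' @param X input matrix.
#' @param y binary labels in \{0, 1\} (internally regressed as -1/+1).
#' @param config a [dkl_config()].
#' @return A `dkmeta_model` (method `"dkl"`) with the fitted extractor,
#'   hyperparameters and the per-iteration loss trajectory in `$history`.
#' @export
train_dkl <- function(X, y, config = dkl_config()) {
  if (!is.matrix(X)) X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2) stop("training data must contain both classes")
  targ <- labels_to_targets(y)
  seeds <- derive_seeds(config$seed, 2)
  nn <- if (config$identity_extractor) NULL else
    mlp_init(ncol(X), config$hidden, config$latent_dim, seed = seeds[1])
  model <- deep_kernel(nn, config$theta_gp_init, config$kernel)
  par <- c(model$theta_gp, nn_flatten(nn))
  opt <- adam_init(length(par), lr = config$lr)
  n <- nrow(X)
  history <- numeric(config$n_iters)
  with_seed(seeds[2], {
    for (it in seq_len(config$n_iters)) {
      rows <- if (n > config$batch_size) sample.int(n, config$batch_size)
              else seq_len(n)
      model$theta_gp[] <- par[1:3]
      if (!is.null(nn)) model$nn <- nn_unflatten(nn, par[-(1:3)])
      g <- nlml_grad(model, X[rows, , drop = FALSE], targ[rows])
      if (!is.finite(g$value)) {
        stop(sprintf("DKL training diverged at iteration %d (loss %g)",
                     it, g$value))
      }
      history[it] <- g$value / length(rows)
      grad <- c(g$g_gp, if (!is.null(g$g_nn)) nn_grad_flatten(g$g_nn)) /
        length(rows)
      st <- adam_step(opt, par, grad)
      par <- st$par
      opt <- st$state
    }
  })
  model$theta_gp[] <- par[1:3]
  if (!is.null(nn)) model$nn <- nn_unflatten(nn, par[-(1:3)])
  structure(list(method = "dkl", nn = model$nn, theta_gp = model$theta_gp,
                 kernel = config$kernel, config = config,
                 history = data.frame(iter = seq_len(config$n_iters),
                                      loss = history)),
            class = "dkmeta_model")
}

# View a fitted dkmeta_model as a deep_kernel parameter bundle.
as_deep_kernel <- function(fit) {
  deep_kernel(fit$nn, fit$theta_gp, fit$kernel)
}

#' @export
print.dkmeta_model <- function(x, ...) {
  cat(sprintf("<dkmeta_model> method = %s, kernel = %s\n",
              x$method, x$kernel))
  if (!is.null(x$nn)) print(x$nn) else cat("  identity extractor\n")
  if (!is.null(x$log_sigma2))
    cat("  prior sigma^2 =", signif(exp(x$log_sigma2), 4), "\n")
  invisible(x)
}
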