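# Bayesian meta-learning trainers for deep kernel GPs (DKT, ADKF,
# ADKF-prior) and the prototypical-network baseline, plus the shared
# meta-test adaptation protocol.
#
# All three Bayesian methods share the hierarchical view: task-specific
# parameters are adapted per task on the support set (inner loop), meta
# parameters are learned across tasks from the query-set predictive
# loss (outer loop).
#   DKT        : no inner loop; one shared (theta_NN, theta_GP) fit by
#                the expected NLML over episodes.
#   ADKF       : inner loop adapts theta_GP on the support NLML; outer
#                loop meta-learns theta_NN from the negative log joint
#                predictive posterior of the query given the support.
#   ADKF-prior : theta_NN gets a Gaussian prior N(phi, sigma^2 I); the
#                inner loop adapts both theta_GP and theta_NN by MAP, in
#                the non-centred parameterization theta_NN = phi +
#                sigma * u with penalty ||u||^2 / 2; the outer loop
#                learns Psi_meta = [phi, sigma^2] with first-order
#                gradients (the inner solution treated as constant).

#' Meta-learning configuration
#'
#' @param support_size,query_size episode sizes used during
#'   meta-training (defaults 512/64; both are clamped per task when a
#'   task is too small).
#' @param task_batch number of tasks per outer iteration (default 5).
#' @param n_iters outer iterations.
#' @param outer_lr Adam learning rate of the outer loop.
#' @param inner_steps,inner_lr,inner_tol inner-loop gradient descent
#'   with backtracking: step count, initial step size, early-stop
#'   tolerance on the loss decrease.
#' @param eval_every validation cadence in outer iterations (model
#'   selection keeps the best validation-AUPRC parameters).
#' @param hidden,latent_dim feature-extractor architecture.
#' @param kernel base kernel (`"rbf"` or `"matern52"`).
#' @param theta_gp_init base-kernel hyperparameter initialization (also
#'   the per-task starting point of the ADKF/ADKF-prior inner loop).
#' @param log_sigma2_init initial log prior variance of the ADKF-prior
#'   Gaussian weight prior.
#' @param stratified stratify support draws by class?
#' @param seed integer seed.
#' @return list of class `meta_config`.
#' @export
meta_config <- function(support_size = 512, query_size = 64,
                        task_batch = 5, n_iters = 300, outer_lr = 1e-2,
                        inner_steps = 50, inner_lr = 0.1,
                        inner_tol = 1e-5, eval_every = 50,
                        hidden = c(256, 128), latent_dim = 64,
                        kernel = c("rbf", "matern52"),
                        theta_gp_init = gp_hyper(),
                        log_sigma2_init = log(1e-2),
                        stratified = TRUE, seed = 1) {
  stopifnot(support_size >= 2, query_size >= 1, task_batch >= 1,
            n_iters >= 1, inner_steps >= 0)
  structure(list(support_size = support_size, query_size = query_size,
                 task_batch = task_batch, n_iters = n_iters,
                 outer_lr = outer_lr, inner_steps = inner_steps,
                 inner_lr = inner_lr, inner_tol = inner_tol,
                 eval_every = eval_every, hidden = hidden,
                 latent_dim = latent_dim, kernel = match.arg(kernel),
                 theta_gp_init = theta_gp_init,
                 log_sigma2_init = log_sigma2_init,
                 stratified = stratified, seed = seed),
            class = "meta_config")
}

# Clamp the configured episode sizes to what a task can support.
effective_episode <- function(n_task, support_size, query_size) {
  q <- min(query_size, max(1L, n_task %/% 3L))
  s <- min(support_size, n_task - q)
  if (s < 2) stop("task too small for an episode", call. = FALSE)
  c(support = as.integer(s), query = as.integer(q))
}

# Draw one meta-training episode for a task (inside a with_seed block).
draw_episode <- function(task, y, config) {
  n <- length(task_indices(task))
  sz <- effective_episode(n, config$support_size, config$query_size)
  sample_episode(task, sz["support"], sz["query"],
                 stratified = config$stratified,
                 seed = sample.int(2147483646, 1), labels = y)
}

# Mean validation AUPRC of a scoring closure over the validation tasks.
validation_auprc <- function(valid_tasks, y, config, score_fn) {
  if (is.null(valid_tasks) || length(valid_tasks) == 0) return(NA_real_)
  scores <- vapply(valid_tasks, function(task) {
    ep <- draw_episode(task, y, config)
    prob <- score_fn(ep)
    auprc(y[ep$query], prob)
  }, 1)
  mean(scores)
}

#' DKT batch objective
#'
#' Mean negative log marginal likelihood over a batch of episodes, each
#' evaluated on the pooled support-plus-query rows of its task.  This is
#' the per-iteration loss of [train_dkt()]; on a batch of identical
#' full-task episodes it coincides with the single-task DKL objective.
#'
#' @param model a [deep_kernel()].
#' @param X,y dataset features and 0/1 labels.
#' @param episodes list of episodes (`list(support, query)`).
#' @return scalar mean NLML.
#' @export
dkt_batch_loss <- function(model, X, y, episodes) {
  targ <- labels_to_targets(y)
  mean(vapply(episodes, function(ep) {
    rows <- c(ep$support, ep$query)
    nlml(model, X[rows, , drop = FALSE], targ[rows])
  }, 1))
}

#' Train a deep kernel by deep kernel transfer (DKT)
#'
#' Learns one shared extractor and base-kernel hyperparameter set by
#' minimizing the expected NLML across episodes drawn from the training
#' tasks (batches of `task_batch` tasks per iteration).  At meta-test
#' time the shared deep kernel conditions on the support set without any
#' adaptation.
#'
#' @param X feature matrix.
#' @param y 0/1 labels.
#' @param train_tasks,valid_tasks lists of tasks ([new_task()] objects
#'   or row-index vectors).
#' @param config a [meta_config()].
#' @return A `dkmeta_model` (method `"dkt"`).
#' @export
train_dkt <- function(X, y, train_tasks, valid_tasks = NULL,
                      config = meta_config()) {
  if (!is.matrix(X)) X <- as.matrix(X)
  targ <- labels_to_targets(y)
  seeds <- derive_seeds(config$seed, 2)
  nn <- mlp_init(ncol(X), config$hidden, config$latent_dim,
                 seed = seeds[1])
  par <- c(config$theta_gp_init, nn_flatten(nn))
  opt <- adam_init(length(par), lr = config$outer_lr)
  best <- list(par = par, score = -Inf)
  history <- data.frame(iter = seq_len(config$n_iters), loss = NA_real_,
                        valid_auprc = NA_real_)
  model <- deep_kernel(nn, config$theta_gp_init, config$kernel)
  with_seed(seeds[2], {
    for (it in seq_len(config$n_iters)) {
      model$theta_gp[] <- par[1:3]
      model$nn <- nn_unflatten(nn, par[-(1:3)])
      batch <- sample(seq_along(train_tasks), config$task_batch,
                      replace = TRUE)
      loss <- 0
      grad <- numeric(length(par))
      for (b in batch) {
        ep <- draw_episode(train_tasks[[b]], y, config)
        rows <- c(ep$support, ep$query)
        g <- nlml_grad(model, X[rows, , drop = FALSE], targ[rows])
        if (!is.finite(g$value)) stop("DKT training diverged")
        sc <- length(rows) * config$task_batch
        loss <- loss + g$value / sc
        grad <- grad + c(g$g_gp, nn_grad_flatten(g$g_nn)) / sc
      }
      history$loss[it] <- loss
      st <- adam_step(opt, par, grad)
      par <- st$par
      opt <- st$state
      if (it %% config$eval_every == 0 || it == config$n_iters) {
        model$theta_gp[] <- par[1:3]
        model$nn <- nn_unflatten(nn, par[-(1:3)])
        va <- validation_auprc(valid_tasks, y, config, function(ep) {
          post <- predictive_posterior(model, X[ep$support, , drop = FALSE],
                                       targ[ep$support],
                                       X[ep$query, , drop = FALSE])
          post$probability
        })
        history$valid_auprc[it] <- va
        if (!is.na(va) && va >= best$score) best <- list(par = par, score = va)
      }
    }
  })
  if (is.finite(best$score)) par <- best$par
  structure(list(method = "dkt",
                 nn = nn_unflatten(nn, par[-(1:3)]),
                 theta_gp = replace(config$theta_gp_init, 1:3, par[1:3]),
                 kernel = config$kernel, config = config,
                 history = history, valid_auprc = best$score),
            class = "dkmeta_model")
}

#' Adapt base-kernel hyperparameters to a support set
#'
#' Inner loop of ADKF: gradient descent with backtracking on the
#' support-set NLML over `theta_GP` only, starting from the
#' meta-initialization stored in `model`.  The accepted iterates never
#' increase the loss.  A single-class support set is allowed (regression
#' on constant targets) but flagged.
#'
#' @param model a [deep_kernel()] whose extractor stays fixed.
#' @param support_X,support_y support inputs and targets.
#' @param inner_steps,inner_lr,inner_tol optimizer controls (0 steps is
#'   a no-op).
#' @return Object of class `adapt_state`: the adapted `model`,
#'   `initial_loss`, `final_loss`, `inner_steps`, and `flagged`.
#' @export
adapt_gp <- function(model, support_X, support_y, inner_steps = 50,
                     inner_lr = 0.1, inner_tol = 1e-5) {
  if (!is.matrix(support_X)) support_X <- as.matrix(support_X)
  stopifnot(nrow(support_X) >= 2)
  targ <- labels_to_targets(support_y)
  flagged <- length(unique(targ)) < 2
  fg <- function(theta) {
    m <- model
    m$theta_gp[] <- theta
    g <- nlml_grad(m, support_X, targ)
    list(value = g$value, grad = g$g_gp)
  }
  if (inner_steps == 0) {
    v <- nlml(model, support_X, targ)
    res <- list(par = model$theta_gp, value = v, initial = v)
  } else {
    res <- gd_backtrack(unclass(model$theta_gp), fg, steps = inner_steps,
                        lr = inner_lr, tol = inner_tol)
  }
  model$theta_gp[] <- res$par
  structure(list(model = model, initial_loss = res$initial,
                 final_loss = res$value, inner_steps = inner_steps,
                 flagged = flagged),
            class = "adapt_state")
}

#' @export
print.adapt_state <- function(x, ...) {
  cat(sprintf("<adapt_state> loss %.4f -> %.4f (%d steps%s)\n",
              x$initial_loss, x$final_loss, x$inner_steps,
              if (isTRUE(x$flagged)) ", flagged" else ""))
  invisible(x)
}

# Outer-loop task term shared by ADKF and ADKF-prior: the negative log
# joint predictive posterior of the query given the support, computed
# through the chain rule nlml(S+Q) - nlml(S) so that one gradient pass
# serves both terms.  Returns the per-query-point loss and the flat
# extractor gradient at the adapted parameters.
outer_loss_grad <- function(model, X, targ, ep) {
  rows_sq <- c(ep$support, ep$query)
  g_all <- nlml_grad(model, X[rows_sq, , drop = FALSE], targ[rows_sq])
  g_s <- nlml_grad(model, X[ep$support, , drop = FALSE],
                   targ[ep$support])
  m <- length(ep$query)
  list(value = (g_all$value - g_s$value) / m,
       g_nn = (nn_grad_flatten(g_all$g_nn) -
                 nn_grad_flatten(g_s$g_nn)) / m)
}

#' Train a deep kernel by adaptive deep kernel fitting (ADKF)
#'
#' Bilevel scheme: for every sampled task the base-kernel
#' hyperparameters are adapted on the support-set NLML ([adapt_gp()]);
#' the extractor weights are meta-learned by minimizing the negative log
#' joint predictive posterior of the query set given the support set,
#' with first-order outer gradients (the inner solution treated as
#' constant).
#'
#' @inheritParams train_dkt
#' @return A `dkmeta_model` (method `"adkf"`); `$theta_gp` stores the
#'   inner-loop initialization.
#' @export
train_adkf <- function(X, y, train_tasks, valid_tasks = NULL,
                       config = meta_config()) {
  if (!is.matrix(X)) X <- as.matrix(X)
  targ <- labels_to_targets(y)
  seeds <- derive_seeds(config$seed, 2)
  nn <- mlp_init(ncol(X), config$hidden, config$latent_dim,
                 seed = seeds[1])
  par <- nn_flatten(nn)
  opt <- adam_init(length(par), lr = config$outer_lr)
  best <- list(par = par, score = -Inf)
  history <- data.frame(iter = seq_len(config$n_iters), loss = NA_real_,
                        valid_auprc = NA_real_)
  skipped <- 0L
  attempted <- 0L
  adapt_for <- function(net, ep) {
    model <- deep_kernel(net, config$theta_gp_init, config$kernel)
    adapt_gp(model, X[ep$support, , drop = FALSE], targ[ep$support],
             config$inner_steps, config$inner_lr, config$inner_tol)
  }
  with_seed(seeds[2], {
    for (it in seq_len(config$n_iters)) {
      net <- nn_unflatten(nn, par)
      batch <- sample(seq_along(train_tasks), config$task_batch,
                      replace = TRUE)
      loss <- 0
      grad <- numeric(length(par))
      used <- 0L
      for (b in batch) {
        attempted <- attempted + 1L
        ep <- draw_episode(train_tasks[[b]], y, config)
        term <- tryCatch({
          st <- adapt_for(net, ep)
          outer_loss_grad(st$model, X, targ, ep)
        }, error = function(e) NULL)
        if (is.null(term) || !is.finite(term$value)) {
          skipped <- skipped + 1L
          if (attempted >= 20 && skipped / attempted > 0.25) {
            stop("ADKF: more than 25% of inner loops diverged",
                 call. = FALSE)
          }
          next
        }
        loss <- loss + term$value
        grad <- grad + term$g_nn
        used <- used + 1L
      }
      if (used == 0) next
      history$loss[it] <- loss / used
      st <- adam_step(opt, par, grad / used)
      par <- st$par
      opt <- st$state
      if (it %% config$eval_every == 0 || it == config$n_iters) {
        net <- nn_unflatten(nn, par)
        va <- validation_auprc(valid_tasks, y, config, function(ep) {
          ad <- adapt_for(net, ep)
          post <- predictive_posterior(ad$model,
                                       X[ep$support, , drop = FALSE],
                                       targ[ep$support],
                                       X[ep$query, , drop = FALSE])
          post$probability
        })
        history$valid_auprc[it] <- va
        if (!is.na(va) && va >= best$score) best <- list(par = par, score = va)
      }
    }
  })
  if (is.finite(best$score)) par <- best$par
  structure(list(method = "adkf", nn = nn_unflatten(nn, par),
                 theta_gp = config$theta_gp_init, kernel = config$kernel,
                 config = config, history = history,
                 valid_auprc = best$score),
            class = "dkmeta_model")
}

# Normalize the ADKF-prior meta-parameter bundle.
as_prior_meta <- function(meta) {
  if (inherits(meta, "dkmeta_model")) {
    stopifnot(meta$method == "adkf_prior")
    list(nn = meta$nn, log_sigma2 = meta$log_sigma2,
         theta_gp = meta$theta_gp, kernel = meta$kernel)
  } else {
    stopifnot(is.list(meta),
              all(c("nn", "log_sigma2", "theta_gp") %in% names(meta)))
    meta$kernel <- meta$kernel %||% "rbf"
    meta
  }
}

#' MAP adaptation of the full deep kernel under a Gaussian weight prior
#'
#' Inner loop of ADKF-prior: jointly adapts the base-kernel
#' hyperparameters and the extractor weights on the support-set NLML,
#' with the extractor held near the prior mean by the penalty implied by
#' `theta_NN ~ N(phi, sigma^2 I)`.  Optimization uses the non-centred
#' parameterization `theta_NN = phi + sigma * u` (penalty
#' `||u||^2 / 2`), starting from `u = 0`, i.e. `theta_NN = phi`; as
#' `sigma^2 -> 0` the adaptation reduces exactly to [adapt_gp()] at the
#' prior mean.
#'
#' @param meta an ADKF-prior `dkmeta_model`, or a list with elements
#'   `nn` (prior mean extractor), `log_sigma2`, `theta_gp`, `kernel`.
#' @inheritParams adapt_gp
#' @return An `adapt_state` whose `model` carries the adapted extractor
#'   and hyperparameters; component `u` holds the whitened weight
#'   deviation.
#' @export
adapt_prior <- function(meta, support_X, support_y, inner_steps = 50,
                        inner_lr = 0.1, inner_tol = 1e-5) {
  meta <- as_prior_meta(meta)
  if (!is.matrix(support_X)) support_X <- as.matrix(support_X)
  stopifnot(nrow(support_X) >= 2)
  targ <- labels_to_targets(support_y)
  flagged <- length(unique(targ)) < 2
  phi <- nn_flatten(meta$nn)
  sigma <- exp(meta$log_sigma2 / 2)
  p <- length(phi)
  fg <- function(par) {
    theta_gp <- par[1:3]
    u <- par[-(1:3)]
    net <- nn_unflatten(meta$nn, phi + sigma * u)
    m <- deep_kernel(net, replace(meta$theta_gp, 1:3, theta_gp),
                     meta$kernel)
    g <- nlml_grad(m, support_X, targ)
    list(value = g$value + 0.5 * sum(u^2),
         grad = c(g$g_gp, sigma * nn_grad_flatten(g$g_nn) + u))
  }
  par0 <- c(unclass(meta$theta_gp), numeric(p))
  if (inner_steps == 0) {
    v <- fg(par0)$value
    res <- list(par = par0, value = v, initial = v)
  } else {
    res <- gd_backtrack(par0, fg, steps = inner_steps, lr = inner_lr,
                        tol = inner_tol)
  }
  u <- res$par[-(1:3)]
  model <- deep_kernel(nn_unflatten(meta$nn, phi + sigma * u),
                       replace(meta$theta_gp, 1:3, res$par[1:3]),
                       meta$kernel)
  structure(list(model = model, u = u, initial_loss = res$initial,
                 final_loss = res$value, inner_steps = inner_steps,
                 flagged = flagged),
            class = "adapt_state")
}

#' Train ADKF with a Gaussian prior over the extractor (ADKF-prior)
#'
#' Learns the meta parameters `Psi_meta = [phi, sigma^2]` of the
#' Gaussian weight prior `theta_NN ~ N(phi, sigma^2 I)`.  Each sampled
#' task is adapted by MAP ([adapt_prior()]); the outer loop minimizes
#' the mean negative log joint predictive posterior on the query sets.
#' Outer gradients are first-order: the adapted `(theta_GP, u)` are
#' treated as constants, giving `d loss / d phi` directly and
#' `d loss / d log sigma^2 = (sigma / 2) * u . d loss / d theta_NN`
#' through `theta_NN = phi + sigma * u`.
#'
#' @inheritParams train_dkt
#' @param init_nn optional extractor used as the initial prior mean
#'   (e.g. the extractor of a trained ADKF model); default is a fresh
#'   initialization.
#' @return A `dkmeta_model` (method `"adkf_prior"`) whose `$nn` is the
#'   prior mean `phi` and `$log_sigma2` the log prior variance.
#' @export
train_adkf_prior <- function(X, y, train_tasks, valid_tasks = NULL,
                             config = meta_config(), init_nn = NULL) {
  if (!is.matrix(X)) X <- as.matrix(X)
  targ <- labels_to_targets(y)
  seeds <- derive_seeds(config$seed, 2)
  nn <- init_nn %||% mlp_init(ncol(X), config$hidden, config$latent_dim,
                              seed = seeds[1])
  stopifnot(inherits(nn, "dkmeta_mlp"), nn$dims[1] == ncol(X))
  phi <- nn_flatten(nn)
  par <- c(phi, config$log_sigma2_init)
  np <- length(phi)
  opt <- adam_init(length(par), lr = config$outer_lr)
  best <- list(par = par, score = -Inf)
  history <- data.frame(iter = seq_len(config$n_iters), loss = NA_real_,
                        log_sigma2 = NA_real_, valid_auprc = NA_real_)
  skipped <- 0L
  attempted <- 0L
  meta_of <- function(par) {
    list(nn = nn_unflatten(nn, par[seq_len(np)]), log_sigma2 = par[np + 1],
         theta_gp = config$theta_gp_init, kernel = config$kernel)
  }
  with_seed(seeds[2], {
    for (it in seq_len(config$n_iters)) {
      meta <- meta_of(par)
      sigma <- exp(meta$log_sigma2 / 2)
      batch <- sample(seq_along(train_tasks), config$task_batch,
                      replace = TRUE)
      loss <- 0
      grad <- numeric(length(par))
      used <- 0L
      for (b in batch) {
        attempted <- attempted + 1L
        ep <- draw_episode(train_tasks[[b]], y, config)
        term <- tryCatch({
          st <- adapt_prior(meta, X[ep$support, , drop = FALSE],
                            targ[ep$support], config$inner_steps,
                            config$inner_lr, config$inner_tol)
          og <- outer_loss_grad(st$model, X, targ, ep)
          og$g_logs2 <- 0.5 * sigma * sum(st$u * og$g_nn)
          og
        }, error = function(e) NULL)
        if (is.null(term) || !is.finite(term$value)) {
          skipped <- skipped + 1L
          if (attempted >= 20 && skipped / attempted > 0.25) {
            stop("ADKF-prior: more than 25% of inner loops diverged",
                 call. = FALSE)
          }
          next
        }
        loss <- loss + term$value
        grad <- grad + c(term$g_nn, term$g_logs2)
        used <- used + 1L
      }
      if (used == 0) next
      history$loss[it] <- loss / used
      st <- adam_step(opt, par, grad / used)
      par <- st$par
      par[np + 1] <- min(max(par[np + 1], -12), 3)
      opt <- st$state
      history$log_sigma2[it] <- par[np + 1]
      if (it %% config$eval_every == 0 || it == config$n_iters) {
        meta <- meta_of(par)
        va <- validation_auprc(valid_tasks, y, config, function(ep) {
          ad <- adapt_prior(meta, X[ep$support, , drop = FALSE],
                            targ[ep$support], config$inner_steps,
                            config$inner_lr, config$inner_tol)
          post <- predictive_posterior(ad$model,
                                       X[ep$support, , drop = FALSE],
                                       targ[ep$support],
                                       X[ep$query, , drop = FALSE])
          post$probability
        })
        history$valid_auprc[it] <- va
        if (!is.na(va) && va >= best$score) best <- list(par = par, score = va)
      }
    }
  })
  if (is.finite(best$score)) par <- best$par
  structure(list(method = "adkf_prior",
                 nn = nn_unflatten(nn, par[seq_len(np)]),
                 log_sigma2 = par[np + 1],
                 theta_gp = config$theta_gp_init, kernel = config$kernel,
                 config = config, history = history,
                 valid_auprc = best$score),
            class = "dkmeta_model")
}

# Prototype coordinates of each class in embedding space.
class_prototypes <- function(Z, y01) {
  classes <- sort(unique(y01))
  proto <- t(vapply(classes, function(c) {
    colMeans(Z[y01 == c, , drop = FALSE])
  }, numeric(ncol(Z))))
  list(classes = classes, proto = proto)
}

#' Prototypical-network prediction
#'
#' Embeds support and query points, computes one prototype per class as
#' the mean support embedding of that class, and classifies each query
#' by a softmax over negative squared Euclidean distances to the
#' prototypes.
#'
#' @param fit a protonet `dkmeta_model` or a bare [mlp_init()] extractor.
#' @param support_X,support_y support inputs and 0/1 labels (both
#'   classes must be present).
#' @param query_X query inputs.
#' @return list with `probability` (class-1 probability per query) and
#'   `class` (hard 0/1 prediction).
#' @export
predict_protonet <- function(fit, support_X, support_y, query_X) {
  net <- if (inherits(fit, "dkmeta_model")) fit$nn else fit
  stopifnot(inherits(net, "dkmeta_mlp"))
  if (!is.matrix(support_X)) support_X <- as.matrix(support_X)
  if (!is.matrix(query_X)) query_X <- as.matrix(query_X)
  y01 <- as.integer(support_y)
  stopifnot(length(unique(y01)) == 2)
  Zs <- mlp_forward(net, support_X)$Z
  Zq <- mlp_forward(net, query_X)$Z
  cp <- class_prototypes(Zs, y01)
  d2 <- pairwise_sqdist(Zq, cp$proto)
  logits <- -d2
  logits <- logits - apply(logits, 1, max)
  p <- exp(logits) / rowSums(exp(logits))
  prob1 <- p[, which(cp$classes == 1)]
  list(probability = prob1,
       class = cp$classes[max.col(p, ties.method = "first")])
}

# Cross-entropy loss and extractor gradient for one protonet episode.
protonet_loss_grad <- function(net, Xs, ys01, Xq, yq01) {
  ns <- nrow(Xs)
  fw <- mlp_forward(net, rbind(Xs, Xq), cache = TRUE)
  Zs <- fw$Z[seq_len(ns), , drop = FALSE]
  Zq <- fw$Z[-seq_len(ns), , drop = FALSE]
  cp <- class_prototypes(Zs, ys01)
  m <- nrow(Zq)
  d2 <- pairwise_sqdist(Zq, cp$proto)
  logits <- -d2
  shift <- apply(logits, 1, max)
  p <- exp(logits - shift)
  p <- p / rowSums(p)
  ci <- match(yq01, cp$classes)
  loss <- -mean(log(pmax(p[cbind(seq_len(m), ci)], 1e-300)))
  dlogit <- p
  dlogit[cbind(seq_len(m), ci)] <- dlogit[cbind(seq_len(m), ci)] - 1
  dlogit <- dlogit / m
  # d logit_qc / d z_q = -2 (z_q - p_c);  d logit_qc / d p_c = 2 (z_q - p_c)
  dZq <- -2 * (rowSums(dlogit) * Zq - dlogit %*% cp$proto)
  dProto <- 2 * (t(dlogit) %*% Zq - colSums(dlogit) * cp$proto)
  dZs <- matrix(0, ns, ncol(Zs))
  for (i in seq_along(cp$classes)) {
    members <- which(ys01 == cp$classes[i])
    dZs[members, ] <- matrix(dProto[i, ] / length(members),
                             length(members), ncol(Zs), byrow = TRUE)
  }
  g <- mlp_backward(net, fw$cache, rbind(dZs, dZq))
  list(value = loss, g_nn = nn_grad_flatten(g))
}

#' Train a prototypical network
#'
#' Episodic training of the extractor by cross-entropy of the softmax
#' over negative squared distances to class prototypes.  Support draws
#' are stratified so every episode has both prototypes; episodes that
#' cannot be stratified (single-class task) are skipped and resampled.
#'
#' @inheritParams train_dkt
#' @return A `dkmeta_model` (method `"protonet"`; `theta_gp` is absent).
#' @export
train_protonet <- function(X, y, train_tasks, valid_tasks = NULL,
                           config = meta_config()) {
  if (!is.matrix(X)) X <- as.matrix(X)
  y01 <- as.integer(y)
  seeds <- derive_seeds(config$seed, 2)
  nn <- mlp_init(ncol(X), config$hidden, config$latent_dim,
                 seed = seeds[1])
  par <- nn_flatten(nn)
  opt <- adam_init(length(par), lr = config$outer_lr)
  best <- list(par = par, score = -Inf)
  cfg <- config
  cfg$stratified <- TRUE  # prototypes need both classes
  history <- data.frame(iter = seq_len(config$n_iters), loss = NA_real_,
                        valid_auprc = NA_real_)
  with_seed(seeds[2], {
    for (it in seq_len(config$n_iters)) {
      net <- nn_unflatten(nn, par)
      batch <- sample(seq_along(train_tasks), config$task_batch,
                      replace = TRUE)
      loss <- 0
      grad <- numeric(length(par))
      used <- 0L
      for (b in batch) {
        ep <- tryCatch(draw_episode(train_tasks[[b]], y01, cfg),
                       error = function(e) NULL)
        if (is.null(ep)) next
        term <- protonet_loss_grad(net, X[ep$support, , drop = FALSE],
                                   y01[ep$support],
                                   X[ep$query, , drop = FALSE],
                                   y01[ep$query])
        if (!is.finite(term$value)) stop("protonet training diverged")
        loss <- loss + term$value
        grad <- grad + term$g_nn
        used <- used + 1L
      }
      if (used == 0) next
      history$loss[it] <- loss / used
      st <- adam_step(opt, par, grad / used)
      par <- st$par
      opt <- st$state
      if (it %% config$eval_every == 0 || it == config$n_iters) {
        net <- nn_unflatten(nn, par)
        va <- validation_auprc(valid_tasks, y01, cfg, function(ep) {
          predict_protonet(net, X[ep$support, , drop = FALSE],
                           y01[ep$support],
                           X[ep$query, , drop = FALSE])$probability
        })
        history$valid_auprc[it] <- va
        if (!is.na(va) && va >= best$score) best <- list(par = par, score = va)
      }
    }
  })
  if (is.finite(best$score)) par <- best$par
  structure(list(method = "protonet", nn = nn_unflatten(nn, par),
                 theta_gp = NULL, kernel = NULL, config = config,
                 history = history, valid_auprc = best$score),
            class = "dkmeta_model")
}

#' Meta-test a trained model on a test task
#'
#' For each repeat, samples a fresh support/query episode from the test
#' task, adapts the model according to its method (DKT and DKL: none;
#' ADKF: [adapt_gp()]; ADKF-prior: [adapt_prior()]; protonet: prototype
#' computation), scores the query set and computes the AUPRC.
#'
#' @param fit a `dkmeta_model` from one of the trainers.
#' @param X,y dataset features and 0/1 labels.
#' @param test_task a `dkmeta_task` or row-index vector.
#' @param support_size,query_size episode sizes.
#' @param n_repeats number of support/query resamples.
#' @param seed integer seed.
#' @param stratified stratify the support draw by class?
#' @return data frame with one row per repeat: `repeat_id`,
#'   `support_size`, `method`, `auprc`.
#' @export
meta_test <- function(fit, X, y, test_task, support_size,
                      query_size = 128, n_repeats = 10, seed = 1,
                      stratified = TRUE) {
  stopifnot(inherits(fit, "dkmeta_model"))
  if (!is.matrix(X)) X <- as.matrix(X)
  y01 <- as.integer(y)
  targ <- labels_to_targets(y01)
  idx <- task_indices(test_task)
  if (support_size + query_size > length(idx)) {
    stop("test task too small for the requested episode", call. = FALSE)
  }
  cfg <- fit$config
  inner_steps <- cfg$inner_steps %||% 50
  inner_lr <- cfg$inner_lr %||% 0.1
  inner_tol <- cfg$inner_tol %||% 1e-5
  seeds <- derive_seeds(seed, n_repeats)
  scores <- vapply(seq_len(n_repeats), function(r) {
    ep <- sample_episode(idx, support_size, query_size,
                         stratified = stratified, seed = seeds[r],
                         labels = y01)
    Xs <- X[ep$support, , drop = FALSE]
    Xq <- X[ep$query, , drop = FALSE]
    prob <- switch(fit$method,
      dkt = ,
      dkl = {
        model <- as_deep_kernel(fit)
        predictive_posterior(model, Xs, targ[ep$support], Xq)$probability
      },
      adkf = {
        model <- as_deep_kernel(fit)
        ad <- adapt_gp(model, Xs, targ[ep$support], inner_steps,
                       inner_lr, inner_tol)
        predictive_posterior(ad$model, Xs, targ[ep$support],
                             Xq)$probability
      },
      adkf_prior = {
        ad <- adapt_prior(fit, Xs, targ[ep$support], inner_steps,
                          inner_lr, inner_tol)
        predictive_posterior(ad$model, Xs, targ[ep$support],
                             Xq)$probability
      },
      protonet = predict_protonet(fit, Xs, y01[ep$support],
                                  Xq)$probability,
      stop("unknown method: ", fit$method))
    auprc(y01[ep$query], prob)
  }, 1)
  data.frame(repeat_id = seq_len(n_repeats), support_size = support_size,
             method = fit$method, auprc = scores)
}
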