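# Synthetic meta-learning tasks.
#
# The generator emulates the statistical structure the meta-learners
# assume in the reaction-outcome setting: sparse binary
# fingerprint-like features plus a few continuous condition columns;
# tasks that share a common latent labelling function but carry
# task-specific perturbations; and a roughly 65/35 class imbalance.
# Labels are drawn by passing a per-task linear latent score through a
# logistic link whose intercept is solved so the expected positive
# fraction matches the target prevalence.

#' Specification of a synthetic task suite
#'
#' @param n_tasks number of tasks.
#' @param n_per_task rows per task.
#' @param dim number of binary fingerprint-like features.
#' @param task_shift_scale size of the per-task perturbation of the
#'   shared weight vector, relative to the shared weights (0 = all tasks
#'   share one labelling function).
#' @param noise_scale logistic temperature: 0 gives deterministic labels
#'   from the latent score, larger values give noisier labels.
#' @param positive_prevalence target positive fraction (default 0.65,
#'   the imbalance of the motivating enantioselectivity data).
#' @param feature_on_rate Bernoulli on-rate of the binary features.
#' @param n_condition number of continuous condition columns.
#' @param seed integer seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_tasks = 16, n_per_task = 320, dim = 64,
                           task_shift_scale = 0.5, noise_scale = 0.5,
                           positive_prevalence = 0.65,
                           feature_on_rate = 0.1, n_condition = 3,
                           seed = 1) {
  stopifnot(n_tasks >= 1, n_per_task >= 4, dim >= 1,
            task_shift_scale >= 0, noise_scale >= 0,
            positive_prevalence > 0, positive_prevalence < 1,
            feature_on_rate > 0, feature_on_rate < 1, n_condition >= 0)
  structure(as.list(environment()), class = "synthetic_spec")
}

# Solve the logistic intercept so that mean(plogis((z - c)/tau)) = p.
solve_intercept <- function(z, tau, p) {
  f <- function(c) mean(stats::plogis((z - c) / tau)) - p
  stats::uniroot(f, lower = min(z) - 20 * tau - 1,
                 upper = max(z) + 20 * tau + 1, tol = 1e-10)$root
}

#' Generate a synthetic meta-learning task suite
#'
#' @param spec a [synthetic_spec()].
#' @return Object of class `synthetic_suite`: list with the feature
#'   matrix `X` (`dim` binary columns then `n_condition` standard-normal
#'   columns), 0/1 labels `y`, `tasks` (list of row-index vectors, one
#'   per task), the shared weights `w`, the per-task weights `w_tasks`
#'   (matrix, one column per task), per-task intercepts `intercepts`,
#'   and the `spec`.
#' @export
generate_tasks <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  d_tot <- spec$dim + spec$n_condition
  n <- spec$n_tasks * spec$n_per_task
  with_seed(spec$seed, {
    Xb <- matrix(stats::rbinom(n * spec$dim, 1, spec$feature_on_rate),
                 n, spec$dim)
    Xc <- if (spec$n_condition > 0) {
      matrix(stats::rnorm(n * spec$n_condition), n, spec$n_condition)
    } else NULL
    X <- cbind(Xb, Xc)
    w <- stats::rnorm(d_tot) / sqrt(d_tot)
    tasks <- split(seq_len(n), rep(seq_len(spec$n_tasks),
                                   each = spec$n_per_task))
    w_tasks <- matrix(0, d_tot, spec$n_tasks)
    intercepts <- numeric(spec$n_tasks)
    y <- integer(n)
    for (t in seq_len(spec$n_tasks)) {
      w_t <- w + spec$task_shift_scale *
        stats::rnorm(d_tot) / sqrt(d_tot)
      w_tasks[, t] <- w_t
      rows <- tasks[[t]]
      z <- drop(X[rows, , drop = FALSE] %*% w_t)
      z <- (z - mean(z)) / max(stats::sd(z), 1e-12)
      if (spec$noise_scale == 0) {
        thr <- stats::quantile(z, 1 - spec$positive_prevalence,
                               names = FALSE)
        y[rows] <- as.integer(z > thr)
      } else {
        cc <- solve_intercept(z, spec$noise_scale,
                              spec$positive_prevalence)
        intercepts[t] <- cc
        p <- stats::plogis((z - cc) / spec$noise_scale)
        y[rows] <- stats::rbinom(length(rows), 1, p)
      }
      # degenerate single-class draws are re-balanced by flipping the
      # most extreme example, so every task is usable for adaptation
      if (length(unique(y[rows])) < 2) {
        flip <- if (all(y[rows] == 1)) which.min(z) else which.max(z)
        y[rows[flip]] <- 1L - y[rows[flip]]
      }
    }
    structure(list(X = X, y = y, tasks = unname(tasks), w = w,
                   w_tasks = w_tasks, intercepts = intercepts,
                   spec = spec),
              class = "synthetic_suite")
  })
}

#' @export
print.synthetic_suite <- function(x, ...) {
  cat(sprintf(
    "<synthetic_suite> %d tasks x %d rows, %d features; prevalence %.3f\n",
    x$spec$n_tasks, x$spec$n_per_task, ncol(x$X), mean(x$y)))
  invisible(x)
}

#' Assign suite tasks to meta-train / validation / test roles
#'
#' Convenience splitter for a [generate_tasks()] suite: the first
#' `n_train` tasks become training tasks, then `n_valid` validation
#' tasks, then `n_test` test tasks.
#'
#' @param suite a `synthetic_suite`.
#' @param n_train,n_valid,n_test task counts (must sum to at most the
#'   number of tasks in the suite).
#' @return list of `dkmeta_task` lists: `train`, `valid`, `test`.
#' @export
suite_split <- function(suite, n_train, n_valid = 1, n_test = 1) {
  stopifnot(inherits(suite, "synthetic_suite"),
            n_train + n_valid + n_test <= length(suite$tasks))
  mk <- function(offset, k, role) {
    lapply(seq_len(k), function(i) {
      new_task(sprintf("%s_%02d", role, i), suite$tasks[[offset + i]],
               role)
    })
  }
  list(train = mk(0L, n_train, "train"),
       valid = mk(n_train, n_valid, "valid"),
       test = mk(n_train + n_valid, n_test, "test"))
}

# Small built-in vocabulary of valid SMILES for toy reaction records:
# prochiral olefins, phosphine/phosphite-like ligands, common solvents.
TOY_OLEFINS <- c(
  "C=Cc1ccccc1", "CC(=Cc1ccccc1)C(=O)O", "C=C(C)c1ccccc1",
  "CC(=O)NC(=Cc1ccccc1)C(=O)O", "C=CCO", "CC=CC(=O)OC",
  "C=C(c1ccccc1)c1ccccc1", "CC(=CC(=O)OC)c1ccccc1", "C=CC(=O)OCC",
  "CC(O)C=Cc1ccccc1", "C=C(C)C(=O)OC", "COC(=O)C=Cc1ccccc1")
TOY_LIGANDS <- c(
  "c1ccc(P(c2ccccc2)c2ccccc2)cc1", "CP(C)c1ccccc1",
  "c1ccc(P(c2ccccc2)CCP(c2ccccc2)c2ccccc2)cc1",
  "CC(C)P(C(C)C)c1ccccc1", "COP(OC)Oc1ccccc1",
  "CC1=NC(C(C)C)CO1", "c1ccc(-c2ccccc2P(c2ccccc2)c2ccccc2)cc1",
  "CCP(CC)CC")
TOY_SOLVENTS <- c("ClCCl", "CO", "C1CCOC1", "Cc1ccccc1", "CC(C)O",
                  "CCO", "ClC(Cl)Cl")

#' Generate toy reaction records
#'
#' Assembles syntactically valid reaction records from a built-in
#' vocabulary of small molecules, with random metals, additives,
#' conditions, percent-ee values (skewed toward high selectivity) and
#' publication years.  Every record passes featurization validation.
#'
#' @param n number of records.
#' @param seed integer seed.
#' @return data frame in the [read_reactions()] schema.
#' @export
generate_toy_reactions <- function(n, seed = 1) {
  stopifnot(n >= 1)
  with_seed(seed, {
    data.frame(
      reaction_id = sprintf("rxn_%05d", seq_len(n)),
      olefin_smiles = sample(TOY_OLEFINS, n, replace = TRUE),
      ligand_smiles = sample(TOY_LIGANDS, n, replace = TRUE),
      solvent_smiles = sample(TOY_SOLVENTS, n, replace = TRUE),
      metal = sample(DKMETA_METALS, n, replace = TRUE,
                     prob = c(0.45, 0.45, 0.1)),
      additive = sample(c(TRUE, FALSE), n, replace = TRUE),
      temperature_c = round(stats::runif(n, 15, 80), 1),
      pressure_bar = round(stats::runif(n, 1, 100), 1),
      loading_molpct = round(stats::runif(n, 0.1, 5), 2),
      ee = round(100 * stats::rbeta(n, 4, 1.5), 1),
      year = sample(2000:2024, n, replace = TRUE),
      stringsAsFactors = FALSE)
  })
}
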