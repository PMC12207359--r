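# Internal numerical utilities shared by the trainers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed
#'
#' Thin wrapper over [withr::with_seed()] so that every stochastic
#' operation in the package is reproducible bit-for-bit from an integer
#' seed without clobbering the caller's RNG state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Adam optimizer state over a flat numeric vector.
adam_init <- function(n_par, lr = 1e-2, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  list(m = numeric(n_par), v = numeric(n_par), t = 0L,
       lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(state, par, grad) {
  state$t <- state$t + 1L
  state$m <- state$beta1 * state$m + (1 - state$beta1) * grad
  state$v <- state$beta2 * state$v + (1 - state$beta2) * grad^2
  mhat <- state$m / (1 - state$beta1^state$t)
  vhat <- state$v / (1 - state$beta2^state$t)
  par <- par - state$lr * mhat / (sqrt(vhat) + state$eps)
  list(par = par, state = state)
}

# Gradient descent with backtracking line search on a flat parameter
# vector.  `fg` returns list(value, grad).  The accepted iterate never
# increases the objective; stops early when the improvement falls below
# `tol`.  Used for the per-task (inner loop) adaptations.
gd_backtrack <- function(par, fg, steps = 50, lr = 0.1, tol = 1e-5,
                         max_halvings = 10) {
  ev <- fg(par)
  if (!is.finite(ev$value)) {
    stop("non-finite objective at the adaptation starting point")
  }
  f0 <- ev$value
  step <- lr
  for (it in seq_len(steps)) {
    g <- ev$grad
    gnorm2 <- sum(g^2)
    if (!is.finite(gnorm2) || gnorm2 == 0) break
    accepted <- FALSE
    for (h in seq_len(max_halvings)) {
      cand <- par - step * g
      ev_cand <- tryCatch(fg(cand), error = function(e) NULL)
      if (!is.null(ev_cand) && is.finite(ev_cand$value) &&
          ev_cand$value <= ev$value) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    improved <- ev$value - ev_cand$value
    par <- cand
    ev <- ev_cand
    step <- min(lr, step * 2)
    if (improved < tol) break
  }
  list(par = par, value = ev$value, initial = f0, grad = ev$grad)
}

# Flatten a list of numeric arrays into one vector and back.
flatten_list <- function(x) {
  if (is.null(x)) return(numeric(0))
  unlist(lapply(x, as.numeric), use.names = FALSE)
}

unflatten_like <- function(template, vec) {
  if (is.null(template)) return(NULL)
  out <- template
  pos <- 0L
  for (i in seq_along(template)) {
    n <- length(template[[i]])
    out[[i]][] <- vec[pos + seq_len(n)]
    pos <- pos + n
  }
  stopifnot(pos == length(vec))
  out
}

# Derive a stream of distinct child seeds from one integer seed,
# keeping them inside the 32-bit integer range.
derive_seeds <- function(seed, n) {
  ((as.double(seed) * 48271 + 7919 * seq_len(n)) %% 2147483629) + 1
}

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(x)
}
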