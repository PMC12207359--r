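#' Feed-forward feature extractor
#'
#' Constructs the neural feature extractor of a deep kernel: a fully
#' connected network with `tanh` hidden activations and a linear output
#' layer mapping a reaction representation to a low-dimensional latent
#' embedding that the Gaussian-process base kernel operates on.
#'
#' @param input_dim number of input features.
#' @param hidden integer vector of hidden-layer widths (may be empty for
#'   a single linear layer).
#' @param latent_dim embedding dimension.
#' @param seed integer seed for the weight initialization.
#' @return An object of class `dkmeta_mlp` holding weight matrices `W`,
#'   bias vectors `b` and the layer dimensions.
#' @examples
#' net <- mlp_init(10, hidden = 8, latent_dim = 4, seed = 1)
#' Z <- mlp_forward(net, matrix(rnorm(50), 5, 10))$Z
#' dim(Z)
#' @export
mlp_init <- function(input_dim, hidden = c(256, 128), latent_dim = 64,
                     seed = 1) {
  stopifnot(input_dim >= 1, latent_dim >= 1, all(hidden >= 1))
  dims <- c(input_dim, hidden, latent_dim)
  with_seed(seed, {
    W <- vector("list", length(dims) - 1L)
    b <- vector("list", length(dims) - 1L)
    for (l in seq_along(W)) {
      fan_in <- dims[l]
      fan_out <- dims[l + 1L]
      sd <- sqrt(2 / (fan_in + fan_out))
      W[[l]] <- matrix(stats::rnorm(fan_in * fan_out, sd = sd),
                       fan_in, fan_out)
      b[[l]] <- numeric(fan_out)
    }
    structure(list(W = W, b = b, dims = dims), class = "dkmeta_mlp")
  })
}

#' Forward pass of the feature extractor
#'
#' @param net a `dkmeta_mlp` object.
#' @param X numeric matrix (rows are examples) with `net$dims[1]` columns.
#' @param cache keep hidden activations for a subsequent backward pass?
#' @return list with the embedding matrix `Z` (and `cache` when requested).
#' @export
mlp_forward <- function(net, X, cache = FALSE) {
  stopifnot(inherits(net, "dkmeta_mlp"))
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  stopifnot(ncol(X) == net$dims[1])
  stop_if_not_finite(X, "extractor input")
  L <- length(net$W)
  H <- vector("list", L)      # activations entering layer l (H[[1]] = X)
  A <- X
  for (l in seq_len(L)) {
    H[[l]] <- A
    A <- sweep(A %*% net$W[[l]], 2, net$b[[l]], "+")
    if (l < L) A <- tanh(A)   # linear output layer
  }
  out <- list(Z = A)
  if (cache) out$cache <- H
  out
}

#' Backward pass of the feature extractor
#'
#' Backpropagates a gradient with respect to the embedding through the
#' network, returning gradients with the same shapes as the weights.
#'
#' @param net a `dkmeta_mlp` object.
#' @param cache activations from `mlp_forward(..., cache = TRUE)`.
#' @param dZ gradient of the loss with respect to the embedding matrix.
#' @return list with components `W` and `b` (gradient lists).
#' @export
mlp_backward <- function(net, cache, dZ) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- dZ
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(cache[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      # activation entering layer l is tanh output of layer l-1
      Hl <- cache[[l]]
      delta <- (delta %*% t(net$W[[l]])) * (1 - Hl^2)
    }
  }
  list(W = gW, b = gb)
}

# Flat-vector views of the weights, used by the optimizers and by the
# Gaussian prior over extractor parameters.
nn_flatten <- function(net) {
  if (is.null(net)) return(numeric(0))
  c(flatten_list(net$W), flatten_list(net$b))
}

nn_unflatten <- function(net, vec) {
  if (is.null(net)) return(NULL)
  nW <- sum(vapply(net$W, length, 1L))
  net$W <- unflatten_like(net$W, vec[seq_len(nW)])
  net$b <- unflatten_like(net$b, vec[-seq_len(nW)])
  net
}

nn_grad_flatten <- function(g) c(flatten_list(g$W), flatten_list(g$b))

#' @export
print.dkmeta_mlp <- function(x, ...) {
  cat("<dkmeta_mlp> layers:", paste(x$dims, collapse = " -> "),
      sprintf("(%d parameters)\n", length(nn_flatten(x))))
  invisible(x)
}
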