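#' @title Shared-encoder multitask regression network
#'
#' @description
#' The decoder model is a feed-forward network with hard parameter
#' sharing: an encoder of `N` fully connected blocks whose widths halve
#' from `2^K` down to the code width `2^(K-N+1)`, followed by `J`
#' per-DoF decoder branches (one hidden block of width `2^S` plus a
#' single linear output neuron). Every block is affine -> leaky ReLU ->
#' parameter-free layer normalization. The code `h` produced by the
#' encoder is shared by all branches, so each DoF estimate depends on the
#' input only through `h`.
#'
#' @name mrl_network
NULL

#' Define a network topology
#'
#' @param n_inputs number of input channels `I`.
#' @param n_dofs number of output DoFs `J`.
#' @param first_layer_log2 `K`: the first encoder block has `2^K` outputs.
#' @param encoder_depth `N`: number of encoder blocks (requires `K >= N`).
#' @param decoder_hidden_log2 `S`: decoder hidden blocks have `2^S` outputs.
#' @param activation_slope negative slope of the leaky ReLU.
#' @param layernorm_eps variance-stabilizing epsilon of layer norm.
#' @return Object of class `mrl_topology` with derived fields
#'   `encoder_widths` and `code_width`.
#' @examples
#' topo <- mrl_topology()
#' topo$encoder_widths # 128 64 32 16 8
#' topo$code_width     # 8
#' @export
mrl_topology <- function(n_inputs = 8, n_dofs = 2, first_layer_log2 = 7,
                         encoder_depth = 5, decoder_hidden_log2 = 5,
                         activation_slope = 0.01, layernorm_eps = 1e-5) {
  K <- as.integer(first_layer_log2); N <- as.integer(encoder_depth)
  if (N < 1 || K < N) stop("invalid topology: require K >= N >= 1")
  if (n_dofs < 1 || n_inputs < 1) stop("invalid topology: I and J must be >= 1")
  widths <- 2^(K:(K - N + 1))
  structure(
    list(n_inputs = as.integer(n_inputs), n_dofs = as.integer(n_dofs),
         first_layer_log2 = K, encoder_depth = N,
         decoder_hidden_log2 = as.integer(decoder_hidden_log2),
         encoder_widths = widths, code_width = widths[N],
         activation_slope = activation_slope, layernorm_eps = layernorm_eps),
    class = "mrl_topology"
  )
}

glorot_uniform <- function(n_out, n_in) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
}

#' Instantiate network parameters
#'
#' Weights are drawn from the Glorot (Xavier) uniform distribution per
#' layer; all biases start at zero. Deterministic for a given seed.
#'
#' @param topology an [mrl_topology()].
#' @param seed integer seed.
#' @return Object of class `mrl_parameters`: lists `encoder` (per block
#'   `W`, `b`) and `decoder` (per branch `hidden` and `out` layers), plus
#'   the topology.
#' @export
mrl_build <- function(topology, seed = 1L) {
  if (!inherits(topology, "mrl_topology")) stop("topology must be an mrl_topology")
  set.seed(seed)
  ins <- c(topology$n_inputs, topology$encoder_widths)
  encoder <- lapply(seq_len(topology$encoder_depth), function(l) {
    list(W = glorot_uniform(topology$encoder_widths[l], ins[l]),
         b = numeric(topology$encoder_widths[l]))
  })
  hw <- 2^topology$decoder_hidden_log2
  decoder <- lapply(seq_len(topology$n_dofs), function(j) {
    list(hidden = list(W = glorot_uniform(hw, topology$code_width),
                       b = numeric(hw)),
         out = list(W = glorot_uniform(1, hw), b = 0))
  })
  structure(list(topology = topology, encoder = encoder, decoder = decoder),
            class = "mrl_parameters")
}

#' @export
print.mrl_parameters <- function(x, ...) {
  tp <- x$topology
  cat("<mrl_parameters>", tp$n_inputs, "inputs ->",
      paste(tp$encoder_widths, collapse = "-"), "encoder ->",
      tp$n_dofs, "branches (hidden", 2^tp$decoder_hidden_log2, ") |",
      n_parameters(x), "parameters\n")
  invisible(x)
}

#' Total number of free parameters (weights and biases)
#' @param params an `mrl_parameters` object.
#' @return Integer count.
#' @export
n_parameters <- function(params) {
  cnt <- function(l) length(l$W) + length(l$b)
  sum(vapply(params$encoder, cnt, numeric(1))) +
    sum(vapply(params$decoder, function(d) cnt(d$hidden) + cnt(d$out), numeric(1)))
}

#' Parameter-free layer normalization
#'
#' Centers and rescales a vector (or each column of a matrix) to zero mean
#' and epsilon-stabilized unit variance across its elements, using the
#' population (biased) variance. No learnable gain or shift.
#'
#' @param v numeric vector, or matrix whose columns are normalized
#'   independently.
#' @param eps stabilizing constant added to the variance.
#' @return Normalized vector or matrix of the same shape.
#' @export
layer_norm <- function(v, eps = 1e-5) {
  if (is.matrix(v)) {
    n <- nrow(v)
    mu <- colMeans(v)
    c_ <- v - rep(mu, each = n)
    r <- 1 / sqrt(colMeans(c_^2) + eps)
    c_ * rep(r, each = n)
  } else {
    c_ <- v - mean(v)
    c_ / sqrt(mean(c_^2) + eps)
  }
}

# forward through one full block (affine -> leaky ReLU -> layer norm)
block_forward <- function(layer, A, slope, eps) {
  Z <- layer$W %*% A + layer$b
  S <- ifelse(Z > 0, 1, slope)
  layer_norm(Z * S, eps)
}

#' Evaluate the network
#'
#' @param params an `mrl_parameters` object.
#' @param e envelope input: length-I vector or I x B matrix (one column
#'   per sample), expected in `[0, 1]^I`.
#' @return List with `code` (shared representation `h`) and `output`
#'   (DoF-wise kinematic estimates; a J-vector for vector input, J x B
#'   matrix otherwise).
#' @export
mrl_forward <- function(params, e) {
  tp <- params$topology
  vec_in <- !is.matrix(e)
  A <- if (vec_in) matrix(e, ncol = 1) else e
  if (nrow(A) != tp$n_inputs) {
    stop("shape error: expected ", tp$n_inputs, " input channels, got ", nrow(A))
  }
  for (layer in params$encoder) {
    A <- block_forward(layer, A, tp$activation_slope, tp$layernorm_eps)
  }
  h <- A
  out <- matrix(0, tp$n_dofs, ncol(A))
  for (j in seq_len(tp$n_dofs)) {
    Aj <- block_forward(params$decoder[[j]]$hidden, h,
                        tp$activation_slope, tp$layernorm_eps)
    out[j, ] <- params$decoder[[j]]$out$W %*% Aj + params$decoder[[j]]$out$b
  }
  if (vec_in) list(code = as.numeric(h), output = as.numeric(out))
  else list(code = h, output = out)
}

#' Analytic Jacobian of the network output
#'
#' Exact forward-mode derivative of every output DoF with respect to every
#' input channel, propagated through the affine, leaky-ReLU (subgradient
#' `slope` at 0) and layer-norm stages.
#'
#' @param params an `mrl_parameters` object.
#' @param e length-I input vector.
#' @return J x I matrix of partial derivatives.
#' @export
mrl_jacobian <- function(params, e) {
  tp <- params$topology
  if (length(e) != tp$n_inputs) stop("shape error: input length mismatch")
  fw <- mrl_engine(params, matrix(e, ncol = 1), Y = NULL, alpha_c = 1,
                   need_grad = FALSE, need_tangent = TRUE)
  matrix(fw$jrows, tp$n_dofs, tp$n_inputs)
}
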