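# Internal differentiation engine for the multitask network.
#
# Computes, for a minibatch E (I x B) with targets Y (J x B):
#   * the forward pass and the inference loss L_i (mean per-sample L1 error),
#   * the full input-output Jacobian of every sample via forward-mode
#     tangent propagation, giving the contractive loss
#     L_c = mean over (sample, input, output) of squared partials,
#   * analytic gradients of L = L_i + alpha_c * L_c with respect to every
#     weight and bias, via a hand-derived reverse pass over the augmented
#     (value + tangent) computation.
#
# Tangent layout: an n x (B*I) matrix; column (i-1)*B + t holds the tangent
# of the layer activation at sample t with respect to input channel i.

# elementwise leaky-ReLU slope mask
slope_mask <- function(Z, slope) (Z > 0) * (1 - slope) + slope

# sum the I column-blocks of an n x (B*I) matrix into an n x B matrix
fold_tangent_blocks <- function(M, B, I) {
  out <- M[, seq_len(B), drop = FALSE]
  if (I > 1) for (i in 2:I) {
    out <- out + M[, ((i - 1) * B + 1):(i * B), drop = FALSE]
  }
  out
}

# forward through affine -> leaky ReLU -> layer norm, with optional tangents
aug_block_forward <- function(layer, A, D, slope, eps, cols_t) {
  n <- nrow(layer$W) # output width
  Z <- layer$W %*% A + layer$b
  S <- slope_mask(Z, slope)
  U <- Z * S
  B <- ncol(A)
  mu <- colMeans(U)
  C <- U - rep(mu, each = n)
  r <- 1 / sqrt(colMeans(C * C) + eps)
  Aout <- C * rep(r, each = n)
  cache <- list(layer = layer, Aprev = A, Dprev = D, S = S, C = C, r = r, n = n)
  if (!is.null(D)) {
    DZ <- layer$W %*% D
    DU <- DZ * S[, cols_t, drop = FALSE]
    DC <- DU - rep(colMeans(DU), each = n)
    Crep <- C[, cols_t, drop = FALSE]
    svec <- colSums(Crep * DC)
    rt <- r[cols_t]
    Dout <- DC * rep(rt, each = n) - Crep * rep(rt^3 * svec / n, each = n)
    cache$DC <- DC
    cache$svec <- svec
  } else {
    Dout <- NULL
  }
  list(A = Aout, D = Dout, cache = cache)
}

# reverse pass through one block; Abar n x B, Dbar n x (B*I) or NULL
aug_block_backward <- function(cache, Abar, Dbar, cols_t) {
  n <- cache$n
  B <- ncol(cache$C)
  C <- cache$C; r <- cache$r; S <- cache$S
  if (!is.null(Dbar)) {
    DC <- cache$DC; svec <- cache$svec
    I_t <- length(cols_t) / B
    Crep <- C[, cols_t, drop = FALSE]
    rt <- r[cols_t]
    q <- colSums(Crep * Dbar)                      # (dabar_i . c) per column
    sbar <- -(rt^3 / n) * q
    DCbar <- Dbar * rep(rt, each = n) + Crep * rep(sbar, each = n)
    term <- Dbar * rep(-(rt^3) * svec / n, each = n) + DC * rep(sbar, each = n)
    Cbar <- fold_tangent_blocks(term, B, I_t)
    rbar_cols <- colSums(Dbar * DC) - (3 * rt^2 * svec / n) * q
    rbar <- rowSums(matrix(rbar_cols, B, I_t))
    DUbar <- DCbar - rep(colMeans(DCbar), each = n)
    DZbar <- DUbar * S[, cols_t, drop = FALSE]
  } else {
    Cbar <- matrix(0, n, B)
    rbar <- numeric(B)
    DZbar <- NULL
  }
  Cbar <- Cbar + Abar * rep(r, each = n)
  rbar <- rbar + colSums(Abar * C)
  vbar <- -0.5 * r^3 * rbar
  Cbar <- Cbar + C * rep(2 * vbar / n, each = n)
  Ubar <- Cbar - rep(colMeans(Cbar), each = n)
  Zbar <- Ubar * S
  W <- cache$layer$W
  Wbar <- tcrossprod(Zbar, cache$Aprev)
  if (!is.null(DZbar)) Wbar <- Wbar + tcrossprod(DZbar, cache$Dprev)
  list(Wbar = Wbar, bbar = rowSums(Zbar),
       Abar = crossprod(W, Zbar),
       Dbar = if (!is.null(DZbar)) crossprod(W, DZbar) else NULL)
}

# Engine dispatcher: the compiled backend is the default; the pure-R
# reference implementation below remains available for cross-checking.
mrl_engine <- function(params, E, Y, alpha_c, need_grad = TRUE,
                       need_tangent = TRUE, backend = c("cpp", "r")) {
  backend <- match.arg(backend)
  if (backend == "cpp") {
    tp <- params$topology
    res <- .mrl_engine_cpp(params$encoder, params$decoder, E, Y, alpha_c,
                           tp$activation_slope, tp$layernorm_eps,
                           need_grad, need_tangent)
    if (!is.null(res$grads)) {
      for (j in seq_along(res$grads$decoder)) {
        res$grads$decoder[[j]]$hidden$b <- as.numeric(res$grads$decoder[[j]]$hidden$b)
      }
      for (l in seq_along(res$grads$encoder)) {
        res$grads$encoder[[l]]$b <- as.numeric(res$grads$encoder[[l]]$b)
      }
    }
    return(res)
  }
  mrl_engine_ref(params, E, Y, alpha_c, need_grad, need_tangent)
}

# Full engine, reference R implementation. Y may be NULL (then L_i and its
# gradient contributions are skipped).
mrl_engine_ref <- function(params, E, Y, alpha_c, need_grad = TRUE,
                           need_tangent = TRUE) {
  tp <- params$topology
  I <- tp$n_inputs; J <- tp$n_dofs
  B <- ncol(E)
  slope <- tp$activation_slope; eps <- tp$layernorm_eps
  cols_t <- if (need_tangent) rep(seq_len(B), times = I) else NULL

  # input tangents: d e / d e_i = unit vectors, constant
  D <- NULL
  if (need_tangent) {
    D <- matrix(0, I, B * I)
    for (i in seq_len(I)) D[i, ((i - 1) * B + 1):(i * B)] <- 1
  }

  A <- E
  enc_caches <- vector("list", length(params$encoder))
  for (l in seq_along(params$encoder)) {
    st <- aug_block_forward(params$encoder[[l]], A, D, slope, eps, cols_t)
    A <- st$A; D <- st$D
    enc_caches[[l]] <- st$cache
  }
  h <- A; Dh <- D

  Yhat <- matrix(0, J, B)
  jrows <- if (need_tangent) matrix(0, J, B * I) else NULL
  br_caches <- vector("list", J)
  for (j in seq_len(J)) {
    st <- aug_block_forward(params$decoder[[j]]$hidden, h, Dh, slope, eps, cols_t)
    out <- params$decoder[[j]]$out
    Yhat[j, ] <- out$W %*% st$A + out$b
    if (need_tangent) jrows[j, ] <- out$W %*% st$D
    br_caches[[j]] <- st
  }

  L_i <- if (!is.null(Y)) sum(abs(Y - Yhat)) / B else NA_real_
  L_c <- if (need_tangent) sum(jrows * jrows) / (B * I * J) else NA_real_
  res <- list(L_i = L_i, L_c = L_c,
              L = if (!is.null(Y) && need_tangent) L_i + alpha_c * L_c
                  else if (!is.null(Y)) L_i else alpha_c * L_c,
              Yhat = Yhat, jrows = jrows, code = h)
  if (!need_grad) return(res)

  Ybar <- if (!is.null(Y)) sign(Yhat - Y) / B else matrix(0, J, B)
  Jbar <- if (need_tangent) (2 * alpha_c / (B * I * J)) * jrows else NULL

  grads <- list(encoder = vector("list", length(params$encoder)),
                decoder = vector("list", J))
  hbar <- matrix(0, nrow(h), B)
  Dhbar <- if (need_tangent) matrix(0, nrow(h), B * I) else NULL
  for (j in seq_len(J)) {
    st <- br_caches[[j]]
    out <- params$decoder[[j]]$out
    ybj <- Ybar[j, , drop = FALSE]                 # 1 x B
    out_Wbar <- tcrossprod(ybj, st$A)              # 1 x n
    Abar <- crossprod(out$W, ybj)                  # n x B
    Dbar <- NULL
    if (need_tangent) {
      jbj <- Jbar[j, , drop = FALSE]
      out_Wbar <- out_Wbar + tcrossprod(jbj, st$D)
      Dbar <- crossprod(out$W, jbj)
    }
    bk <- aug_block_backward(st$cache, Abar, Dbar, cols_t)
    grads$decoder[[j]] <- list(
      hidden = list(W = bk$Wbar, b = bk$bbar),
      out = list(W = out_Wbar, b = sum(ybj))
    )
    hbar <- hbar + bk$Abar
    if (need_tangent) Dhbar <- Dhbar + bk$Dbar
  }
  Abar <- hbar; Dbar <- Dhbar
  for (l in rev(seq_along(params$encoder))) {
    bk <- aug_block_backward(enc_caches[[l]], Abar, Dbar, cols_t)
    grads$encoder[[l]] <- list(W = bk$Wbar, b = bk$bbar)
    Abar <- bk$Abar; Dbar <- bk$Dbar
  }
  res$grads <- grads
  res
}
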