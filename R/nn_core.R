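# Layer primitives with explicit forward and backward passes. Every backward
# takes the cached forward input, so the same code serves gradient descent
# (guided = FALSE) and guided backpropagation (guided = TRUE).

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Guided backward rule for a rectified-linear unit
#'
#' During guided backpropagation the backward pass of every ReLU passes an
#' incoming gradient only where the gradient itself is positive *and* the
#' forward input to the unit was positive (the standard ReLU mask is kept and
#' the negative-gradient mask is added). Elementwise and vectorised.
#'
#' @param upstream_grad gradient arriving from the layer above.
#' @param forward_input the input the unit saw in the forward pass.
#' @return masked gradient, same shape as the inputs.
#' @examples
#' guided_relu_backward(c(-2, 2, 2), c(3, 3, -1))  # 0, 2, 0
#' @export
guided_relu_backward <- function(upstream_grad, forward_input) {
  upstream_grad * (upstream_grad > 0) * (forward_input > 0)
}

# backward through ReLU given the pre-activation; guided adds the grad mask
relu_backward <- function(grad, pre, guided = FALSE) {
  if (guided) guided_relu_backward(grad, pre) else grad * (pre > 0)
}

# ---------------------------------------------------------------------------
# 3D convolution (kernel k, stride 1, zero padding (k-1)/2) via im2col + BLAS.
# The big im2col patch matrices and the backward gemm intermediate are written
# into process-wide workspaces keyed by shape, so repeated passes reuse the
# same memory. A workspace returned from conv3d_fwd stays valid until the next
# forward pass over an input of the same shape; the training and attribution
# loops run backward immediately after forward, per subject, which honours
# that contract.

.conv_ws <- new.env(parent = emptyenv())

get_ws <- function(key, nr, nc) {
  ws <- .conv_ws[[key]]
  if (is.null(ws) || nrow(ws) != nr || ncol(ws) != nc) {
    ws <- matrix(0, nr, nc)
    .conv_ws[[key]] <- ws
  }
  ws
}

# x: array (d1,d2,d3,Cin); W: (k^3*Cin) x Cout; b: length Cout
# Returns the output array plus the filled patch workspace (for the backward).
conv3d_fwd <- function(x, W, b, k = 3L) {
  d <- as.integer(dim(x))
  nvox <- prod(d[1:3])
  P <- get_ws(paste0("P_", paste(d, collapse = "_")), nvox, k^3 * d[4])
  im2col_fill(P, x, d, k)
  Z <- P %*% W
  Z <- Z + rep(b, each = nrow(Z))
  list(y = array(Z, c(d[1:3], length(b))), P = P, dims_in = d)
}

# permutation mapping W (k^3*Cin x Cout) onto the flipped kernel
# Wflip (k^3*Cout x Cin), used for the adjoint ("same"-padded) convolution
flip_perm <- function(cin, cout, k3) {
  key <- sprintf("flip_%d_%d_%d", cin, cout, k3)
  perm <- .conv_ws[[key]]
  if (is.null(perm)) {
    perm <- integer(k3 * cin * cout)
    for (ci in seq_len(cin)) for (co in seq_len(cout)) for (t in seq_len(k3)) {
      dst <- (co - 1L) * k3 + (k3 - t + 1L) + (ci - 1L) * k3 * cout
      src <- (ci - 1L) * k3 + t + (co - 1L) * k3 * cin
      perm[dst] <- src
    }
    .conv_ws[[key]] <- perm
  }
  perm
}

# dY: array (d1,d2,d3,Cout); P/dims_in from the matching forward pass.
# dX is the adjoint of the padded convolution, computed as a padded
# convolution of dY with the channel-swapped, spatially flipped kernel.
# dW must be taken from P before the dY im2col reuses its workspace
# (the shapes coincide when no pooling follows the layer).
conv3d_bwd <- function(dY, P, dims_in, W, k = 3L, compute_dx = TRUE) {
  nvox <- prod(dims_in[1:3])
  cout <- dim(dY)[4]
  cin <- dims_in[4]
  dYm <- matrix(dY, nvox, cout)
  dW <- crossprod(P, dYm)
  db <- colSums(dYm)
  dx <- NULL
  if (compute_dx) {
    dyd <- as.integer(dim(dY))
    Wflip <- matrix(W[flip_perm(cin, cout, k^3)], k^3 * cout, cin)
    Pb <- get_ws(paste0("P_", paste(dyd, collapse = "_")), nvox, k^3 * cout)
    im2col_fill(Pb, dY, dyd, k)
    dx <- array(Pb %*% Wflip, c(dims_in[1:3], cin))
  }
  list(dx = dx, dW = dW, db = db)
}

maxpool_fwd <- function(x) maxpool3d_forward(x, as.integer(dim(x)))

maxpool_bwd <- function(dY, idx, dims_in) {
  dx <- numeric(prod(dims_in))
  dx[idx] <- dY
  array(dx, dims_in)
}

# ---------------------------------------------------------------------------
# Dense layers (vector in, vector out)

dense_fwd <- function(x, W, b) drop(crossprod(W, x)) + b

dense_bwd <- function(dy, x, W) {
  list(dx = drop(W %*% dy), dW = outer(x, dy), db = dy)
}

# ---------------------------------------------------------------------------
# Graph convolution with signed edge weights (sum aggregation + self update):
#   Z = H Wself + (A H) Wneigh + b
# A is the full signed adjacency (zero diagonal), H is n x f.

gcn_fwd <- function(H, A, Wself, Wneigh, b) {
  Z <- H %*% Wself + (A %*% H) %*% Wneigh
  Z + rep(b, each = nrow(Z))
}

gcn_bwd <- function(dZ, H, A, Wself, Wneigh) {
  AH <- A %*% H
  list(dH = dZ %*% t(Wself) + A %*% (dZ %*% t(Wneigh)),  # A symmetric
       dWself = crossprod(H, dZ),
       dWneigh = crossprod(AH, dZ),
       db = colSums(dZ))
}

# ---------------------------------------------------------------------------
# Chebyshev spectral graph convolution of order K on the rescaled Laplacian:
#   Z = sum_k (T_k H) W_k + b,  T_k = T_k(Ltilde), Ltilde = 2 L / lambda_max - I

# symmetric-normalised Laplacian; isolated nodes get L_ii = 1, off-diag 0
sym_laplacian <- function(A) {
  n <- nrow(A)
  d <- rowSums(A)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- diag(n) - (dinv * A) * rep(dinv, each = n)  # D^-1/2 A D^-1/2
  (L + t(L)) / 2
}

# dominant eigenvalue of a symmetric PSD matrix by power iteration
power_lambda_max <- function(L, tol = 1e-6, max_iter = 10000L) {
  n <- nrow(L)
  v <- cos(seq_len(n)) + 1.5     # fixed, nonzero, generic start
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (i in seq_len(max_iter)) {
    w <- drop(L %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v <- w / nw
    lam_new <- drop(crossprod(v, L %*% v))
    if (abs(lam_new - lam) < tol * max(1, abs(lam_new))) return(lam_new)
    lam <- lam_new
  }
  lam
}

scaled_laplacian <- function(A, tol = 1e-6) {
  L <- sym_laplacian(A)
  lam <- power_lambda_max(L, tol = tol)
  if (lam <= 0) lam <- 2  # degenerate graph: fall back to the spectral bound
  2 * L / lam - diag(nrow(A))
}

# T_0..T_{K-1} by the Chebyshev recursion T_k = 2 Lt T_{k-1} - T_{k-2}
cheb_polynomials <- function(Lt, K) {
  n <- nrow(Lt)
  Tk <- vector("list", K)
  Tk[[1]] <- diag(n)
  if (K >= 2) Tk[[2]] <- Lt
  if (K >= 3) for (k in 3:K) Tk[[k]] <- 2 * Lt %*% Tk[[k - 1]] - Tk[[k - 2]]
  Tk
}

# W: array (fin, fout, K)
cheb_fwd <- function(H, Tk, W, b) {
  K <- dim(W)[3]
  Z <- matrix(0, nrow(H), dim(W)[2])
  for (k in seq_len(K)) Z <- Z + (Tk[[k]] %*% H) %*% W[, , k, drop = TRUE]
  Z + rep(b, each = nrow(Z))
}

cheb_bwd <- function(dZ, H, Tk, W) {
  K <- dim(W)[3]
  dH <- matrix(0, nrow(H), ncol(H))
  dW <- array(0, dim(W))
  for (k in seq_len(K)) {
    Wk <- matrix(W[, , k], dim(W)[1], dim(W)[2])
    TkH <- Tk[[k]] %*% H
    dW[, , k] <- crossprod(TkH, dZ)
    dH <- dH + Tk[[k]] %*% (dZ %*% t(Wk))  # T_k symmetric
  }
  list(dH = dH, dW = dW, db = colSums(dZ))
}

# ---------------------------------------------------------------------------
# Output head

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# weighted cross entropy for one subject; y is the class index, w the class
# weights. Returns loss and the gradient w.r.t. the logits.
weighted_ce <- function(logits, y, w) {
  p <- softmax(logits)
  loss <- -w[y] * log(max(p[y], 1e-12))
  dlogits <- w[y] * p
  dlogits[y] <- dlogits[y] - w[y]
  list(loss = loss, dlogits = dlogits, p = p)
}
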