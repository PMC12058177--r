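## Low-level neural building blocks: layer normalization, GELU, row softmax,
## and their analytic gradients. Everything operates on plain double matrices
## whose rows are token states, so the heavy lifting is done by BLAS.
## Correctness of every backward rule is pinned by a finite-difference test.

ln_forward <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- xhat * rep(g, each = nrow(x)) + rep(b, each = nrow(x))
  list(y = y, xhat = xhat, inv = inv)
}

ln_backward <- function(dy, cache, g) {
  n <- nrow(dy)
  dxhat <- dy * rep(g, each = n)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dx <- cache$inv * (dxhat - m1 - cache$xhat * m2)
  list(dx = dx, dg = colSums(dy * cache$xhat), db = colSums(dy))
}

relu <- function(x) (x > 0) * x
relu_grad <- function(x) (x > 0) + 0

## Row-wise softmax of a matrix of logits.
softmax_rows <- function(x) {
  mx <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - mx)
  e / rowSums(e)
}

## Backward through row softmax: dS = P * (dP - rowSums(dP * P))
softmax_rows_backward <- function(dP, P) {
  P * (dP - rowSums(dP * P))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## Linear layer helpers on (n x d_in) row-state matrices.
lin_forward <- function(x, W, b) x %*% W + rep(b, each = nrow(x))
lin_backward <- function(dy, x, W) {
  list(dx = dy %*% t(W), dW = crossprod(x, dy), db = colSums(dy))
}

## Inverted dropout; returns the already-scaled mask (1/keep or 0).
dropout_mask <- function(n, d, rate) {
  if (rate <= 0) return(NULL)
  matrix((runif(n * d) >= rate) / (1 - rate), n, d)
}
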