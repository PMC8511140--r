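# Independent brute-force evaluators used as oracles for the network
# layers.  They follow the definitional formulas literally (materializing
# the full N x N x C x F filter tensor, explicit loops) and share no code
# with the implementation under test.

brute_graph_conv <- function(V, A, weights, act = function(x) pmax(x, 0)) {
  N <- nrow(V); C <- ncol(V); F <- ncol(weights$W0); L <- dim(A)[3]
  out <- matrix(0, N, F)
  for (f in seq_len(F)) {
    for (c in seq_len(C)) {
      H_cf <- matrix(0, N, N)
      for (l in seq_len(L)) H_cf <- H_cf + weights$h[c, f, l] * A[, , l]
      out[, f] <- out[, f] + as.numeric(H_cf %*% V[, c])
    }
  }
  b <- as.numeric(weights$b)
  if (length(b) == 1) b <- rep(b, F)
  for (i in seq_len(N)) {
    for (f in seq_len(F)) {
      out[i, f] <- out[i, f] + sum(V[i, ] * weights$W0[, f]) + b[f]
    }
  }
  act(out)
}

brute_affine <- function(u, W, b, act = function(x) pmax(x, 0)) {
  out <- matrix(0, nrow(u), ncol(W))
  b <- as.numeric(b)
  for (i in seq_len(nrow(u))) {
    for (j in seq_len(ncol(W))) {
      out[i, j] <- act(sum(u[i, ] * W[, j]) + b[j])
    }
  }
  out
}

brute_attention <- function(V, phi, mask = rep(1, nrow(V))) {
  scores <- numeric(nrow(V))
  for (i in seq_len(nrow(V))) {
    hid <- pmax(as.numeric(V[i, ] %*% phi$W1) + as.numeric(phi$b1), 0)
    scores[i] <- sum(hid * as.numeric(phi$w2)) + as.numeric(phi$b2)
  }
  keep <- which(mask > 0)
  w <- numeric(nrow(V))
  e <- exp(scores[keep] - max(scores[keep]))
  w[keep] <- e / sum(e)
  pooled <- numeric(ncol(V))
  for (i in seq_len(nrow(V))) pooled <- pooled + w[i] * V[i, ]
  list(weights = w, pooled = pooled)
}

# Random tiny instances for the oracle comparisons.
random_conv_instance <- function() {
  N <- sample(2:6, 1); C <- sample(1:5, 1); F <- sample(1:5, 1)
  L <- sample(1:4, 1)
  A <- array(0, c(N, N, L))
  for (l in seq_len(L)) {
    n_edges <- sample(0:(N * (N - 1) / 2), 1)
    if (n_edges > 0) {
      pairs <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
      pick <- pairs[sample(nrow(pairs), min(n_edges, nrow(pairs))), , drop = FALSE]
      for (r in seq_len(nrow(pick))) {
        A[pick[r, 1], pick[r, 2], l] <- 1
        A[pick[r, 2], pick[r, 1], l] <- 1
      }
    }
  }
  list(V = matrix(rnorm(N * C), N, C), A = A,
       weights = list(h = array(rnorm(C * F * L), c(C, F, L)),
                      W0 = matrix(rnorm(C * F), C, F),
                      b = rnorm(F)))
}

# Random ccgraph-shaped object with two coformer blocks (no chemistry).
random_ccgraph <- function(n1 = sample(3:6, 1), n2 = sample(3:6, 1),
                           C = atom_feature_width(), label = sample(0:1, 1)) {
  n <- n1 + n2
  A <- array(0, c(n, n, 4))
  for (blk in list(seq_len(n1), n1 + seq_len(n2))) {
    for (rep in seq_len(length(blk))) {
      ij <- sample(blk, 2)
      l <- sample(1:4, 1)
      A[ij[1], ij[2], l] <- 1
      A[ij[2], ij[1], l] <- 1
    }
  }
  U <- matrix(rnorm(24), 2, 12,
              dimnames = list(c("a", "b"), ccgnet:::CCG_DESCRIPTOR_NAMES))
  structure(list(V = matrix(rnorm(n * C), n, C), A = A, U = U,
                 slices = list(a = seq_len(n1), b = n1 + seq_len(n2)),
                 label = label, ids = c("x", "y")),
            class = "ccgraph")
}

identity_scaler <- function() {
  list(V_center = rep(0, atom_feature_width()),
       V_scale = rep(1, atom_feature_width()),
       U_center = rep(0, 12), U_scale = rep(1, 12))
}
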