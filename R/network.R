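# The network: stacked co-crystal graph blocks (graph convolution on atoms,
# feedforward update of the per-coformer global state, broadcast
# concatenation of the state onto each coformer's atoms), a multi-head
# global-attention readout, and a dense classification head with a
# two-dimensional output (score_negative, score_positive).
#
# The R functions here are the reference forward pass used for inspection
# and tests; training and batched prediction run through the compiled
# engine (src/), which implements the identical arithmetic.

relu <- function(x) pmax(x, 0)

#' Network configuration
#'
#' Sizes of the message-passing stack and readout.  The descriptor feature
#' mode selects which global-state columns are used: `"MG"` drops the global
#' state entirely (molecular graph alone), `"MG+2D"` keeps the five
#' conformer-independent descriptors, `"MG+3D"` the seven conformer-derived
#' ones, `"MG+2D+3D"` all twelve.
#'
#' Defaults are sized for CPU-scale screening work; all widths are
#' configurable and recorded in checkpoints.
#'
#' @param feature_mode One of `"MG"`, `"MG+2D"`, `"MG+3D"`, `"MG+2D+3D"`.
#' @param conv_widths Graph-convolution output width per block (depth 4 by
#'   default).
#' @param global_widths Global-state embedding width per block (same length
#'   as `conv_widths`; ignored in `"MG"` mode).
#' @param n_heads Attention head count K (>= 1).
#' @param att_hidden Hidden width of each head's two-layer scorer MLP.
#' @param dense_widths Widths of the dense head's hidden layers; a final
#'   2-unit linear layer is always appended.
#' @param atom_width Atom feature width (fixed by the feature layout).
#' @return A `ccgnet_config` object with resolved per-layer dimensions.
#' @export
ccgnet_config <- function(feature_mode = "MG+2D+3D",
                          conv_widths = c(16L, 16L, 32L, 32L),
                          global_widths = c(24L, 24L, 24L, 24L),
                          n_heads = 2L,
                          att_hidden = 16L,
                          dense_widths = c(128L, 64L),
                          atom_width = atom_feature_width()) {
  feature_mode <- match.arg(feature_mode, c("MG", "MG+2D", "MG+3D", "MG+2D+3D"))
  stopifnot(length(conv_widths) >= 1, n_heads >= 1, att_hidden >= 1,
            length(dense_widths) >= 1,
            length(global_widths) == length(conv_widths))
  desc_names <- switch(feature_mode,
                       "MG" = character(),
                       "MG+2D" = CCG_DESC_2D,
                       "MG+3D" = CCG_DESC_3D,
                       "MG+2D+3D" = CCG_DESCRIPTOR_NAMES)
  desc_idx <- match(desc_names, CCG_DESCRIPTOR_NAMES)
  has_global <- length(desc_idx) > 0
  if (!has_global) global_widths <- rep(0L, length(conv_widths))

  T <- length(conv_widths)
  node_in <- integer(T); state_in <- integer(T)
  cw <- atom_width; dw <- length(desc_idx)
  for (t in seq_len(T)) {
    node_in[t] <- cw; state_in[t] <- dw
    dw <- if (has_global) global_widths[t] else 0L
    cw <- conv_widths[t] + dw
  }
  structure(list(
    feature_mode = feature_mode, desc_idx = desc_idx,
    conv_widths = as.integer(conv_widths),
    global_widths = as.integer(global_widths),
    n_heads = as.integer(n_heads), att_hidden = as.integer(att_hidden),
    dense_widths = as.integer(dense_widths),
    atom_width = as.integer(atom_width),
    n_blocks = T, node_in = node_in, state_in = state_in,
    node_out = cw, state_out = dw,
    head_in = as.integer(n_heads) * cw + 2L * dw,
    layout_version = CCG_LAYOUT_VERSION
  ), class = "ccgnet_config")
}

#' @export
print.ccgnet_config <- function(x, ...) {
  cat("<ccgnet_config> mode ", x$feature_mode, ", ", x$n_blocks,
      " blocks (conv ", paste(x$conv_widths, collapse = "/"),
      ", global ", paste(x$global_widths, collapse = "/"),
      "), K=", x$n_heads, ", dense ",
      paste(c(x$dense_widths, 2L), collapse = "-"), "\n", sep = "")
  invisible(x)
}

he_init <- function(nr, nc) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / max(nr, 1))), nr, nc)
}

#' Initialize network weights
#'
#' He-normal initialization for all ReLU layers, driven entirely by one
#' seed so that a configuration and a seed fully determine the starting
#' point.
#'
#' @param config A [ccgnet_config()].
#' @param seed Integer seed.
#' @return Named list of weight arrays (the flat parameter set used by both
#'   the R forward pass and the compiled engine).
#' @export
ccgnet_init <- function(config, seed = 1L) {
  set.seed(seed)
  p <- list()
  L <- length(CCG_BOND_TYPES)
  for (t in seq_len(config$n_blocks)) {
    C <- config$node_in[t]; F <- config$conv_widths[t]
    if (config$state_in[t] > 0) {
      p[[sprintf("b%d_gW", t)]] <- he_init(config$state_in[t], config$global_widths[t])
      p[[sprintf("b%d_gb", t)]] <- matrix(0, 1, config$global_widths[t])
    }
    p[[sprintf("b%d_W0", t)]] <- he_init(C, F)
    h <- array(rnorm(C * F * L, sd = sqrt(2 / (C * L))), dim = c(C, F, L))
    p[[sprintf("b%d_h", t)]] <- h
    p[[sprintf("b%d_cb", t)]] <- matrix(0, 1, F)
  }
  for (k in seq_len(config$n_heads)) {
    p[[sprintf("att%d_W1", k)]] <- he_init(config$node_out, config$att_hidden)
    p[[sprintf("att%d_b1", k)]] <- matrix(0, 1, config$att_hidden)
    p[[sprintf("att%d_w2", k)]] <- he_init(config$att_hidden, 1)
    p[[sprintf("att%d_b2", k)]] <- matrix(0, 1, 1)
  }
  dims <- c(config$head_in, config$dense_widths, 2L)
  for (d in seq_len(length(dims) - 1)) {
    p[[sprintf("head_W%d", d)]] <- he_init(dims[d], dims[d + 1])
    p[[sprintf("head_b%d", d)]] <- matrix(0, 1, dims[d + 1])
  }
  p
}

#' Graph convolution over a bond-type adjacency tensor
#'
#' Filters node features with one scalar weight per (bond type, input
#' feature, output filter) triple: the effective filter for input channel c
#' and output filter f is `sum_l h[c,f,l] * A_l`, applied to the channel and
#' summed over channels, plus a self-loop term `V %*% W0` and a bias.
#'
#' @param V_in N x C node feature matrix.
#' @param A N x N x L adjacency tensor.
#' @param weights List with `h` (C x F x L array), `W0` (C x F), `b` (length
#'   F or 1 x F).
#' @param act Activation function (default ReLU).
#' @return N x F matrix of updated node features.
#' @export
graph_conv <- function(V_in, A, weights, act = relu) {
  C <- ncol(V_in); L <- dim(A)[3]
  stopifnot(dim(weights$h)[1] == C, dim(weights$h)[3] == L,
            nrow(weights$W0) == C, dim(A)[1] == nrow(V_in))
  Z <- V_in %*% weights$W0
  for (l in seq_len(L)) {
    Z <- Z + A[, , l] %*% (V_in %*% weights$h[, , l])
  }
  act(sweep(Z, 2, as.numeric(weights$b), `+`))
}

#' Global-state update
#'
#' One feedforward layer applied independently to each coformer's global
#' state row: `u' = act(u W + b)`.
#'
#' @param u Matrix with one row per coformer (2 x D).
#' @param W D x D' weight matrix.
#' @param b Bias (length D').
#' @param act Activation function (default ReLU).
#' @return Updated global-state matrix (2 x D').
#' @export
global_state_update <- function(u, W, b, act = relu) {
  stopifnot(ncol(u) == nrow(W))
  act(sweep(u %*% W, 2, as.numeric(b), `+`))
}

#' Broadcast-concatenate the global state onto each coformer's atoms
#'
#' Every atom of coformer 1 gets the first global-state row appended, every
#' atom of coformer 2 the second.
#'
#' @param V N x F node matrix.
#' @param u 2 x D' global-state matrix.
#' @param slices List of the two coformers' atom index ranges.
#' @return N x (F + D') matrix.
#' @export
broadcast_concat <- function(V, u, slices) {
  n <- nrow(V)
  if (length(intersect(slices$a, slices$b)) > 0 ||
      max(slices$a, slices$b) > n) {
    stop("coformer slices do not partition the node set", call. = FALSE)
  }
  # rows beyond both slices (zero padding) keep a zero appended segment
  B <- matrix(0, n, ncol(u))
  B[slices$a, ] <- matrix(u[1, ], length(slices$a), ncol(u), byrow = TRUE)
  B[slices$b, ] <- matrix(u[2, ], length(slices$b), ncol(u), byrow = TRUE)
  cbind(V, B)
}

#' One message-passing block
#'
#' Updates the global state, convolves the node features over the adjacency
#' tensor, then broadcasts the updated state onto each coformer's atoms.
#' Both the node embeddings and the global state are replaced for the next
#' block.
#'
#' @param state List with `V`, `A`, `U`, `slices` (a `ccgraph` or the output
#'   of a previous block).
#' @param block Named sublist of weights: `gW`, `gb` (absent in MG mode),
#'   `W0`, `h`, `cb`.
#' @param act Activation function.
#' @return Updated state (same shape of list).
#' @export
ccgblock <- function(state, block, act = relu) {
  has_global <- !is.null(block$gW) && !is.null(state$U) && ncol(state$U) > 0
  Vc <- graph_conv(state$V, state$A, list(h = block$h, W0 = block$W0,
                                          b = block$cb), act = act)
  if (has_global) {
    Un <- global_state_update(state$U, block$gW, block$gb, act = act)
    state$V <- broadcast_concat(Vc, Un, state$slices)
    state$U <- Un
  } else {
    state$V <- Vc
  }
  state
}

masked_softmax <- function(logits, mask) {
  keep <- mask > 0
  if (!any(keep)) stop("empty-graph error: all nodes masked", call. = FALSE)
  w <- numeric(length(logits))
  z <- logits[keep] - max(logits[keep])
  e <- exp(z)
  w[keep] <- e / sum(e)
  w
}

#' Global attention pooling
#'
#' Scores every node with a small MLP, softmaxes the scores over the real
#' (unmasked) nodes, and returns the attention-weighted sum of node
#' features.
#'
#' @param V N x C node embedding matrix.
#' @param phi Head weights: `W1`, `b1`, `w2`, `b2` (two-layer scorer MLP).
#' @param mask Optional 0/1 vector marking real nodes (default all real).
#' @return List with `weights` (length N, zero on padded nodes, summing to 1)
#'   and `pooled` (length C graph embedding).
#' @export
global_attention <- function(V, phi, mask = NULL) {
  if (is.null(mask)) mask <- rep(1, nrow(V))
  H <- relu(sweep(V %*% phi$W1, 2, as.numeric(phi$b1), `+`))
  logits <- as.numeric(H %*% phi$w2) + as.numeric(phi$b2)
  a <- masked_softmax(logits, mask)
  list(weights = a, pooled = as.numeric(crossprod(V, a)))
}

#' Multi-head global-attention readout
#'
#' K independent attention heads pool the node embeddings in parallel; the K
#' pooled vectors are concatenated into the graph-level embedding.
#'
#' @param V N x C node embedding matrix.
#' @param heads List of K head weight lists (as in [global_attention()]).
#' @param mask Optional 0/1 node mask.
#' @return List with `pooled` (length K*C) and `weights` (N x K matrix).
#' @export
multihead_readout <- function(V, heads, mask = NULL) {
  outs <- lapply(heads, function(phi) global_attention(V, phi, mask))
  list(pooled = unlist(lapply(outs, `[[`, "pooled"), use.names = FALSE),
       weights = do.call(cbind, lapply(outs, `[[`, "weights")))
}

block_weights <- function(params, t) {
  list(gW = params[[sprintf("b%d_gW", t)]], gb = params[[sprintf("b%d_gb", t)]],
       W0 = params[[sprintf("b%d_W0", t)]], h = params[[sprintf("b%d_h", t)]],
       cb = params[[sprintf("b%d_cb", t)]])
}

head_weights <- function(params, k) {
  list(W1 = params[[sprintf("att%d_W1", k)]], b1 = params[[sprintf("att%d_b1", k)]],
       w2 = params[[sprintf("att%d_w2", k)]], b2 = params[[sprintf("att%d_b2", k)]])
}

#' Reference forward pass
#'
#' Runs the full network on one (possibly padded) co-crystal graph in plain
#' R.  The compiled engine reproduces this arithmetic; tests hold the two
#' implementations together.
#'
#' @param graph A `ccgraph` (V, A, U, slices), with `U` already restricted
#'   to the configured descriptor columns and features scaled as during
#'   training.
#' @param params Weight list from [ccgnet_init()] or a trained model.
#' @param config The matching [ccgnet_config()].
#' @param mask Optional 0/1 node mask for padded graphs.
#' @return List with `logits` (length 2: score_negative, score_positive),
#'   `prob` (softmax of logits), `label` (1 iff positive score exceeds the
#'   negative score), `attention` (N x K), `embedding` (readout vector).
#' @export
ccgnet_forward <- function(graph, params, config, mask = NULL) {
  state <- list(V = graph$V, A = graph$A,
                U = if (length(config$desc_idx) > 0) graph$U else NULL,
                slices = graph$slices)
  for (t in seq_len(config$n_blocks)) {
    state <- ccgblock(state, block_weights(params, t))
  }
  ro <- multihead_readout(state$V, lapply(seq_len(config$n_heads),
                                          function(k) head_weights(params, k)),
                          mask = mask)
  g <- c(ro$pooled,
         if (!is.null(state$U)) as.numeric(t(state$U)) else numeric())
  n_dense <- length(config$dense_widths) + 1L
  x <- matrix(g, 1)
  for (d in seq_len(n_dense)) {
    x <- sweep(x %*% params[[sprintf("head_W%d", d)]], 2,
               as.numeric(params[[sprintf("head_b%d", d)]]), `+`)
    if (d < n_dense) x <- relu(x)
  }
  logits <- as.numeric(x)
  z <- logits - max(logits)
  prob <- exp(z) / sum(exp(z))
  list(logits = logits, prob = prob,
       label = as.integer(logits[2] > logits[1]),
       attention = ro$weights, embedding = g)
}

#' Decision rule on the two-dimensional output
#'
#' The network emits `(a, b)` = (negative score, positive score); a sample
#' is called positive exactly when `b > a`.  Ties classify as negative,
#' the conservative choice for screening.
#'
#' @param scores Numeric vector of length 2 or an n x 2 matrix.
#' @return Integer label(s) in {0, 1}.
#' @export
decide_label <- function(scores) {
  if (is.matrix(scores)) as.integer(scores[, 2] > scores[, 1])
  else as.integer(scores[2] > scores[1])
}

#' Per-atom attention weights of a trained model
#'
#' Extracts the K attention-weight vectors for one sample, aligned to the
#' input atom order; each head's weights are nonnegative and sum to one, and
#' high-weight atoms mark the substructures the readout relies on.
#'
#' @param model A trained `ccgnet_model`.
#' @param graph A `ccgraph` sample.
#' @return N x K matrix of attention weights.
#' @export
attention_map <- function(model, graph) {
  pred <- predict(model, list(graph), attention = TRUE)
  attr(pred, "attention")[[1]]
}
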