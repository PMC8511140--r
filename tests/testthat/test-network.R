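ident <- function(x) x

test_that("graph convolution reproduces the hand-computed fixtures", {
  for (fx in tiny_graph_fixtures()) {
    act <- if (fx$act == "relu") function(x) pmax(x, 0) else ident
    expect_equal(graph_conv(fx$V, fx$A, fx$weights, act = act), fx$expected,
                 tolerance = 1e-12)
    # and the loop-based evaluator agrees on the same frozen values
    expect_equal(brute_graph_conv(fx$V, fx$A, fx$weights, act = act),
                 fx$expected, tolerance = 1e-12)
  }
})

test_that("graph convolution matches the brute-force filter-tensor oracle", {
  set.seed(7)
  for (rep in 1:50) {
    inst <- random_conv_instance()
    expect_equal(graph_conv(inst$V, inst$A, inst$weights),
                 brute_graph_conv(inst$V, inst$A, inst$weights),
                 tolerance = 1e-6)
  }
  # all-zero adjacency with identity self-loop weights is the identity map
  V <- matrix(rnorm(12), 4, 3)
  w <- list(h = array(0, c(3, 3, 2)), W0 = diag(3), b = rep(0, 3))
  expect_equal(graph_conv(V, array(0, c(4, 4, 2)), w, act = ident), V)
})

test_that("global-state update is the per-row affine map", {
  u <- matrix(rnorm(8), 2, 4)
  expect_equal(global_state_update(u, diag(4), rep(0, 4), act = ident), u)
  expect_equal(global_state_update(u, matrix(0, 4, 3), c(-1, 0, 2)),
               matrix(rep(c(0, 0, 2), each = 2), 2, 3))
  W <- matrix(rnorm(12), 4, 3); b <- rnorm(3)
  expect_equal(global_state_update(u, W, b), brute_affine(u, W, b),
               tolerance = 1e-6)
})

test_that("broadcast concatenation appends the right state to each coformer", {
  V <- matrix(rnorm(5 * 3), 5, 3)
  u <- matrix(rnorm(4), 2, 2)
  slices <- list(a = 1:2, b = 3:5)
  out <- broadcast_concat(V, u, slices)
  expect_equal(dim(out), c(5, 5))
  expect_equal(out[1, 4:5], out[2, 4:5])
  expect_equal(out[1, 4:5], u[1, ])
  expect_equal(out[4, 4:5], u[2, ])
  # swapping coformer order permutes rows consistently
  perm <- c(3:5, 1:2)
  swapped <- broadcast_concat(V[perm, ], u[c(2, 1), ],
                              list(a = 1:3, b = 4:5))
  expect_equal(swapped, out[perm, ])
  expect_error(broadcast_concat(V, u, list(a = 1:2, b = 2:5)), "partition")
})

test_that("stacked blocks trace the concatenation arithmetic symbolically", {
  # identity weights, zero adjacency: V_t = [V_{t-1} | U0], U stays U0
  n1 <- 2; n2 <- 2; C0 <- 3; D <- 2
  V0 <- matrix(rnorm((n1 + n2) * C0), n1 + n2, C0)
  U0 <- matrix(rnorm(2 * D), 2, D)
  state <- list(V = V0, A = array(0, c(4, 4, 1)), U = U0,
                slices = list(a = 1:2, b = 3:4))
  width <- C0
  for (t in 1:4) {
    blk <- list(gW = diag(D), gb = rep(0, D),
                W0 = diag(width), h = array(0, c(width, width, 1)),
                cb = rep(0, width))
    state <- ccgblock(state, blk, act = ident)
    width <- width + D
  }
  expect_equal(ncol(state$V), C0 + 4 * D)
  expect_equal(state$U, U0)
  expect_equal(state$V[, 1:C0], V0)
  for (t in 1:4) {
    seg <- state$V[, C0 + (t - 1) * D + seq_len(D), drop = FALSE]
    expect_equal(seg[1:2, ], matrix(U0[1, ], 2, D, byrow = TRUE))
    expect_equal(seg[3:4, ], matrix(U0[2, ], 2, D, byrow = TRUE))
  }
})

test_that("global attention normalizes over real nodes only", {
  V <- matrix(rnorm(4 * 3), 4, 3)
  # constant scorer: uniform weights, pooled = node mean
  phi_const <- list(W1 = matrix(0, 3, 2), b1 = c(1, 1),
                    w2 = matrix(0, 2, 1), b2 = 0.3)
  out <- global_attention(V, phi_const)
  expect_equal(out$weights, rep(0.25, 4))
  expect_equal(out$pooled, colMeans(V))
  # hand softmax on logits (0, ln 3) -> (0.25, 0.75)
  V2 <- diag(2)
  phi2 <- list(W1 = diag(2), b1 = c(0, 0),
               w2 = matrix(c(0, log(3)), 2, 1), b2 = 0)
  expect_equal(global_attention(V2, phi2)$weights, c(0.25, 0.75),
               tolerance = 1e-12)
  # appending a masked zero node changes nothing
  V3 <- rbind(V, 0)
  out3 <- global_attention(V3, phi_const, mask = c(1, 1, 1, 1, 0))
  expect_equal(out3$pooled, out$pooled)
  expect_equal(out3$weights, c(out$weights, 0))
  expect_error(global_attention(V, phi_const, mask = rep(0, 4)), "masked")
  # brute-force agreement on random heads
  set.seed(8)
  for (rep in 1:50) {
    N <- sample(2:6, 1); C <- sample(2:5, 1)
    Vr <- matrix(rnorm(N * C), N, C)
    phi <- list(W1 = matrix(rnorm(C * 3), C, 3), b1 = rnorm(3),
                w2 = matrix(rnorm(3), 3, 1), b2 = rnorm(1))
    got <- global_attention(Vr, phi)
    want <- brute_attention(Vr, phi)
    expect_equal(got$weights, want$weights, tolerance = 1e-6)
    expect_equal(got$pooled, want$pooled, tolerance = 1e-6)
  }
})

test_that("multi-head readout concatenates independent heads", {
  set.seed(9)
  V <- matrix(rnorm(5 * 8), 5, 8)
  mk_head <- function() list(W1 = matrix(rnorm(8 * 4), 8, 4), b1 = rnorm(4),
                             w2 = matrix(rnorm(4), 4, 1), b2 = rnorm(1))
  h1 <- mk_head(); h2 <- mk_head(); h3 <- mk_head()
  single <- global_attention(V, h1)
  ro1 <- multihead_readout(V, list(h1))
  expect_equal(ro1$pooled, single$pooled)
  ro3 <- multihead_readout(V, list(h1, h2, h3))
  expect_length(ro3$pooled, 3 * 8)
  expect_equal(dim(ro3$weights), c(5, 3))
  ro_same <- multihead_readout(V, list(h1, h1))
  expect_equal(ro_same$pooled[1:8], ro_same$pooled[9:16])
})

test_that("the two-dimensional output decides positive iff b > a", {
  expect_equal(decide_label(c(0.2, 0.9)), 1L)
  expect_equal(decide_label(c(0.9, 0.2)), 0L)
  expect_equal(decide_label(c(0.5, 0.5)), 0L)   # tie is conservative
  expect_equal(decide_label(rbind(c(0, 1), c(1, 0), c(2, 2))), c(1L, 0L, 0L))
})

test_that("R reference forward and compiled engine agree", {
  set.seed(10)
  for (mode in c("MG+2D+3D", "MG")) {
    cfg <- ccgnet_config(feature_mode = mode, conv_widths = c(4L, 5L),
                         global_widths = c(3L, 4L), n_heads = 2L,
                         att_hidden = 4L, dense_widths = c(6L))
    params <- ccgnet_init(cfg, seed = 21)
    for (rep in 1:5) {
      g <- random_ccgraph()
      s <- ccgnet:::graph_to_sample(g, cfg, identity_scaler())
      fr <- ccgnet_forward(list(V = s$V, A = g$A, U = s$U, slices = g$slices),
                           params, cfg)
      fc <- ccgnet:::ccg_forward_cpp(s, params)
      expect_equal(fr$logits, as.numeric(fc$logits), tolerance = 1e-10)
      expect_equal(fr$attention, fc$attention, tolerance = 1e-10,
                   ignore_attr = TRUE)
    }
  }
})

test_that("engine gradients match central finite differences", {
  set.seed(11)
  cfg <- ccgnet_config(conv_widths = c(4L, 4L), global_widths = c(3L, 3L),
                       n_heads = 2L, att_hidden = 4L, dense_widths = c(6L))
  params <- ccgnet_init(cfg, seed = 31)
  # randomize biases away from zero so no pre-activation sits on the ReLU kink
  for (nm in names(params)) params[[nm]] <- params[[nm]] + 0.05 * rnorm(length(params[[nm]]))
  g <- random_ccgraph(4, 3)
  s <- ccgnet:::graph_to_sample(g, cfg, identity_scaler())
  gr <- ccgnet:::ccg_grad_cpp(s, 1L, params)
  loss_at <- function(p) ccgnet:::ccg_loss_cpp(list(s), 1L, p)
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(3, length(params[[nm]])))
    for (ii in idx) {
      eps <- 1e-5
      up <- params; up[[nm]][ii] <- up[[nm]][ii] + eps
      dn <- params; dn[[nm]][ii] <- dn[[nm]][ii] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(gr$grads[[nm]][ii], num, tolerance = 1e-4,
                   label = paste("grad", nm))
    }
  }
})

test_that("readout is invariant to node reordering within a coformer", {
  set.seed(12)
  cfg <- tiny_config()
  params <- ccgnet_init(cfg, seed = 41)
  g <- random_ccgraph(4, 3)
  perm_a <- sample(1:4)
  perm <- c(perm_a, 5:7)
  gp <- g
  gp$V <- g$V[perm, ]
  gp$A <- g$A[perm, perm, ]
  s1 <- ccgnet:::graph_to_sample(g, cfg, identity_scaler())
  s2 <- ccgnet:::graph_to_sample(gp, cfg, identity_scaler())
  f1 <- ccgnet:::ccg_forward_cpp(s1, params)
  f2 <- ccgnet:::ccg_forward_cpp(s2, params)
  expect_equal(as.numeric(f1$logits), as.numeric(f2$logits), tolerance = 1e-10)
  expect_equal(f1$attention[perm, ], f2$attention, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("predictions are invariant to padding width", {
  set.seed(13)
  cfg <- tiny_config()
  params <- ccgnet_init(cfg, seed = 51)
  g <- random_ccgraph(3, 4)
  s <- ccgnet:::graph_to_sample(g, cfg, identity_scaler())
  base <- ccgnet_forward(list(V = s$V, A = g$A, U = s$U, slices = g$slices),
                         params, cfg)
  for (n_max in c(10L, 16L)) {
    batch <- pad_batch(list(g), n_max = n_max)
    gp <- unpad_batch(batch)[[1]]          # round trip first
    expect_equal(gp$V, g$V)
    Vp <- rbind(s$V, matrix(0, n_max - nrow(s$V), ncol(s$V)))
    Ap <- array(0, c(n_max, n_max, 4))
    Ap[seq_len(nrow(s$V)), seq_len(nrow(s$V)), ] <- g$A
    padded <- ccgnet_forward(list(V = Vp, A = Ap, U = s$U, slices = g$slices),
                             params, cfg, mask = batch$mask[1, ])
    expect_equal(padded$logits, base$logits, tolerance = 1e-6)
  }
})

test_that("attention maps align with atoms and normalize per head", {
  model <- tiny_model()
  g <- tiny_pairset()$graphs[[1]]
  att <- attention_map(model, g)
  expect_equal(nrow(att), nrow(g$V))
  expect_equal(ncol(att), model$config$n_heads)
  expect_true(all(att >= 0))
  expect_equal(colSums(att), rep(1, ncol(att)), tolerance = 1e-6)
})

test_that("every feature-toggle ablation builds and trains", {
  d <- tiny_pairset()
  for (mode in c("MG", "MG+2D", "MG+3D", "MG+2D+3D")) {
    cfg <- ccgnet_config(feature_mode = mode, conv_widths = c(8L, 8L),
                         global_widths = c(8L, 8L), dense_widths = c(16L))
    m <- train_ccgnet(d$graphs[1:30], cfg, epochs = 3, seed = 2)
    pred <- predict(m, d$graphs[31:40])
    expect_equal(nrow(pred), 10)
    expect_true(all(pred$label %in% 0:1))
  }
})
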