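# Training, cross-validation, metrics and ensemble scoring.

# --- sample conversion ------------------------------------------------------

# Column-wise standardization fitted on the training graphs; constant
# columns keep scale 1.  Stored in the model and re-applied at prediction.
fit_scaler <- function(graphs, config) {
  Vall <- do.call(rbind, lapply(graphs, `[[`, "V"))
  Uall <- do.call(rbind, lapply(graphs, function(g)
    g$U[, config$desc_idx, drop = FALSE]))
  safe_sd <- function(x) { s <- sd(x); if (!is.finite(s) || s < 1e-8) 1 else s }
  list(V_center = colMeans(Vall), V_scale = apply(Vall, 2, safe_sd),
       U_center = if (ncol(Uall) > 0) colMeans(Uall) else numeric(),
       U_scale = if (ncol(Uall) > 0) apply(Uall, 2, safe_sd) else numeric())
}

slice_edges <- function(A) {
  lapply(seq_len(dim(A)[3]), function(l) {
    e <- which(A[, , l] != 0, arr.ind = TRUE)
    matrix(as.integer(e) - 1L, ncol = 2)
  })
}

# ccgraph -> engine sample (descriptor subset + scaling + 0-based edges).
graph_to_sample <- function(g, config, scaler) {
  V <- sweep(sweep(g$V, 2, scaler$V_center), 2, scaler$V_scale, `/`)
  U <- g$U[, config$desc_idx, drop = FALSE]
  if (ncol(U) > 0) {
    U <- sweep(sweep(U, 2, scaler$U_center), 2, scaler$U_scale, `/`)
  }
  list(V = V, edges = slice_edges(g$A), U = U, n1 = length(g$slices$a))
}

graphs_to_samples <- function(graphs, config, scaler) {
  lapply(graphs, graph_to_sample, config = config, scaler = scaler)
}

graph_labels <- function(graphs) {
  y <- vapply(graphs, function(g) as.numeric(g$label), numeric(1))
  if (anyNA(y)) stop("unlabeled samples cannot be used for training", call. = FALSE)
  as.integer(y)
}

# --- metrics ----------------------------------------------------------------

#' Classification metrics for imbalanced screening
#'
#' Tallies the confusion matrix and reports the true positive rate
#' (sensitivity), true negative rate (specificity) and balanced accuracy,
#' the mean of the two.  Balanced accuracy weighs both classes equally
#' regardless of prevalence, which is why it is the headline metric for
#' heavily imbalanced co-crystal data.
#'
#' @param y_true,y_pred Equal-length binary (0/1) vectors.
#' @return `ccg_metrics` object: counts TP, FP, TN, FN and rates TPR, TNR,
#'   BACC in `[0, 1]` (`NA` when a class is absent from `y_true`).
#' @export
compute_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  if (length(y_true) == 0) stop("empty input", call. = FALSE)
  stopifnot(all(y_true %in% c(0, 1)), all(y_pred %in% c(0, 1)))
  tp <- sum(y_true == 1 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tnr <- if (tn + fp > 0) tn / (fp + tn) else NA_real_
  bacc <- if (is.na(tpr) || is.na(tnr)) NA_real_ else (tpr + tnr) / 2
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 TPR = tpr, TNR = tnr, BACC = bacc),
            class = "ccg_metrics")
}

#' @export
print.ccg_metrics <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", 100 * v)
  cat("TP ", x$TP, "  FP ", x$FP, "  TN ", x$TN, "  FN ", x$FN, "\n",
      "TPR ", pct(x$TPR), "  TNR ", pct(x$TNR), "  BACC ", pct(x$BACC), "\n",
      sep = "")
  invisible(x)
}

#' Balanced accuracy from per-class rates
#'
#' @param tpr,tnr True positive / true negative rates (same units, either
#'   fractions or percentages).
#' @return `(tpr + tnr) / 2` in the input units.
#' @export
balanced_accuracy <- function(tpr, tnr) (tpr + tnr) / 2

# --- training ---------------------------------------------------------------

#' Train a co-crystal graph network
#'
#' Optimizes softmax cross-entropy on the two-class output with Adam.  No
#' class reweighting is applied; robustness to the positive/negative
#' imbalance is carried by the feature representation and architecture.
#' By default the training set is augmented by coformer-order exchange
#' (each pair also enters with its components swapped), which makes the
#' fitted scores insensitive to input order.
#'
#' @param graphs List of labeled `ccgraph` samples (the training split).
#' @param config A [ccgnet_config()].
#' @param epochs,batch_size,lr Optimizer settings.
#' @param weight_decay Decoupled L2 weight decay applied at each Adam step;
#'   the small default regularizes against pair memorization on small
#'   datasets.
#' @param dropout Dropout rate on the dense head's hidden layers during
#'   training (inverted dropout; inference is deterministic).
#' @param seed Integer seed driving weight initialization and batch
#'   shuffling; a fixed seed reproduces the run exactly.
#' @param augment Apply order-swap augmentation to the training set.
#' @return A `ccgnet_model`: trained weights, config, feature scaler,
#'   per-epoch training-loss history and the seed.
#' @export
train_ccgnet <- function(graphs, config = ccgnet_config(), epochs = 60L,
                         batch_size = 32L, lr = 1e-3, seed = 1L,
                         augment = TRUE, weight_decay = 1e-3, dropout = 0) {
  train_set <- if (augment) augment_pairs(graphs) else graphs
  y <- graph_labels(train_set)
  scaler <- fit_scaler(train_set, config)
  params <- ccgnet_init(config, seed = seed)
  samples <- graphs_to_samples(train_set, config, scaler)
  fit <- ccg_train_cpp(samples, y, params, as.integer(epochs),
                       as.integer(batch_size), lr, as.integer(seed),
                       weight_decay, dropout)
  structure(list(params = fit$params, config = config, scaler = scaler,
                 history = as.numeric(fit$history), seed = as.integer(seed),
                 epochs = as.integer(epochs), lr = lr,
                 augmented = isTRUE(augment), weight_decay = weight_decay,
                 layout_version = CCG_LAYOUT_VERSION),
            class = "ccgnet_model")
}

#' @export
print.ccgnet_model <- function(x, ...) {
  cat("<ccgnet_model> mode ", x$config$feature_mode, ", ",
      x$config$n_blocks, " blocks, K=", x$config$n_heads,
      ", trained ", x$epochs, " epochs (final loss ",
      sprintf("%.4f", x$history[length(x$history)]), ")\n", sep = "")
  invisible(x)
}

#' Predict co-crystal formation for a list of pair graphs
#'
#' @param object A trained `ccgnet_model`.
#' @param graphs List of `ccgraph` samples.
#' @param attention If `TRUE`, attach per-sample attention-weight matrices
#'   as the `"attention"` attribute.
#' @param ... Unused.
#' @return Data frame with the two class scores (`score_neg`, `score_pos`,
#'   softmax probabilities) and the predicted `label` (positive iff the
#'   positive score strictly exceeds the negative one).
#' @export
predict.ccgnet_model <- function(object, graphs, attention = FALSE, ...) {
  samples <- graphs_to_samples(graphs, object$config, object$scaler)
  probs <- ccg_predict_cpp(samples, object$params)
  out <- data.frame(score_neg = probs[, 1], score_pos = probs[, 2],
                    label = as.integer(probs[, 2] > probs[, 1]))
  if (attention) {
    attr(out, "attention") <- lapply(samples, function(s)
      ccg_forward_cpp(s, object$params)$attention)
  }
  out
}

# Mean cross-entropy of a model on labeled graphs (used for transfer
# ensemble selection).
validation_loss <- function(model, graphs) {
  samples <- graphs_to_samples(graphs, model$config, model$scaler)
  ccg_loss_cpp(samples, graph_labels(graphs), model$params)
}

#' k-fold cross-validation
#'
#' Stratified folds are assigned before augmentation, each model is trained
#' on the other k-1 folds (order-swap augmented) and evaluated on its own
#' untouched fold, and per-fold rates are summarized as mean and standard
#' deviation.
#'
#' @param graphs Labeled `ccgraph` list.
#' @param config A [ccgnet_config()].
#' @param k Fold count (default 10).
#' @param seed Seed for fold assignment and per-fold training.
#' @param epochs,batch_size,lr,augment,weight_decay Passed to
#'   [train_ccgnet()].
#' @return List with `models` (k trained models), `folds`, per-fold
#'   `metrics`, and `summary` (mean and sd of TPR/TNR/BACC).
#' @export
cross_validate <- function(graphs, config = ccgnet_config(), k = 10L,
                           seed = 1L, epochs = 60L, batch_size = 32L,
                           lr = 1e-3, augment = TRUE, weight_decay = 1e-3, dropout = 0) {
  y <- graph_labels(graphs)
  folds <- stratified_kfold(y, k = k, seed = seed)
  models <- vector("list", k)
  metrics <- vector("list", k)
  for (i in seq_len(k)) {
    train_idx <- which(folds != i)
    val_idx <- which(folds == i)
    models[[i]] <- train_ccgnet(graphs[train_idx], config, epochs = epochs,
                                batch_size = batch_size, lr = lr,
                                seed = seed + i, augment = augment,
                                weight_decay = weight_decay, dropout = dropout)
    pred <- predict(models[[i]], graphs[val_idx])
    metrics[[i]] <- compute_metrics(y[val_idx], pred$label)
  }
  rates <- vapply(metrics, function(m) c(m$TPR, m$TNR, m$BACC), numeric(3))
  summary <- data.frame(metric = c("TPR", "TNR", "BACC"),
                        mean = rowMeans(rates),
                        sd = apply(rates, 1, sd))
  list(models = models, folds = folds, metrics = metrics, summary = summary)
}

#' Ensemble scoring and ranked screening
#'
#' Each ensemble member scores every pair; pairs are ranked by the sum of
#' the members' positive-class scores (highest first), and the predicted
#' label is the majority of the members' individual decisions.  Ties in the
#' summed score keep the input order (stable sort); tied votes classify as
#' negative.
#'
#' @param graphs List of `ccgraph` samples to screen.
#' @param models List of trained `ccgnet_model` objects sharing one feature
#'   layout.
#' @param ids Optional data frame (or 2-column matrix) of pair identifiers.
#' @return Data frame sorted by descending summed positive score: `rank`,
#'   `id_a`, `id_b`, `sum_positive_score`, `predicted_label`,
#'   `positive_votes`, and one `member<i>_score` column per member.
#' @export
ensemble_rank <- function(graphs, models, ids = NULL) {
  stopifnot(length(models) >= 1)
  versions <- vapply(models, `[[`, character(1), "layout_version")
  if (length(unique(versions)) != 1) {
    stop("ensemble members disagree on feature layout version", call. = FALSE)
  }
  if (is.null(ids)) {
    ids <- t(vapply(graphs, function(g) as.character(g$ids), character(2)))
  }
  ids <- as.data.frame(ids, stringsAsFactors = FALSE)
  names(ids) <- c("id_a", "id_b")
  scores <- vapply(models, function(m) predict(m, graphs)$score_pos,
                   numeric(length(graphs)))
  scores <- matrix(scores, nrow = length(graphs))
  votes <- rowSums(scores > 0.5)
  out <- data.frame(ids,
                    sum_positive_score = rowSums(scores),
                    predicted_label = as.integer(votes > length(models) / 2),
                    positive_votes = votes)
  colnames(scores) <- sprintf("member%d_score", seq_along(models))
  out <- cbind(out, scores)
  out <- out[order(-out$sum_positive_score), , drop = FALSE]  # stable on ties
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("rank", setdiff(names(out), "rank"))]
}
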