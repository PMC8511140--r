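# Transfer learning: weight transfer with re-initialization of the last
# two dense layers, full-network finetuning on a small domain-shifted
# dataset, and loss-based selection of the finetuned ensemble.

#' Transfer pretrained weights into a fresh model
#'
#' Copies every layer of the pretrained model -- message-passing blocks,
#' attention heads and all dense layers except the final two -- and
#' re-initializes exactly the last two dense layers from the given seed.
#' Nothing is frozen: finetuning afterwards updates all weights.
#'
#' @param pretrained A trained `ccgnet_model`.
#' @param seed Seed for the re-initialized layers.
#' @return A `ccgnet_model` with transferred weights (untrained head tail),
#'   carrying the pretrained model's config and feature scaler.
#' @export
transfer_weights <- function(pretrained, seed = 1L) {
  stopifnot(inherits(pretrained, "ccgnet_model"))
  cfg <- pretrained$config
  n_dense <- length(cfg$dense_widths) + 1L
  if (n_dense < 2) stop("transfer error: head has fewer than two dense layers")
  params <- pretrained$params
  fresh <- ccgnet_init(cfg, seed = seed)
  for (d in c(n_dense - 1L, n_dense)) {
    params[[sprintf("head_W%d", d)]] <- fresh[[sprintf("head_W%d", d)]]
    params[[sprintf("head_b%d", d)]] <- fresh[[sprintf("head_b%d", d)]]
  }
  out <- pretrained
  out$params <- params
  out$history <- numeric()
  out$seed <- as.integer(seed)
  out$transfer_from <- pretrained$seed
  out
}

#' Continue training an existing model
#'
#' Runs further Adam steps from the model's current weights (used for
#' finetuning after [transfer_weights()]).  The pretrained feature scaler
#' is kept, so inputs are standardized exactly as during pretraining.
#'
#' @param model A `ccgnet_model`.
#' @param graphs Labeled `ccgraph` training samples.
#' @param epochs,batch_size,lr,weight_decay,dropout Optimizer settings
#'   (finetuning defaults to a reduced learning rate).
#' @param seed Shuffling seed.
#' @param augment Apply order-swap augmentation.
#' @return The updated `ccgnet_model`.
#' @export
finetune_model <- function(model, graphs, epochs = 15L, batch_size = 16L,
                           lr = 1e-4, seed = 1L, augment = TRUE,
                           weight_decay = 1e-3, dropout = 0) {
  train_set <- if (augment) augment_pairs(graphs) else graphs
  y <- graph_labels(train_set)
  samples <- graphs_to_samples(train_set, model$config, model$scaler)
  fit <- ccg_train_cpp(samples, y, model$params, as.integer(epochs),
                       as.integer(batch_size), lr, as.integer(seed),
                       weight_decay, dropout)
  model$params <- fit$params
  model$history <- c(model$history, as.numeric(fit$history))
  model
}

#' Finetune an ensemble from pretrained models with loss-based selection
#'
#' Every pretrained model is finetuned once per fold of a k-fold random
#' cross-validation of the small target dataset (all weights trainable, the
#' last two dense layers freshly initialized), giving
#' `length(pretrained) * folds` candidate models.  The `select` candidates
#' with the lowest validation loss become the ensemble; equal losses are
#' tie-broken by (pretrained index, fold index) order, and the selection is
#' a pure function of the recorded losses.
#'
#' @param pretrained List of trained `ccgnet_model` objects.
#' @param graphs Labeled `ccgraph` samples of the target domain.
#' @param folds Fold count for the finetuning cross-validation (default 5).
#' @param select Ensemble size to keep (default 10).
#' @param epochs,batch_size,lr Finetuning settings.
#' @param seed Integer seed for folds, re-initialization and shuffling.
#' @return List with `ensemble` (selected models), `candidates` (data frame
#'   of pretrained index, fold, validation loss, selection flag) and
#'   `folds`.
#' @export
finetune_ensemble <- function(pretrained, graphs, folds = 5L, select = 10L,
                              epochs = 15L, batch_size = 16L, lr = 1e-4,
                              seed = 1L) {
  n_cand <- length(pretrained) * folds
  if (n_cand < select) {
    stop("selection error: ", n_cand, " candidates < ensemble size ", select,
         call. = FALSE)
  }
  y <- graph_labels(graphs)
  fold_of <- stratified_kfold(y, k = folds, seed = seed)
  cand_models <- vector("list", n_cand)
  tab <- data.frame(pretrained = integer(n_cand), fold = integer(n_cand),
                    val_loss = numeric(n_cand))
  r <- 0L
  for (i in seq_along(pretrained)) {
    for (j in seq_len(folds)) {
      r <- r + 1L
      sub_seed <- as.integer(seed + 131L * i + j)
      m0 <- transfer_weights(pretrained[[i]], seed = sub_seed)
      mf <- finetune_model(m0, graphs[fold_of != j], epochs = epochs,
                           batch_size = batch_size, lr = lr, seed = sub_seed)
      cand_models[[r]] <- mf
      tab$pretrained[r] <- i
      tab$fold[r] <- j
      tab$val_loss[r] <- validation_loss(mf, graphs[fold_of == j])
    }
  }
  picked <- select_by_loss(tab, select)
  tab$selected <- seq_len(n_cand) %in% picked
  list(ensemble = cand_models[picked], candidates = tab, folds = fold_of)
}

# Pure selection rule: lowest validation loss, ties by (pretrained, fold).
select_by_loss <- function(candidates, select) {
  ord <- order(candidates$val_loss, candidates$pretrained, candidates$fold)
  ord[seq_len(select)]
}

#' Domain-shift transfer benchmark on synthetic families
#'
#' Builds a small domain-shifted coformer family (different molecule
#' library, altered planted-rule weights), then compares (i) the pretrained
#' ensemble applied directly and (ii) the finetuned ensemble from
#' [finetune_ensemble()], both evaluated on a held-out test split of the
#' shifted family.
#'
#' @param seed Integer seed for the shifted family and finetuning.
#' @param pretrained List of models pretrained on the base family (for
#'   example the fold models of [cross_validate()]).  May be reused across
#'   seeds.
#' @param n_finetune,n_test Shifted-family sizes for finetuning and testing.
#' @param folds,select,epochs,lr Passed to [finetune_ensemble()].
#' @param library_n Size of the shifted molecule library.
#' @return List with `direct` and `finetuned` metrics (`ccg_metrics`),
#'   `candidates` (per-member validation losses for audit) and sizes.
#' @export
domain_shift_benchmark <- function(seed, pretrained, n_finetune = 240L,
                                   n_test = 120L, folds = 5L, select = 10L,
                                   epochs = 15L, lr = 1e-4,
                                   library_n = 40L) {
  lib <- molecule_library(library_n, seed = seed + 1000L)
  rule <- shifted_rule()
  pairs <- planted_pairs(lib, n_finetune + n_test, rule = rule, seed = seed)
  graphs <- pairs_to_graphs(pairs)
  set.seed(seed)
  test_idx <- sample.int(length(graphs), n_test)
  test <- graphs[test_idx]
  fit_set <- graphs[-test_idx]
  y_test <- graph_labels(test)

  eval_ens <- function(models) {
    votes <- rowSums(vapply(models, function(m) predict(m, test)$label,
                            integer(length(test))))
    compute_metrics(y_test, as.integer(votes > length(models) / 2))
  }
  direct <- eval_ens(pretrained)
  ft <- finetune_ensemble(pretrained, fit_set, folds = folds, select = select,
                          epochs = epochs, lr = lr, seed = seed)
  finetuned <- eval_ens(ft$ensemble)
  list(direct = direct, finetuned = finetuned, candidates = ft$candidates,
       n_finetune = length(fit_set), n_test = n_test)
}
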