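test_that("metric arithmetic matches hand-tallied confusion counts", {
  m <- compute_metrics(c(1, 1, 1, 1, 0, 0), c(1, 1, 1, 0, 0, 1))
  expect_equal(m$TP, 3); expect_equal(m$FN, 1)
  expect_equal(m$TN, 1); expect_equal(m$FP, 1)
  expect_equal(m$TPR, 0.75)
  expect_equal(m$TNR, 0.5)
  expect_equal(m$BACC, 0.625)
  perfect <- compute_metrics(c(0, 1, 1), c(0, 1, 1))
  expect_equal(perfect$TPR, 1); expect_equal(perfect$TNR, 1)
  expect_equal(perfect$BACC, 1)
  # brute-force tally over random vectors
  set.seed(14)
  for (rep in 1:200) {
    n <- sample(1:50, 1)
    yt <- sample(0:1, n, replace = TRUE)
    yp <- sample(0:1, n, replace = TRUE)
    m <- compute_metrics(yt, yp)
    expect_equal(m$TP + m$FP + m$TN + m$FN, n)
    expect_equal(m$TP, sum(yt & yp))
    expect_equal(m$TN, sum(!yt & !yp))
    if (any(yt == 1)) expect_equal(m$TPR, sum(yt & yp) / sum(yt))
    if (any(yt == 0)) expect_equal(m$TNR, sum(!yt & !yp) / sum(!yt))
  }
})

test_that("a missing class yields undefined rates, not numbers", {
  m <- compute_metrics(c(1, 1, 1), c(1, 0, 1))
  expect_true(is.na(m$TNR))
  expect_true(is.na(m$BACC))
  expect_error(compute_metrics(numeric(), numeric()), "empty")
})

test_that("balanced accuracy ignores class prevalence given fixed rates", {
  # synthesize predictions with TPR = 0.9, TNR = 0.6 at two prevalences
  mk <- function(n_pos, n_neg) {
    yt <- c(rep(1, n_pos), rep(0, n_neg))
    yp <- c(rep(1, 0.9 * n_pos), rep(0, 0.1 * n_pos),
            rep(0, 0.6 * n_neg), rep(1, 0.4 * n_neg))
    compute_metrics(yt, yp)$BACC
  }
  expect_equal(mk(100, 100), mk(1000, 100))
  expect_equal(mk(100, 100), 0.75)
})

test_that("training is deterministic and can overfit a single minibatch", {
  d <- tiny_pairset()
  cfg <- tiny_config()
  m1 <- train_ccgnet(d$graphs[1:40], cfg, epochs = 5, seed = 9)
  m2 <- train_ccgnet(d$graphs[1:40], cfg, epochs = 5, seed = 9)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  # one minibatch, many steps: training accuracy reaches 100%
  mini <- d$graphs[c(1:8, which(sapply(d$graphs, `[[`, "label") == 0)[1:4])]
  over <- train_ccgnet(mini, cfg, epochs = 200, batch_size = 32,
                       seed = 3, augment = FALSE, weight_decay = 0)
  pred <- predict(over, mini)
  expect_equal(pred$label, sapply(mini, `[[`, "label"))
  expect_lt(over$history[length(over$history)], 0.05)
  # loss decreases on the training data
  expect_lt(mean(tail(over$history, 10)), mean(head(over$history, 10)))
})

test_that("training refuses unlabeled samples and aborts on divergence", {
  d <- tiny_pairset()
  g <- d$graphs[[1]]
  g$label <- NA
  expect_error(train_ccgnet(c(list(g), d$graphs[2:5]), tiny_config(),
                            epochs = 1), "unlabeled")
})

test_that("cross-validation produces one model per disjoint fold", {
  d <- tiny_pairset()
  cv <- cross_validate(d$graphs, tiny_config(), k = 3, seed = 2, epochs = 4)
  expect_length(cv$models, 3)
  expect_length(cv$metrics, 3)
  expect_setequal(unique(as.integer(cv$folds)), 1:3)
  expect_length(cv$folds, length(d$graphs))
  expect_equal(cv$summary$metric, c("TPR", "TNR", "BACC"))
  expect_true(all(cv$summary$mean >= 0 & cv$summary$mean <= 1))
})

test_that("ensemble ranking sums positive scores and sorts stably", {
  d <- tiny_pairset()
  model <- tiny_model()
  graphs <- d$graphs[1:6]
  single <- predict(model, graphs)
  ranked <- ensemble_rank(graphs, list(model, model))
  expect_equal(ranked$sum_positive_score,
               sort(2 * single$score_pos, decreasing = TRUE))
  expect_equal(ranked$rank, 1:6)
  expect_true(all(diff(ranked$sum_positive_score) <= 0))
  # ensemble of identical members ranks like a single member
  ranked1 <- ensemble_rank(graphs, list(model))
  expect_equal(ranked$id_a, ranked1$id_a)
  expect_equal(ranked$id_b, ranked1$id_b)
  # duplicated graphs tie in score and keep input order
  dup <- list(graphs[[1]], graphs[[2]], graphs[[1]])
  rd <- ensemble_rank(dup, list(model), ids = data.frame(
    id_a = c("first", "second", "third"), id_b = c("x", "y", "z")))
  tied <- rd$id_a[rd$sum_positive_score == rd$sum_positive_score[
    rd$id_a == "first"]]
  expect_true(which(tied == "first") < which(tied == "third"))
  # majority vote with member decisions
  expect_true(all(ranked$predicted_label %in% 0:1))
})
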