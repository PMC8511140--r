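test_that("screening rules reject what the curation conditions forbid", {
  rules <- fixture("rules", screening_rules)
  heavy <- paste(rep("C", 50), collapse = "")       # C50 alkane, MW > 700
  expect_true("mw_max" %in% screen_pair(heavy, "c1ccncc1", rules)$reasons)
  expect_true("allowed_elements" %in%
                screen_pair("[Fe]", "c1ccncc1", rules)$reasons)
  expect_true("require_neutral" %in%
                screen_pair("CC(=O)[O-]", "c1ccncc1", rules)$reasons)
  expect_true("require_two_components" %in%
                screen_pair("c1ccncc1", "c1ccncc1", rules)$reasons)
  res <- screen_pair("c1ccccc1", "c1ccncc1", rules)
  # outcome must agree with the packaged solvent list
  benzene_listed <- canonical_smiles("c1ccccc1") %in% rules$solvent_blacklist
  expect_identical("solvent_blacklist" %in% res$reasons, benzene_listed)
  ok <- screen_pair("NC(=O)c1cccnc1", "Oc1ccc(C(=O)O)cc1", rules)
  expect_true(ok$accepted)
  expect_length(ok$reasons, 0)
})

test_that("pairing builds a block-diagonal disjoint union with a 2x12 state", {
  mols <- test_mols()
  g <- pair_graph(mols$benzene, mols$pyridine, label = 1)
  expect_equal(nrow(g$V), 12 + 11)
  expect_equal(dim(g$U), c(2, 12))
  expect_identical(rownames(g$U), c("a", "b"))
  expect_equal(g$U[1, ], compute_descriptors(mols$benzene),
               ignore_attr = TRUE)
  # no cross-coformer edges in any slice
  expect_equal(sum(g$A[g$slices$a, g$slices$b, ]), 0)
  expect_equal(sum(g$A[g$slices$b, g$slices$a, ]), 0)
  expect_error(
    make_ccgraph(list(V = matrix(0, 2, 5), A = array(0, c(2, 2, 4))), 1:12,
                 list(V = matrix(0, 2, 6), A = array(0, c(2, 2, 4))), 1:12),
    "layout")
})

test_that("order-swap augmentation doubles the set with consistent twins", {
  set.seed(1)
  graphs <- lapply(1:3, function(i) random_ccgraph())
  aug <- augment_pairs(graphs)
  expect_length(aug, 6)
  for (i in 1:3) {
    orig <- aug[[2 * i - 1]]; twin <- aug[[2 * i]]
    expect_identical(attr(twin, "twin_of"), i)
    expect_identical(twin$U, orig$U[c(2, 1), ], ignore_attr = TRUE)
    expect_identical(twin$label, orig$label)
    perm <- c(orig$slices$b, orig$slices$a)
    expect_identical(twin$V, orig$V[perm, ])
    expect_identical(twin$A, orig$A[perm, perm, ])
  }
  # doubling twice gives each sample four times
  expect_length(augment_pairs(aug), 12)
})

test_that("stratified folds partition samples with exact class balance", {
  labels <- c(rep(1, 80), rep(0, 20))
  folds <- stratified_kfold(labels, 10, seed = 4)
  expect_length(folds, 100)
  for (f in 1:10) {
    expect_equal(sum(labels[folds == f] == 1), 8)
    expect_equal(sum(labels[folds == f] == 0), 2)
  }
  expect_identical(as.integer(folds),
                   as.integer(stratified_kfold(labels, 10, seed = 4)))
  expect_error(stratified_kfold(c(rep(1, 50), 0, 0), 5), "stratification")
  # fold-then-augment keeps twins on one side of every split
  graphs <- lapply(seq_along(labels), function(i) random_ccgraph(label = labels[i]))
  aug <- augment_pairs(graphs)
  aug_fold <- rep(folds, each = 2)
  for (i in seq_along(aug)) {
    tw <- attr(aug[[i]], "twin_of")
    if (!is.null(tw)) expect_equal(aug_fold[i], folds[tw])
  }
})

test_that("batch padding is masked, zero-filled and lossless", {
  set.seed(2)
  graphs <- list(random_ccgraph(3, 2), random_ccgraph(4, 4))
  batch <- pad_batch(graphs, n_max = 8L)
  expect_equal(dim(batch$V), c(2, 8, atom_feature_width()))
  expect_equal(rowSums(batch$mask), c(5, 8))
  expect_true(all(batch$V[1, 6:8, ] == 0))
  back <- unpad_batch(batch)
  for (i in 1:2) {
    expect_equal(back[[i]]$V, graphs[[i]]$V)
    expect_equal(back[[i]]$A, graphs[[i]]$A, ignore_attr = TRUE)
    expect_equal(back[[i]]$U, graphs[[i]]$U, ignore_attr = TRUE)
    expect_equal(back[[i]]$slices, graphs[[i]]$slices)
  }
  expect_error(pad_batch(graphs, n_max = 6L), "capacity")
})
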