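test_that("parsing adds explicit hydrogens and perceives bonds", {
  mols <- test_mols()
  expect_equal(nrow(mols$ethanol$atoms), 9)    # 3 heavy + 6 H
  expect_equal(nrow(mols$ethanol$bonds), 8)
  expect_equal(nrow(mols$benzene$atoms), 12)
  types <- table(mols$benzene$bonds$type)
  expect_equal(unname(types[["aromatic"]]), 6)
  expect_equal(unname(types[["single"]]), 6)   # the six C-H bonds
})

test_that("conformer generation is deterministic given the seed", {
  a <- read_molecule("CCO", seed = 99L)
  b <- read_molecule("CCO", seed = 99L)
  expect_identical(a$coords, b$coords)
})

test_that("featurization errors name the failure", {
  expect_error(read_molecule("xx("), "parse error")
  expect_error(read_molecule("[Fe]"), "element error")
  expect_error(read_molecule("CCO.O"), "connected")
})

test_that("atom features follow the fixed layout", {
  mols <- test_mols()
  ring_c <- which(mols$benzene$atoms$symbol == "C")[1]
  f <- atom_features(mols$benzene, ring_c)
  expect_equal(unname(f["type_C"]), 1)
  expect_equal(sum(f[paste0("type_", ccgnet:::CCG_ATOM_TYPES)]), 1)
  expect_equal(unname(f["hyb_SP2"]), 1)
  expect_equal(unname(f["is_aromatic"]), 1)
  expect_equal(unname(f["is_cyclic"]), 1)
  expect_equal(unname(f["degree"]), 3)
  expect_equal(unname(f["total_h"]), 1)
  expect_equal(unname(f["formal_charge"]), 0)

  h_idx <- which(mols$methane$atoms$symbol == "H")[1]
  fh <- atom_features(mols$methane, h_idx)
  expect_equal(unname(fh["type_H"]), 1)
  expect_equal(unname(fh["degree"]), 1)
  expect_equal(unname(fh["is_aromatic"]), 0)
  expect_equal(unname(fh["total_h"]), 0)

  spiro_flags <- mols$spiro$atoms$is_spiro
  expect_equal(sum(spiro_flags), 1)            # exactly the shared atom
  expect_equal(mols$spiro$atoms$is_cyclic[spiro_flags == 1], 1)
})

test_that("atom-type one-hot is exactly one bit for every atom", {
  for (mol in test_mols()) {
    V <- atom_feature_matrix(mol)
    expect_true(all(rowSums(V[, 1:11, drop = FALSE]) == 1))
    expect_true(all(rowSums(V[, 12:15, drop = FALSE]) <= 1))
  }
})

test_that("bond-type adjacency slices are symmetric, exclusive and complete", {
  mols <- test_mols()
  A <- bond_adjacency_tensor(mols$ethane)
  expect_equal(sum(A[, , "single"] != 0), 14)  # 7 bonds, both directions
  expect_equal(sum(A[, , c("double", "triple", "aromatic")]), 0)
  for (mol in mols) {
    A <- bond_adjacency_tensor(mol)
    for (l in 1:4) {
      expect_identical(A[, , l], t(A[, , l]))
      expect_true(all(diag(A[, , l]) == 0))
    }
    # at most one slice per atom pair, and slice-sum == plain adjacency
    counts <- apply(A, c(1, 2), sum)
    expect_true(all(counts <= 1))
    expect_equal(sum(counts) / 2, nrow(mol$bonds))
  }
})

test_that("box axes are ordered, rotation-invariant and flag degeneracy", {
  two <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  expect_warning(ext <- box_axes(two), "degenerate")
  expect_equal(unname(ext[["L"]]), 1)
  expect_equal(unname(ext[["S"]]), 0)
  expect_equal(unname(ext[["M"]]), 0)
  expect_true(attr(ext, "degenerate"))

  coords <- test_mols()$phenol$coords
  theta <- 0.7
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  rotated <- coords %*% R + matrix(rep(c(5, -2, 1), each = nrow(coords)), ncol = 3)
  expect_equal(as.numeric(box_axes(coords)), as.numeric(box_axes(rotated)),
               tolerance = 1e-6)

  ext_methane <- box_axes(test_mols()$methane$coords)
  expect_gte(ext_methane[["S"]] / ext_methane[["L"]], 0.8)
})

test_that("descriptors match hand counts and stay in bounds", {
  mols <- test_mols()
  expect_equal(unname(compute_descriptors(mols$benzene)[["Fr_NO"]]), 0)
  expect_equal(unname(compute_descriptors(mols$benzene)[["Fr_AromaticAtoms"]]), 1)
  expect_equal(unname(compute_descriptors(mols$pyridine)[["Fr_NO"]]), 1 / 6,
               tolerance = 1e-12)
  expect_equal(unname(compute_descriptors(mols$butane)[["RBN"]]), 1)
  d_phenol <- compute_descriptors(mols$phenol)
  expect_equal(unname(d_phenol[["HBD"]]), 1)
  expect_lt(d_phenol[["Globularity"]], 1)

  for (mol in mols) {
    d <- compute_descriptors(mol)
    expect_true(all(is.finite(d)))
    expect_true(d[["S_L"]] <= d[["S_M"]] + 1e-12)   # S/L <= S/M since M <= L
    expect_true(all(d[c("S_L", "S_M", "M_L")] >= 0 &
                    d[c("S_L", "S_M", "M_L")] <= 1 + 1e-12))
    expect_true(d[["Globularity"]] >= 0 && d[["Globularity"]] <= 1)
    expect_true(d[["Fr_NO"]] >= 0 && d[["Fr_NO"]] <= 1)
    expect_true(d[["Fr_AromaticAtoms"]] >= 0 && d[["Fr_AromaticAtoms"]] <= 1)
    expect_gte(d[["FrTPSA"]], 0)
    expect_true(all(d[c("HBA", "HBD", "RBN")] >= 0))
  }
})

test_that("2D descriptors are conformer-independent, 3D ones rigid-invariant", {
  d1 <- compute_descriptors(read_molecule("NC(=O)c1cccnc1", seed = 11L))
  d2 <- compute_descriptors(read_molecule("NC(=O)c1cccnc1", seed = 12L))
  flat <- c("Fr_NO", "Fr_AromaticAtoms", "HBA", "HBD", "RBN")
  expect_identical(d1[flat], d2[flat])
})
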