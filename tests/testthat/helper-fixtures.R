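# Shared, lazily-built fixtures.  Molecule featurization goes through one
# backend process per batch and is memoised by the package, so these
# helpers keep the suite's subprocess count low.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Common single molecules used across featurization tests.
test_mols <- function() {
  fixture("mols", function() {
    read_molecules(c(ethanol = "CCO", benzene = "c1ccccc1",
                     pyridine = "c1ccncc1", butane = "CCCC",
                     phenol = "Oc1ccccc1", methane = "C", ethane = "CC",
                     spiro = "C1CCC2(CC1)CCCC2", methanol = "CO",
                     nicotinamide = "NC(=O)c1cccnc1",
                     paracetamol = "CC(=O)Nc1ccc(O)cc1"),
                   seed = 2024L)
  })
}

# Small labeled pair set for fast training-path tests (independent of the
# benchmark-scale study set).
tiny_pairset <- function() {
  fixture("tiny_pairs", function() {
    lib <- molecule_library(24, seed = 3)
    pairs <- planted_pairs(lib, 80, seed = 3)
    list(lib = lib, pairs = pairs, graphs = pairs_to_graphs(pairs))
  })
}

tiny_config <- function() {
  ccgnet_config(conv_widths = c(8L, 8L), global_widths = c(8L, 8L),
                n_heads = 2L, att_hidden = 8L, dense_widths = c(16L))
}

# One small trained model, reused by checkpoint/report/attention tests.
tiny_model <- function() {
  fixture("tiny_model", function() {
    d <- tiny_pairset()
    train_ccgnet(d$graphs, tiny_config(), epochs = 15, seed = 5)
  })
}

# The benchmark-scale study set (library of 120, 600 pairs, default rule);
# shared between the synthetic-data tests and the acceptance suite.
study_library <- function() {
  fixture("study_library", function() molecule_library(120, seed = 7))
}

study_set <- function(seed = 1L) {
  key <- paste0("study_set_", seed)
  fixture(key, function() {
    pairs <- planted_pairs(study_library(), 600, seed = seed)
    list(pairs = pairs, graphs = pairs_to_graphs(pairs))
  })
}
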