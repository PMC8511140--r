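# Pairing two coformers into one sample, dataset screening, order-swap
# augmentation, stratified fold assignment and batch padding.

#' Dataset screening rules
#'
#' The curation conditions applied to candidate coformer pairs: a blacklist
#' of common solvents / small molecules that are liquid or gaseous at room
#' temperature (shipped as a packaged SMILES list and canonicalized once at
#' load), an element whitelist that rules out metals, a per-component
#' molecular-weight cap of 700, neutrality of each component (excludes
#' salts), and the requirement that the two components be chemically
#' different.
#'
#' @param blacklist_path Path to a SMILES file (one entry per line, optional
#'   tab-separated name); defaults to the packaged solvent list.
#' @param allowed_elements Character vector of permitted element symbols.
#' @param mw_max Maximum molecular weight per component.
#' @param require_neutral Require each component's net formal charge to be 0.
#' @param require_two_components Require two chemically different molecules.
#' @return A `ccg_screening_rules` list.
#' @export
screening_rules <- function(blacklist_path = NULL,
                            allowed_elements = c("C", "H", "O", "N", "P", "S",
                                                 "Cl", "Br", "I", "F", "Si"),
                            mw_max = 700,
                            require_neutral = TRUE,
                            require_two_components = TRUE) {
  if (is.null(blacklist_path)) {
    blacklist_path <- system.file("extdata", "solvent_blacklist.smi",
                                  package = "ccgnet")
  }
  lines <- readLines(blacklist_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  smis <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1)
  blk <- unique(stats::na.omit(canonical_smiles(smis)))
  structure(list(solvent_blacklist = blk,
                 allowed_elements = allowed_elements,
                 mw_max = mw_max,
                 require_neutral = require_neutral,
                 require_two_components = require_two_components),
            class = "ccg_screening_rules")
}

mol_facts <- function(x) {
  if (inherits(x, "ccg_molecule")) {
    list(ok = TRUE,
         canonical_smiles = x$canonical_smiles,
         mw = x$mw, net_charge = x$net_charge,
         elements = unique(x$atoms$symbol))
  } else {
    stopifnot(is.character(x), length(x) == 1)
    inspect_smiles(x)[[1]]
  }
}

#' Screen a coformer pair against the dataset rules
#'
#' Violations are reported, not raised: the result lists every rule the pair
#' fails by name.
#'
#' @param a,b The two coformers, each a `ccg_molecule` or a SMILES string.
#' @param rules A [screening_rules()] object.
#' @return List with `accepted` (logical) and `reasons` (character vector of
#'   violated rule names, empty when accepted).
#' @export
screen_pair <- function(a, b, rules = screening_rules()) {
  fa <- mol_facts(a)
  fb <- mol_facts(b)
  reasons <- character()
  if (!isTRUE(fa$ok) || !isTRUE(fb$ok)) {
    return(list(accepted = FALSE, reasons = "parse_error"))
  }
  els <- unique(c(fa$elements, fb$elements))
  if (!all(els %in% rules$allowed_elements)) reasons <- c(reasons, "allowed_elements")
  if (max(fa$mw, fb$mw) >= rules$mw_max) reasons <- c(reasons, "mw_max")
  if (rules$require_neutral && (fa$net_charge != 0 || fb$net_charge != 0)) {
    reasons <- c(reasons, "require_neutral")
  }
  if (rules$require_two_components &&
      identical(fa$canonical_smiles, fb$canonical_smiles)) {
    reasons <- c(reasons, "require_two_components")
  }
  if (fa$canonical_smiles %in% rules$solvent_blacklist ||
      fb$canonical_smiles %in% rules$solvent_blacklist) {
    reasons <- c(reasons, "solvent_blacklist")
  }
  list(accepted = length(reasons) == 0, reasons = reasons)
}

#' Assemble a co-crystal graph sample
#'
#' The two coformer graphs form a disjoint union: stacked vertex matrices
#' and a block-diagonal adjacency tensor with no cross-coformer edges (the
#' covalent-bond-only edge representation).  The two descriptor vectors form
#' the 2 x 12 global-state matrix, row order matching coformer order.
#'
#' @param a_graph,b_graph `ccg_molgraph` objects (or lists with `V`, `A`).
#' @param a_desc,b_desc Numeric descriptor vectors of length 12.
#' @param label 0, 1 or `NA` (unlabeled).
#' @param ids Optional character vector of length 2 naming the coformers.
#' @return A `ccgraph` object: `V` ((n+m) x C), `A` ((n+m) x (n+m) x 4),
#'   `U` (2 x 12), `slices` (per-coformer atom index ranges), `label`, `ids`.
#' @export
make_ccgraph <- function(a_graph, a_desc, b_graph, b_desc, label = NA,
                         ids = c("a", "b")) {
  if (ncol(a_graph$V) != ncol(b_graph$V)) {
    stop("layout error: coformer feature widths differ", call. = FALSE)
  }
  n <- nrow(a_graph$V); m <- nrow(b_graph$V)
  L <- dim(a_graph$A)[3]
  V <- rbind(a_graph$V, b_graph$V)
  A <- array(0, dim = c(n + m, n + m, L), dimnames = dimnames(a_graph$A))
  A[seq_len(n), seq_len(n), ] <- a_graph$A
  A[n + seq_len(m), n + seq_len(m), ] <- b_graph$A
  U <- rbind(a = as.numeric(a_desc), b = as.numeric(b_desc))
  colnames(U) <- CCG_DESCRIPTOR_NAMES
  structure(list(V = V, A = A, U = U,
                 slices = list(a = seq_len(n), b = n + seq_len(m)),
                 label = label, ids = ids),
            class = "ccgraph")
}

#' Build a co-crystal graph straight from two molecules
#' @param a,b `ccg_molecule` objects.
#' @inheritParams make_ccgraph
#' @return A `ccgraph`.
#' @export
pair_graph <- function(a, b, label = NA) {
  make_ccgraph(molecular_graph(a), compute_descriptors(a),
               molecular_graph(b), compute_descriptors(b),
               label = label,
               ids = c(a$canonical_smiles, b$canonical_smiles))
}

#' @export
print.ccgraph <- function(x, ...) {
  cat("<ccgraph> ", length(x$slices$a), "+", length(x$slices$b), " atoms, label ",
      x$label, "\n", sep = "")
  invisible(x)
}

# Order-swapped twin of one sample.
swap_ccgraph <- function(g) {
  n <- length(g$slices$a); m <- length(g$slices$b)
  perm <- c(g$slices$b, g$slices$a)
  out <- g
  out$V <- g$V[perm, , drop = FALSE]
  out$A <- g$A[perm, perm, , drop = FALSE]
  out$U <- g$U[c(2, 1), , drop = FALSE]
  rownames(out$U) <- c("a", "b")
  out$slices <- list(a = seq_len(m), b = m + seq_len(n))
  out$ids <- rev(g$ids)
  out
}

#' Order-swap data augmentation
#'
#' Doubles a labeled sample list by appending, after each sample, its
#' coformer-order-swapped twin with the same label.  Twin linkage is
#' recorded (`twin_of` attribute per element) so fold assignment can keep a
#' sample and its twin on the same side of every train/validation split.
#'
#' @param samples List of `ccgraph` objects.
#' @return List of length `2 * length(samples)`.
#' @export
augment_pairs <- function(samples) {
  out <- vector("list", 2 * length(samples))
  for (i in seq_along(samples)) {
    tw <- swap_ccgraph(samples[[i]])
    attr(tw, "twin_of") <- i
    out[[2 * i - 1]] <- samples[[i]]
    out[[2 * i]] <- tw
  }
  out
}

#' Stratified k-fold assignment
#'
#' Assigns pre-augmentation samples to k folds with per-fold class
#' proportions matching the global ones as closely as counts allow
#' (round-robin dealing within each class after a seeded shuffle).
#' Augmentation twins inherit their original's fold by construction, since
#' folds are assigned before augmentation.
#'
#' @param labels Binary vector (0/1) of sample labels.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; the same seed always yields the same folds.
#' @return Object of class `ccg_folds`: integer fold index per sample, with
#'   `k` and `seed` attributes.
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  stopifnot(k >= 2, all(labels %in% c(0, 1)), length(labels) >= k)
  counts <- table(factor(labels, levels = c(0, 1)))
  if (min(counts) < k) {
    stop("stratification error: fewer minority-class samples (", min(counts),
         ") than folds (", k, ")", call. = FALSE)
  }
  fold <- integer(length(labels))
  set.seed(seed)
  for (cls in c(0, 1)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  structure(fold, k = k, seed = seed, class = "ccg_folds")
}

#' Pad a list of co-crystal graphs into fixed-size batch tensors
#'
#' Vertex matrices are padded with zero rows and adjacency tensors with zero
#' rows/columns up to `n_max`; a node mask marks real atoms.  Downstream
#' attention pooling ignores masked nodes, so predictions are invariant to
#' the padding width.
#'
#' @param graphs List of `ccgraph` objects, each with at most `n_max` nodes.
#' @param n_max Padded node count (default: 160).
#' @return List of batch arrays: `V` (B x n_max x C), `A` (B x n_max x n_max
#'   x 4), `U` (B x 2 x 12), `mask` (B x n_max), `n1` (atoms in coformer 1),
#'   `n` (true node counts), `labels`.
#' @export
pad_batch <- function(graphs, n_max = 160L) {
  sizes <- vapply(graphs, function(g) nrow(g$V), integer(1))
  if (any(sizes > n_max)) {
    stop("capacity error: graph with ", max(sizes), " nodes exceeds n_max = ",
         n_max, call. = FALSE)
  }
  B <- length(graphs)
  C <- ncol(graphs[[1]]$V)
  L <- dim(graphs[[1]]$A)[3]
  V <- array(0, c(B, n_max, C))
  A <- array(0, c(B, n_max, n_max, L))
  U <- array(0, c(B, 2, ncol(graphs[[1]]$U)))
  mask <- matrix(0, B, n_max)
  for (b in seq_len(B)) {
    g <- graphs[[b]]
    n <- sizes[b]
    V[b, seq_len(n), ] <- g$V
    A[b, seq_len(n), seq_len(n), ] <- g$A
    U[b, , ] <- g$U
    mask[b, seq_len(n)] <- 1
  }
  list(V = V, A = A, U = U, mask = mask,
       n1 = vapply(graphs, function(g) length(g$slices$a), integer(1)),
       n = sizes,
       labels = vapply(graphs, function(g) as.numeric(g$label), numeric(1)))
}

#' Recover the original graphs from a padded batch
#' @param batch Result of [pad_batch()].
#' @return List of `ccgraph` objects equal to the padded input.
#' @export
unpad_batch <- function(batch) {
  lapply(seq_along(batch$n), function(b) {
    n <- batch$n[b]
    n1 <- batch$n1[b]
    structure(list(
      V = matrix(batch$V[b, seq_len(n), ], nrow = n),
      A = array(batch$A[b, seq_len(n), seq_len(n), ],
                dim = c(n, n, dim(batch$A)[4]),
                dimnames = list(NULL, NULL, CCG_BOND_TYPES)),
      U = matrix(batch$U[b, , ], nrow = 2,
                 dimnames = list(c("a", "b"), CCG_DESCRIPTOR_NAMES)),
      slices = list(a = seq_len(n1), b = n1 + seq_len(n - n1)),
      label = batch$labels[b], ids = c(NA, NA)
    ), class = "ccgraph")
  })
}
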