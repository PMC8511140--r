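# Featurization: one molecule -> vertex feature matrix, bond-type adjacency
# tensor, and the 12-descriptor global state.

# Frozen atom-feature column layout (version 1).  Checkpoints record this
# version; changing the layout invalidates them.
CCG_LAYOUT_VERSION <- "ccg-atom-layout-1"

CCG_ATOM_TYPES <- c("Cl", "N", "P", "Br", "B", "S", "I", "F", "C", "O", "H")
CCG_HYBRIDIZATIONS <- c("SP2", "SP3", "SP", "S")
CCG_CHIRALITY <- c("None", "R", "S")
CCG_BOND_TYPES <- c("single", "double", "triple", "aromatic")

CCG_FEATURE_NAMES <- c(
  paste0("type_", CCG_ATOM_TYPES),
  paste0("hyb_", CCG_HYBRIDIZATIONS),
  paste0("chir_", CCG_CHIRALITY),
  "is_chiral", "is_spiro", "is_cyclic", "is_aromatic", "is_acceptor",
  "is_donor", "explicit_valence", "implicit_valence", "formal_charge",
  "degree", "total_h", "atomic_number", "vdw_radius")

#' Width of the atom feature vector
#' @return Integer, the fixed number of per-atom feature columns.
#' @export
atom_feature_width <- function() length(CCG_FEATURE_NAMES)

CCG_DESCRIPTOR_NAMES <- c("S", "S_L", "S_M", "M_L", "Globularity", "FrTPSA",
                          "Fr_NO", "Fr_AromaticAtoms", "HBA", "HBD", "RBN",
                          "Dipole_Moment")
# Conformer-independent descriptors vs conformer-derived ones; used by the
# feature-mode ablations (molecular graph alone, graph + 2D, graph + 3D).
CCG_DESC_2D <- c("Fr_NO", "Fr_AromaticAtoms", "HBA", "HBD", "RBN")
CCG_DESC_3D <- setdiff(CCG_DESCRIPTOR_NAMES, CCG_DESC_2D)

#' Read and perceive a molecule
#'
#' Parses a SMILES string or a MOL/SDF V2000 block, adds explicit hydrogens,
#' perceives aromaticity and CIP stereochemistry, and attaches a 3D
#' conformer.  When the input has no coordinates a conformer is generated by
#' seeded distance-geometry embedding followed by force-field relaxation, so
#' the same record and seed always give identical coordinates.
#'
#' @param record A SMILES string, or a MOL/SDF V2000 block (detected by an
#'   embedded newline).
#' @param seed Integer seed for conformer embedding.
#' @param id Optional identifier carried through to reports.
#' @return An object of class `ccg_molecule`: atom table (element, charge,
#'   chirality, hybridization, ring/aromatic/donor/acceptor flags, valences,
#'   Gasteiger charge, van der Waals radius), bond table (i, j, type),
#'   `coords` (N x 3, Angstrom), canonical SMILES, molecular weight, net
#'   charge and scalar properties (TPSA, SASA, molecular volume, rotatable
#'   bond count).
#' @export
read_molecule <- function(record, seed = 2024L, id = NULL) {
  stopifnot(is.character(record), length(record) == 1)
  rec <- if (grepl("\n", record)) list(molblock = record) else list(smiles = record)
  rec$id <- if (is.null(id)) record else id
  mol <- backend_featurize(list(rec), seed = seed)[[1]]
  as_ccg_molecule(mol, seed = seed)
}

#' Read and perceive a batch of molecules
#'
#' Vectorised [read_molecule()]; one backend invocation for all new records.
#'
#' @param smiles Character vector of SMILES (optionally named with ids).
#' @param seed Integer conformer seed shared by the batch.
#' @param strict If `TRUE`, any failing record aborts; otherwise failures are
#'   returned as `NULL` entries with a warning.
#' @return List of `ccg_molecule` objects (NULL where parsing failed and
#'   `strict` is off), named like the input.
#' @export
read_molecules <- function(smiles, seed = 2024L, strict = TRUE) {
  ids <- if (is.null(names(smiles))) smiles else names(smiles)
  recs <- lapply(seq_along(smiles),
                 function(i) list(id = ids[[i]], smiles = smiles[[i]]))
  raw <- backend_featurize(recs, seed = seed)
  out <- vector("list", length(raw))
  names(out) <- ids
  for (i in seq_along(raw)) {
    if (isTRUE(raw[[i]]$ok)) {
      out[[i]] <- as_ccg_molecule(raw[[i]], seed = seed)
    } else if (strict) {
      stop(raw[[i]]$error, " [record ", ids[[i]], "]", call. = FALSE)
    } else {
      warning("skipping record ", ids[[i]], ": ", raw[[i]]$error, call. = FALSE)
    }
  }
  out
}

as_ccg_molecule <- function(mol, seed) {
  if (!isTRUE(mol$ok)) stop(mol$error, call. = FALSE)
  atoms <- as.data.frame(mol$atoms, stringsAsFactors = FALSE)
  bonds <- as.data.frame(mol$bonds, stringsAsFactors = FALSE)
  coords <- matrix(as.numeric(mol$coords), ncol = 3)
  stopifnot(nrow(atoms) >= 2, all(is.finite(coords)),
            all(bonds$i <= nrow(atoms)), all(bonds$j <= nrow(atoms)))
  structure(list(
    atoms = atoms, bonds = bonds, coords = coords,
    source_id = mol$id, canonical_smiles = mol$canonical_smiles,
    mw = mol$mw, net_charge = mol$net_charge,
    props = mol$mol_props, seed = seed
  ), class = "ccg_molecule")
}

#' @export
print.ccg_molecule <- function(x, ...) {
  cat("<ccg_molecule> ", x$canonical_smiles, "\n",
      "  atoms: ", nrow(x$atoms), " (", sum(x$atoms$atomic_number > 1),
      " heavy), bonds: ", nrow(x$bonds), ", MW ", round(x$mw, 2), "\n", sep = "")
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

#' Atom feature vector
#'
#' Builds the fixed-layout numeric feature row for one atom: element one-hot
#' over (Cl, N, P, Br, B, S, I, F, C, O, H), hybridization one-hot
#' (SP2, SP3, SP, S), CIP chirality one-hot, six binary flags (chiral,
#' spiro, cyclic, aromatic, H-bond acceptor, H-bond donor), integer valence /
#' charge / degree / attached-H / atomic-number fields and the van der Waals
#' radius.  Explicit hydrogens are graph nodes, so `degree` counts them and
#' `total_h` is the number of attached hydrogen atoms.
#'
#' @param mol A `ccg_molecule`.
#' @param atom_index 1-based atom index.
#' @return Named numeric vector of length [atom_feature_width()].
#' @export
atom_features <- function(mol, atom_index) {
  stopifnot(inherits(mol, "ccg_molecule"),
            atom_index >= 1, atom_index <= n_atoms(mol))
  a <- mol$atoms[atom_index, ]
  if (!a$symbol %in% CCG_ATOM_TYPES) {
    stop("element error: no atom-type slot for element ", a$symbol, call. = FALSE)
  }
  v <- c(
    as.numeric(CCG_ATOM_TYPES == a$symbol),
    as.numeric(CCG_HYBRIDIZATIONS == a$hybridization),
    as.numeric(CCG_CHIRALITY == a$chirality),
    a$is_chiral, a$is_spiro, a$is_cyclic, a$is_aromatic, a$is_acceptor,
    a$is_donor, a$explicit_valence, a$implicit_valence, a$formal_charge,
    a$degree, a$total_h, a$atomic_number, a$vdw_radius)
  names(v) <- CCG_FEATURE_NAMES
  v
}

#' Vertex feature matrix of a molecule
#' @param mol A `ccg_molecule`.
#' @return N x C numeric matrix, one [atom_features()] row per atom.
#' @export
atom_feature_matrix <- function(mol) {
  t(vapply(seq_len(n_atoms(mol)), function(i) atom_features(mol, i),
           numeric(atom_feature_width())))
}

#' Bond-type adjacency tensor
#'
#' One symmetric 0/1 adjacency slice per bond type, in the fixed order
#' (single, double, triple, aromatic).
#'
#' @param mol A `ccg_molecule`.
#' @return N x N x 4 array with zero diagonals; for any atom pair at most one
#'   slice is nonzero and the slice-sum is the plain bond adjacency matrix.
#' @export
bond_adjacency_tensor <- function(mol) {
  n <- n_atoms(mol)
  A <- array(0, dim = c(n, n, length(CCG_BOND_TYPES)),
             dimnames = list(NULL, NULL, CCG_BOND_TYPES))
  for (k in seq_len(nrow(mol$bonds))) {
    b <- mol$bonds[k, ]
    l <- match(b$type, CCG_BOND_TYPES)
    if (is.na(l)) stop("unsupported bond type: ", b$type, call. = FALSE)
    A[b$i, b$j, l] <- 1
    A[b$j, b$i, l] <- 1
  }
  A
}

#' Principal-axis box extents of a conformer
#'
#' The enclosing box is taken along the three principal axes of the centred
#' atomic coordinates, which makes the extents invariant to rigid rotation
#' and translation.  No van der Waals padding is added.
#'
#' @param coords N x 3 coordinate matrix (Angstrom).
#' @return Named numeric vector `c(S=, M=, L=)` with S <= M <= L, plus
#'   attribute `degenerate` flagging (near-)collinear or coincident input.
#' @export
box_axes <- function(coords) {
  stopifnot(is.matrix(coords), ncol(coords) == 3, nrow(coords) >= 2,
            all(is.finite(coords)))
  centred <- sweep(coords, 2, colMeans(coords))
  # principal axes = eigenbasis of the 3x3 coordinate covariance (full rank
  # even for fewer than 3 atoms, unlike an SVD of the coordinate matrix)
  rot <- eigen(crossprod(centred), symmetric = TRUE)$vectors
  proj <- centred %*% rot
  ext <- sort(apply(proj, 2, function(x) diff(range(x))))
  names(ext) <- c("S", "M", "L")
  # a zero short axis is normal for planar molecules; only (near-)collinear
  # geometry leaves the medium axis degenerate too
  degenerate <- ext[["M"]] < 1e-8
  if (degenerate) {
    warning("degenerate geometry: atoms are (near-)collinear", call. = FALSE)
  }
  structure(ext, degenerate = degenerate)
}

#' Prior-knowledge molecular descriptors
#'
#' Computes the 12-descriptor global state of one coformer: box extents and
#' their ratios (S, S_L, S_M, M_L), globularity (surface of the sphere with
#' the molecule's volume over its solvent-accessible surface area), FrTPSA
#' (TPSA/SASA), heteroatom fraction Fr_NO, aromatic-atom fraction, H-bond
#' acceptor and donor counts, rotatable-bond count, and the magnitude of the
#' Gasteiger point-charge dipole (Debye) on the stored conformer.
#'
#' The donor/acceptor counts are the sums of the per-atom `is_donor` /
#' `is_acceptor` flags, so the atom features and the descriptor layer share a
#' single pharmacophore definition.
#'
#' @param mol A `ccg_molecule` with 3D coordinates.
#' @return Named numeric vector of length 12 in the fixed descriptor order.
#' @export
compute_descriptors <- function(mol) {
  stopifnot(inherits(mol, "ccg_molecule"))
  if (is.null(mol$coords) || nrow(mol$coords) == 0) {
    stop("state error: molecule has no 3D coordinates", call. = FALSE)
  }
  heavy <- mol$atoms$atomic_number > 1
  n_heavy <- sum(heavy)
  if (n_heavy == 0) stop("undefined descriptors: no heavy atoms", call. = FALSE)

  ext <- box_axes(mol$coords)
  S <- ext[["S"]]; M <- ext[["M"]]; L <- ext[["L"]]
  ratio <- function(a, b) if (b > 1e-12) a / b else 0
  sphere_area <- (36 * pi)^(1 / 3) * mol$props$volume^(2 / 3)
  glob <- min(sphere_area / mol$props$sasa, 1)

  centred <- sweep(mol$coords, 2, colMeans(mol$coords))
  mu_ea <- colSums(mol$atoms$gasteiger * centred)   # e * Angstrom
  dipole <- sqrt(sum(mu_ea^2)) * 4.80320425         # -> Debye

  out <- c(
    S = S, S_L = ratio(S, L), S_M = ratio(S, M), M_L = ratio(M, L),
    Globularity = glob,
    FrTPSA = mol$props$tpsa / mol$props$sasa,
    Fr_NO = sum(heavy & mol$atoms$symbol %in% c("N", "O")) / n_heavy,
    Fr_AromaticAtoms = sum(heavy & mol$atoms$is_aromatic == 1) / n_heavy,
    HBA = sum(mol$atoms$is_acceptor),
    HBD = sum(mol$atoms$is_donor),
    RBN = mol$props$rbn,
    Dipole_Moment = dipole)
  structure(out, degenerate = attr(ext, "degenerate"))
}

#' Molecular graph of one coformer
#'
#' Bundles the vertex feature matrix and the bond-type adjacency tensor.
#'
#' @param mol A `ccg_molecule`.
#' @return List with elements `V` (N x C) and `A` (N x N x 4), class
#'   `ccg_molgraph`.
#' @export
molecular_graph <- function(mol) {
  structure(list(V = atom_feature_matrix(mol), A = bond_adjacency_tensor(mol)),
            class = "ccg_molgraph")
}
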