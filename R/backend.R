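# Bridge to the RDKit perception helper (inst/python/featurize.py).
#
# The helper is invoked in batches through temporary JSON files; results are
# memoised per session so repeated featurization of the same molecule (and
# the same conformer seed) costs one subprocess call in total.

.ccg_cache <- new.env(parent = emptyenv())

ccg_python <- function() {
  py <- Sys.getenv("CCGNET_PYTHON", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) stop("no 'python' interpreter found on the PATH", call. = FALSE)
  py
}

ccg_helper_script <- function() {
  path <- system.file("python", "featurize.py", package = "ccgnet")
  if (!nzchar(path)) stop("featurize.py helper not found in the installed package")
  path
}

run_backend <- function(job) {
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(job, fin, auto_unbox = TRUE, digits = NA, null = "null")
  status <- system2(ccg_python(), c(ccg_helper_script(), fin, fout),
                    stdout = FALSE, stderr = "")
  if (!identical(status, 0L) || !file.exists(fout)) {
    stop("molecular perception backend failed (exit status ", status, ")",
         call. = FALSE)
  }
  jsonlite::read_json(fout, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = TRUE)
}

#' Canonicalize SMILES strings
#'
#' Canonical SMILES are the single identity authority for molecules in this
#' package: duplicate detection, solvent blacklists and report keys all
#' compare canonical forms.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES; `NA` where a string does not
#'   parse.
#' @export
canonical_smiles <- function(smiles) {
  if (length(smiles) == 0) return(character())
  keys <- paste0("can|", smiles)
  miss <- !vapply(keys, exists, logical(1), envir = .ccg_cache)
  if (any(miss)) {
    res <- run_backend(list(op = "canonicalize", smiles = as.list(smiles[miss])))
    vals <- res$canonical
    vals <- vapply(seq_along(vals), function(i)
      if (is.null(vals[[i]])) NA_character_ else as.character(vals[[i]]),
      character(1))
    for (i in seq_along(vals)) assign(keys[miss][i], vals[i], envir = .ccg_cache)
  }
  vapply(keys, get, character(1), envir = .ccg_cache, USE.NAMES = FALSE)
}

# Composition-level screening facts (no conformer generation).
inspect_smiles <- function(smiles) {
  keys <- paste0("ins|", smiles)
  miss <- !vapply(keys, exists, logical(1), envir = .ccg_cache)
  if (any(miss)) {
    res <- run_backend(list(op = "inspect", smiles = as.list(smiles[miss])))
    for (i in seq_along(res$inspect)) {
      assign(keys[miss][i], res$inspect[[i]], envir = .ccg_cache)
    }
  }
  lapply(keys, get, envir = .ccg_cache)
}

# Raw featurization records for a batch of inputs. `records` is a list of
# list(id=, smiles=) or list(id=, molblock=).
backend_featurize <- function(records, seed) {
  keyof <- function(r) paste0("mol|", seed, "|",
                              if (is.null(r$smiles)) r$molblock else r$smiles)
  keys <- vapply(records, keyof, character(1))
  miss <- !vapply(keys, exists, logical(1), envir = .ccg_cache)
  if (any(miss)) {
    res <- run_backend(list(op = "featurize", seed = seed,
                            records = records[miss]))
    mols <- res$molecules
    for (i in seq_along(mols)) assign(keys[miss][i], mols[[i]], envir = .ccg_cache)
  }
  lapply(keys, get, envir = .ccg_cache)
}
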