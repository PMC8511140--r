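# End-user surface: pair-list CSV reading, graph building, screening
# reports, checkpoints and run manifests.

#' Read and validate a labeled pair list
#'
#' Expects a CSV with header `id, coformer_a, coformer_b[, label]`.  SMILES
#' are canonicalized, unparseable rows are reported (and dropped unless
#' `strict`), and duplicate unordered pairs are collapsed with a warning
#' (the polymorph/duplicate analogue for pair lists).
#'
#' @param path CSV path.
#' @param strict Abort on the first invalid SMILES instead of dropping the
#'   row.
#' @return Data frame `id, coformer_a, coformer_b, label` (label `NA` when
#'   the column is absent; such samples are refused by training).
#' @export
read_pairs_csv <- function(path, strict = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "coformer_a", "coformer_b")
  if (!all(need %in% names(df))) {
    stop("schema error: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  if (!"label" %in% names(df)) df$label <- NA_integer_
  can_a <- canonical_smiles(df$coformer_a)
  can_b <- canonical_smiles(df$coformer_b)
  bad <- is.na(can_a) | is.na(can_b)
  if (any(bad)) {
    msg <- paste0("invalid SMILES in row(s): ",
                  paste(which(bad), collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; dropped", call. = FALSE)
    df <- df[!bad, , drop = FALSE]
    can_a <- can_a[!bad]; can_b <- can_b[!bad]
  }
  df$coformer_a <- can_a
  df$coformer_b <- can_b
  key <- ifelse(can_a <= can_b, paste(can_a, can_b), paste(can_b, can_a))
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate unordered pair(s) collapsed", call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df[, c("id", "coformer_a", "coformer_b", "label")]
}

#' Build co-crystal graphs from a pair table
#'
#' Featurizes every unique coformer once and assembles one `ccgraph` per
#' row.
#'
#' @param pairs Data frame with `coformer_a`, `coformer_b` and optionally
#'   `label` columns (e.g. from [read_pairs_csv()] or [planted_pairs()]).
#' @param conformer_seed Seed for 3D embedding.
#' @return List of `ccgraph` objects.
#' @export
pairs_to_graphs <- function(pairs, conformer_seed = 2024L) {
  smis <- unique(c(pairs$coformer_a, pairs$coformer_b))
  mols <- read_molecules(smis, seed = conformer_seed)
  labels <- if ("label" %in% names(pairs)) pairs$label else rep(NA, nrow(pairs))
  lapply(seq_len(nrow(pairs)), function(i) {
    pair_graph(mols[[pairs$coformer_a[i]]], mols[[pairs$coformer_b[i]]],
               label = labels[i])
  })
}

#' Write a ranked screening report
#'
#' CSV output is byte-stable given identical input.  HTML output renders
#' the ranked table and, when attention maps are supplied, a per-pair
#' color-coded atom-weight strip (redder = more attended).
#'
#' @param ranked Data frame from [ensemble_rank()].
#' @param path Output file.
#' @param format `"csv"` or `"html"`.
#' @param attention Optional list of attention matrices aligned with the
#'   ranked rows (HTML only).
#' @return `path`, invisibly.
#' @export
write_report <- function(ranked, path, format = c("csv", "html"),
                         attention = NULL) {
  format <- match.arg(format)
  if (nrow(ranked) == 0) warning("writing empty report", call. = FALSE)
  if (format == "csv") {
    write.csv(ranked, path, row.names = FALSE)
    return(invisible(path))
  }
  esc <- function(x) gsub("<", "&lt;", gsub("&", "&amp;", as.character(x)))
  rows <- vapply(seq_len(nrow(ranked)), function(i) {
    cells <- vapply(ranked[i, ], function(v)
      sprintf("<td>%s</td>", esc(if (is.numeric(v)) signif(v, 6) else v)),
      character(1))
    extra <- ""
    if (!is.null(attention) && length(attention) >= i) {
      w <- rowMeans(attention[[i]])
      shade <- vapply(w / max(w), function(f) sprintf(
        "<span style='background-color: rgba(255,0,0,%.2f)'>&#9608;</span>",
        f), character(1))
      extra <- sprintf("<td>%s</td>", paste(shade, collapse = ""))
    }
    sprintf("<tr>%s%s</tr>", paste(cells, collapse = ""), extra)
  }, character(1))
  header <- paste(sprintf("<th>%s</th>", esc(names(ranked))), collapse = "")
  if (!is.null(attention)) header <- paste0(header, "<th>attention</th>")
  html <- c("<html><body><table border='1'>",
            sprintf("<tr>%s</tr>", header), rows, "</table></body></html>")
  writeLines(html, path)
  invisible(path)
}

#' Save a model checkpoint
#'
#' Single-file checkpoint holding the serialized model (weights, config,
#' scaler, seeds, feature-layout version) together with its MD5 checksum;
#' loading verifies the checksum and the layout version.
#'
#' @param model A `ccgnet_model`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "ccgnet_model"))
  payload <- serialize(model, NULL)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(payload, tmp)
  saveRDS(list(payload = payload,
               md5 = unname(tools::md5sum(tmp)),
               layout_version = model$layout_version,
               package_version = as.character(utils::packageVersion("ccgnet"))),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint written by [save_checkpoint()].
#' @return The restored `ccgnet_model`.
#' @export
load_checkpoint <- function(path) {
  wrap <- readRDS(path)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(wrap$payload, tmp)
  if (!identical(unname(tools::md5sum(tmp)), wrap$md5)) {
    stop("integrity error: checkpoint checksum mismatch", call. = FALSE)
  }
  model <- unserialize(wrap$payload)
  if (!identical(model$layout_version, CCG_LAYOUT_VERSION)) {
    stop("layout-version mismatch: checkpoint uses ", model$layout_version,
         ", this package uses ", CCG_LAYOUT_VERSION, call. = FALSE)
  }
  model
}

#' Save an ensemble to a directory
#' @param models List of `ccgnet_model` objects.
#' @param dir Destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_ensemble <- function(models, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(models)) {
    save_checkpoint(models[[i]], file.path(dir, sprintf("member%02d.ccg", i)))
  }
  jsonlite::write_json(list(n_members = length(models),
                            layout_version = CCG_LAYOUT_VERSION),
                       file.path(dir, "ensemble.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Load an ensemble directory
#' @param dir Directory written by [save_ensemble()].
#' @return List of `ccgnet_model` objects in member order.
#' @export
load_ensemble <- function(dir) {
  files <- sort(list.files(dir, pattern = "^member[0-9]+\\.ccg$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no ensemble members found in ", dir)
  lapply(files, load_checkpoint)
}

#' Write a run manifest
#'
#' Records what a run needs to be reproduced: the command, configuration,
#' seeds, package version, feature-layout version, input-file hashes and a
#' timestamp.
#'
#' @param path Output JSON path.
#' @param command Name of the command or function run.
#' @param config List of configuration values.
#' @param seeds Named list/vector of seeds.
#' @param inputs Character vector of input file paths to hash.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config = list(), seeds = list(),
                           inputs = character()) {
  hashes <- if (length(inputs)) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else list()
  jsonlite::write_json(list(
    command = command, config = config, seeds = seeds,
    input_md5 = hashes,
    package_version = as.character(utils::packageVersion("ccgnet")),
    layout_version = CCG_LAYOUT_VERSION,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
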