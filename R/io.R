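#' Read a dataset into the stacked layout
#'
#' Supported formats:
#' * `csv` — one dense table, cells as rows: a `cell_id` column, the
#'   covariate column, an optional label column, and one column per feature.
#' * `mtx` — a directory with `matrix.mtx` (features x cells, MatrixMarket),
#'   `features.tsv`, `barcodes.tsv` and an optional `metadata.tsv`
#'   (columns `cell_id`, covariate, label).
#'
#' Features are aligned by name to the block layout; features absent from the
#' file are zero-filled, and a block none of whose features are present is
#' flagged unavailable. Duplicate feature names are an error. H5AD is not
#' supported by this package; export to MTX or CSV first.
#'
#' @param path File (csv) or directory (mtx).
#' @param layout A [block_layout()] defining the stacked feature axis.
#' @param format `"csv"` or `"mtx"`.
#' @param covariate_col Name of the covariate column (default `"covariate"`);
#'   must be present.
#' @param label_col Name of the label column (default `"label"`); when absent
#'   the dataset is read as unlabeled.
#' @return A [stacked_dataset()].
#' @export
read_dataset <- function(path, layout, format = c("csv", "mtx", "h5ad"),
                         covariate_col = "covariate", label_col = "label") {
  format <- match.arg(format)
  if (format == "h5ad") {
    abort(paste(
      "H5AD is not supported (no HDF5 interface is available to this package);",
      "export the AnnData object to MTX + TSV or dense CSV first."
    ))
  }
  if (format == "csv") {
    tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (!"cell_id" %in% names(tab)) abort("CSV must contain a `cell_id` column.")
    meta_cols <- intersect(c("cell_id", covariate_col, label_col), names(tab))
    feat_names <- names(tab)[!names(tab) %in% meta_cols]  # keep duplicates
    M <- as.matrix(tab[, feat_names, drop = FALSE])
    storage.mode(M) <- "double"
    rownames(M) <- tab$cell_id
    meta <- tab[, meta_cols, drop = FALSE]
  } else {
    mtx_file <- file.path(path, "matrix.mtx")
    M <- as.matrix(Matrix::t(Matrix::readMM(mtx_file)))
    feat_names <- utils::read.delim(file.path(path, "features.tsv"),
                                    header = FALSE)[[1]]
    barcodes <- utils::read.delim(file.path(path, "barcodes.tsv"),
                                  header = FALSE)[[1]]
    if (length(feat_names) != ncol(M) || length(barcodes) != nrow(M)) {
      abort("features.tsv / barcodes.tsv do not match matrix.mtx dimensions.")
    }
    colnames(M) <- feat_names
    rownames(M) <- barcodes
    meta_file <- file.path(path, "metadata.tsv")
    if (file.exists(meta_file)) {
      meta <- utils::read.delim(meta_file, stringsAsFactors = FALSE)
      meta <- meta[match(barcodes, meta$cell_id), , drop = FALSE]
    } else {
      meta <- data.frame(cell_id = barcodes)
    }
    feat_names <- colnames(M)
  }

  if (anyDuplicated(feat_names)) {
    abort(sprintf("Duplicate feature names in %s: %s", path,
                  paste(unique(feat_names[duplicated(feat_names)]), collapse = ", ")))
  }
  if (!covariate_col %in% names(meta)) {
    abort(sprintf("Covariate column '%s' not found in %s.", covariate_col, path))
  }

  n <- nrow(M)
  D <- n_features(layout)
  X <- matrix(0, n, D)
  avail <- matrix(FALSE, n, nrow(layout))
  all_feats <- layout_features(layout)
  hit <- match(all_feats, feat_names)
  extra <- setdiff(feat_names, all_feats)
  if (length(extra)) {
    warn(sprintf("%d feature(s) not in the layout were dropped.", length(extra)))
  }
  X[, !is.na(hit)] <- M[, hit[!is.na(hit)], drop = FALSE]
  for (b in seq_len(nrow(layout))) {
    avail[, b] <- any(!is.na(hit[block_span(layout, layout$name[b])]))
  }

  labels <- if (label_col %in% names(meta)) meta[[label_col]] else NULL
  covariate <- as.integer(factor(meta[[covariate_col]]))
  stacked_dataset(X, layout, covariate, labels = labels, available = avail,
                  cell_ids = as.character(meta$cell_id))
}

#' Write a stacked dataset to disk
#'
#' Inverse of [read_dataset()] for both supported formats; `csv` writes one
#' dense table, `mtx` writes a directory of `matrix.mtx` (features x cells),
#' `features.tsv`, `barcodes.tsv` and `metadata.tsv`.
#'
#' @param dataset A [stacked_dataset()].
#' @param path Output file (csv) or directory (mtx).
#' @param format `"csv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, format = c("csv", "mtx")) {
  format <- match.arg(format)
  lab <- rep(NA_character_, n_cells(dataset))
  has <- !is.na(dataset$labels)
  if (length(dataset$label_levels)) {
    lab[has] <- dataset$label_levels[dataset$labels[has]]
  }
  if (format == "csv") {
    tab <- data.frame(cell_id = dataset$cell_ids,
                      covariate = dataset$covariate,
                      check.names = FALSE)
    if (any(has)) tab$label <- lab
    tab <- cbind(tab, as.data.frame(dataset$X, check.names = FALSE))
    utils::write.csv(tab, path, row.names = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(t(dataset$X), sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    writeLines(layout_features(dataset$layout), file.path(path, "features.tsv"))
    writeLines(dataset$cell_ids, file.path(path, "barcodes.tsv"))
    meta <- data.frame(cell_id = dataset$cell_ids,
                       covariate = dataset$covariate, label = lab)
    utils::write.table(meta, file.path(path, "metadata.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with fields such as `scenario`, dataset paths,
#'   block definitions, model dimensions, training hyperparameters and
#'   `seed`. Unknown top-level keys are an error (typo guard).
#' @return A named list with a resolved [model_config()] under `$config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("scenario", "datasets", "blocks", "model", "seed", "outdir",
             "covariate_col", "label_col", "n_clusters", "common")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    abort(sprintf("Unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  model_args <- raw$model %||% list()
  raw$config <- do.call(model_config, model_args)
  raw$seed <- as.integer(raw$seed %||% 1L)
  raw
}

#' Write a metrics report as JSON
#'
#' @param metrics Named list of scalar metrics.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
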