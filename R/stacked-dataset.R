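#' Assemble a stacked multimodal dataset
#'
#' A `stacked_dataset` holds one cells-by-features matrix in which all
#' modalities are stacked along the feature axis, together with the block
#' layout, one integer covariate code per cell (batch and/or dataset of
#' origin), optional per-cell labels, and a cells-by-blocks availability flag.
#' Feature values of blocks a cell was never measured in are zero-filled;
#' the availability flags record which blocks are genuinely observed so that
#' training phases never ask the model to reconstruct padding.
#'
#' @param X Numeric matrix, cells x stacked features, nonnegative. Column
#'   names, if present, must match `layout_features(layout)`.
#' @param layout A [block_layout()].
#' @param covariate Integer codes in `1..n_cov` (or a factor), one per cell.
#' @param labels Optional per-cell labels: integer codes, factor or character;
#'   `NA` marks unlabeled cells.
#' @param available Logical matrix, cells x blocks (columns in layout order).
#'   Defaults to all blocks available for every cell.
#' @param cell_ids Optional character cell identifiers.
#'
#' @return A `stacked_dataset` object.
#'
#' @examples
#' layout <- block_layout(rna = c("g1", "g2", "g3"))
#' ds <- stacked_dataset(matrix(abs(rnorm(6)), 2, 3), layout, covariate = c(1, 1))
#' dim(ds$X)
#' @export
stacked_dataset <- function(X, layout, covariate, labels = NULL,
                            available = NULL, cell_ids = NULL) {
  if (!inherits(layout, "block_layout")) abort("`layout` must be a block_layout.")
  X <- as.matrix(X)
  .check_matrix(X, "X")
  D <- n_features(layout)
  if (ncol(X) != D) {
    abort(sprintf("`X` has %d columns but the layout stacks %d features.", ncol(X), D))
  }
  if (any(X < 0)) abort("`X` must be nonnegative (zero-filled where unobserved).")
  n <- nrow(X)
  colnames(X) <- layout_features(layout)

  if (is.factor(covariate)) covariate <- as.integer(covariate)
  covariate <- as.integer(covariate)
  if (length(covariate) != n) abort("`covariate` must have one code per cell.")
  if (anyNA(covariate) || any(covariate < 1L)) {
    abort("`covariate` codes must be positive integers (1-based).")
  }

  if (!is.null(labels)) {
    if (is.character(labels)) labels <- factor(labels)
    if (is.factor(labels)) {
      label_levels <- levels(labels)
      labels <- as.integer(labels)
    } else {
      labels <- as.integer(labels)
      label_levels <- as.character(sort(unique(labels[!is.na(labels)])))
      labels <- match(labels, as.integer(label_levels))
    }
    if (length(labels) != n) abort("`labels` must have one entry per cell.")
  } else {
    labels <- rep(NA_integer_, n)
    label_levels <- character(0)
  }

  if (is.null(available)) {
    available <- matrix(TRUE, n, nrow(layout))
  }
  available <- as.matrix(available)
  if (!identical(dim(available), c(n, nrow(layout)))) {
    abort("`available` must be cells x blocks.")
  }
  storage.mode(available) <- "logical"
  colnames(available) <- layout$name

  # zero-fill invariant: unavailable blocks must hold only padding
  for (b in seq_len(nrow(layout))) {
    idx <- block_span(layout, layout$name[b])
    off <- !available[, b]
    if (any(off) && any(X[off, idx, drop = FALSE] != 0)) {
      abort(sprintf(
        "Block '%s' is flagged unavailable for some cells but carries nonzero values there.",
        layout$name[b]
      ))
    }
  }

  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(n))
  if (n > 0) rownames(X) <- cell_ids

  structure(
    list(
      X = X, layout = layout, covariate = covariate, labels = labels,
      label_levels = label_levels, available = available, cell_ids = cell_ids
    ),
    class = "stacked_dataset"
  )
}

#' @export
print.stacked_dataset <- function(x, ...) {
  cat(sprintf(
    "<stacked_dataset> %d cells x %d features in %d block(s): %s\n",
    nrow(x$X), ncol(x$X), nrow(x$layout),
    paste(sprintf("%s[%d]", x$layout$name, x$layout$end - x$layout$start + 1L),
          collapse = ", ")
  ))
  cat(sprintf(
    "  covariates: %d level(s); labeled cells: %d/%d\n",
    max(x$covariate), sum(!is.na(x$labels)), nrow(x$X)
  ))
  invisible(x)
}

#' @export
dim.stacked_dataset <- function(x) dim(x$X)

#' Number of cells in a stacked dataset
#' @param dataset A [stacked_dataset()].
#' @return Integer cell count.
#' @export
n_cells <- function(dataset) nrow(dataset$X)

#' Combine stacked datasets into one training set
#'
#' Rows are concatenated on a shared feature layout (the union of all blocks,
#' aligned by feature name); blocks absent from a dataset are zero-filled and
#' flagged unavailable. Covariate codes are re-assigned so that each input
#' dataset becomes one covariate level, which is the conditioning used to
#' remove dataset (batch/modality) effects by latent vector arithmetic.
#'
#' @param datasets A list of [stacked_dataset()] objects.
#' @return A `stacked_dataset` whose `covariate` is the dataset index and
#'   which carries the per-dataset origin in `$dataset_of_origin`.
#' @export
bind_datasets <- function(datasets) {
  if (!length(datasets)) abort("`datasets` must be a non-empty list.")
  for (d in datasets) {
    if (!inherits(d, "stacked_dataset")) abort("All elements must be stacked_dataset objects.")
  }

  # union layout, preserving first-seen block order and feature order
  blocks <- list()
  kinds <- character(0)
  for (d in datasets) {
    for (b in seq_len(nrow(d$layout))) {
      nm <- d$layout$name[b]
      if (is.null(blocks[[nm]])) {
        blocks[[nm]] <- d$layout$features[[b]]
        kinds[nm] <- d$layout$kind[b]
      } else if (!identical(blocks[[nm]], d$layout$features[[b]])) {
        abort(sprintf("Block '%s' has inconsistent feature sets across datasets.", nm))
      }
    }
  }
  layout <- do.call(block_layout, c(blocks, list(kinds = unname(kinds))))

  n_tot <- sum(vapply(datasets, n_cells, integer(1)))
  D <- n_features(layout)
  X <- matrix(0, n_tot, D)
  avail <- matrix(FALSE, n_tot, nrow(layout))
  labels <- rep(NA_integer_, n_tot)
  covariate <- integer(n_tot)
  origin <- integer(n_tot)
  ids <- character(n_tot)

  all_levels <- unique(unlist(lapply(datasets, function(d) d$label_levels)))
  at <- 0L
  for (k in seq_along(datasets)) {
    d <- datasets[[k]]
    rows <- at + seq_len(n_cells(d))
    for (b in seq_len(nrow(d$layout))) {
      nm <- d$layout$name[b]
      X[rows, block_span(layout, nm)] <- d$X[, block_span(d$layout, nm), drop = FALSE]
      avail[rows, match(nm, layout$name)] <- d$available[, b]
    }
    lab <- d$labels
    if (length(d$label_levels)) {
      labels[rows] <- match(d$label_levels[lab], all_levels)
    }
    covariate[rows] <- k
    origin[rows] <- k
    ids[rows] <- paste0("d", k, "_", d$cell_ids)
    at <- at + n_cells(d)
  }

  out <- stacked_dataset(X, layout, covariate,
                         labels = NULL, available = avail, cell_ids = ids)
  out$labels <- labels
  out$label_levels <- all_levels %||% character(0)
  out$dataset_of_origin <- origin
  out
}
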