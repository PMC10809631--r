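#' Mask pair for unpaired integration with dataset-specific genes
#'
#' Builds the input/output mask templates for integrating two unpaired
#' datasets that share a common gene panel while one (or, in the symmetric
#' variant, each) carries additional specific genes. Both datasets are
#' encoded from the common genes only (shared weights carry the knowledge
#' transfer); the reference dataset is supervised on all its genes so the
#' decoder learns to produce the specific genes from common-gene input, while
#' the query dataset is supervised on the common genes only — its specific
#' positions hold zero padding, never ground truth.
#'
#' @param common_idx Integer indices of the shared genes on the stacked axis.
#' @param specific_idx Integer indices of genes measured only in the
#'   reference (or, with `own_specific_idx`, in this dataset).
#' @param dataset `"reference"` (all genes supervised) or `"query"`
#'   (common genes supervised only).
#' @param n_features Total stacked dimension.
#' @param own_specific_idx Optional indices of genes specific to *this*
#'   dataset (the symmetric variant in which every dataset has its own
#'   specific genes): they are added to this dataset's output mask.
#' @return A `mask_pair`: list with binary vectors `input_mask` and
#'   `output_mask` of length `n_features`.
#' @examples
#' build_unpaired_masks(1:3, 4:5, "query", 5)
#' @export
build_unpaired_masks <- function(common_idx, specific_idx,
                                 dataset = c("reference", "query"),
                                 n_features = max(common_idx, specific_idx, 0L),
                                 own_specific_idx = NULL) {
  dataset <- match.arg(dataset)
  common_idx <- as.integer(common_idx)
  specific_idx <- as.integer(specific_idx)
  if (length(intersect(common_idx, specific_idx))) {
    abort("`common_idx` and `specific_idx` overlap.")
  }
  if (!length(common_idx)) abort("At least one common gene is required.")
  D <- as.integer(n_features)
  covered <- sort(union(common_idx, specific_idx))
  if (!identical(covered, seq_len(D))) {
    abort("`common_idx` and `specific_idx` must tile the gene axis 1..n_features.")
  }
  input_mask <- numeric(D)
  input_mask[common_idx] <- 1
  output_mask <- numeric(D)
  if (dataset == "reference") {
    output_mask[] <- 1
  } else {
    output_mask[common_idx] <- 1
  }
  if (!is.null(own_specific_idx)) {
    own_specific_idx <- as.integer(own_specific_idx)
    if (length(setdiff(own_specific_idx, specific_idx))) {
      abort("`own_specific_idx` must be a subset of `specific_idx`.")
    }
    output_mask[own_specific_idx] <- 1
  }
  structure(list(input_mask = input_mask, output_mask = output_mask),
            class = "mask_pair")
}

#' Mask pair for one stacked-modality training phase
#'
#' In the stacked architecture a training phase names one input block and one
#' output block: the input mask is 1 exactly on the input block's span and the
#' output mask 1 exactly on the output block's span, so only the matching
#' first-layer encoder sublayer and last-layer decoder sublayer contribute.
#' Equal blocks give a self-reconstruction phase; different blocks give an
#' alternative-reconstruction (cross-modal translation) phase.
#'
#' @param input_block,output_block Block names present in `layout`.
#' @param layout A [block_layout()].
#' @return A `mask_pair` of length-`n_features(layout)` templates.
#' @examples
#' lay <- block_layout(rna = paste0("g", 1:4), adt = paste0("p", 1:2))
#' build_phase_masks("adt", "rna", lay)
#' @export
build_phase_masks <- function(input_block, output_block, layout) {
  D <- n_features(layout)
  input_mask <- numeric(D)
  input_mask[block_span(layout, input_block)] <- 1
  output_mask <- numeric(D)
  output_mask[block_span(layout, output_block)] <- 1
  structure(list(input_mask = input_mask, output_mask = output_mask),
            class = "mask_pair")
}

#' @export
print.mask_pair <- function(x, ...) {
  cat(sprintf("<mask_pair> %d features; input on %d, output on %d\n",
              length(x$input_mask), sum(x$input_mask), sum(x$output_mask)))
  invisible(x)
}
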