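#' Define the stacked feature layout of a multimodal dataset
#'
#' Modalities are concatenated along one feature axis: the first layer of the
#' encoder and the last layer of the decoder can then be read as independent
#' per-modality sublayers that binary masks switch on and off. A block layout
#' records, for each modality block, its name, kind and half-open span
#' `[start, end)` on the stacked axis.
#'
#' @param ... Named character vectors of feature identifiers, one per modality
#'   block, in stacking order (e.g. `rna = paste0("g", 1:100)`).
#' @param kinds Optional character vector (recycled) giving the kind of each
#'   block: one of `"expression"`, `"protein"`, `"accessibility"`,
#'   `"generic"`. Defaults to `"generic"`.
#'
#' @return A `block_layout`: a tibble with columns `name`, `kind`, `start`,
#'   `end` (1-based inclusive start, exclusive end+1 convention is avoided:
#'   `start:end` indexes the block) and a list-column `features`.
#'
#' @examples
#' layout <- block_layout(rna = paste0("g", 1:5), adt = paste0("p", 1:2),
#'                        kinds = c("expression", "protein"))
#' block_span(layout, "adt")
#' @export
block_layout <- function(..., kinds = "generic") {
  blocks <- list(...)
  if (length(blocks) == 0L) abort("At least one modality block is required.")
  if (is.null(names(blocks)) || any(names(blocks) == "")) {
    abort("Every modality block must be named.")
  }
  if (anyDuplicated(names(blocks))) abort("Block names must be unique.")
  kinds <- rep(kinds, length.out = length(blocks))
  ok <- c("expression", "protein", "accessibility", "generic")
  if (!all(kinds %in% ok)) {
    abort(sprintf("Block kinds must be one of: %s.", paste(ok, collapse = ", ")))
  }
  sizes <- vapply(blocks, length, integer(1))
  if (any(sizes == 0L)) abort("Modality blocks must contain at least one feature.")
  feats <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(feats)) {
    abort(sprintf(
      "Duplicate feature identifiers across blocks: %s",
      paste(unique(feats[duplicated(feats)]), collapse = ", ")
    ))
  }
  end <- unname(cumsum(sizes))
  start <- end - unname(sizes) + 1L
  structure(
    tibble(
      name = names(blocks),
      kind = kinds,
      start = start,
      end = end,
      features = lapply(blocks, as.character)
    ),
    class = c("block_layout", "tbl_df", "tbl", "data.frame")
  )
}

#' @rdname block_layout
#' @param layout A `block_layout`.
#' @param block Block name.
#' @return `block_span()`: the integer indices of `block` on the stacked axis.
#' @export
block_span <- function(layout, block) {
  i <- match(block, layout$name)
  if (is.na(i)) {
    abort(sprintf(
      "Unknown block '%s'; layout has: %s.",
      block, paste(layout$name, collapse = ", ")
    ))
  }
  seq.int(layout$start[i], layout$end[i])
}

#' @rdname block_layout
#' @return `layout_features()`: all feature identifiers in stacked order.
#' @export
layout_features <- function(layout) {
  unlist(layout$features, use.names = FALSE)
}

#' @rdname block_layout
#' @return `n_features()`: the total stacked dimension.
#' @export
n_features <- function(layout) {
  layout$end[nrow(layout)]
}
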