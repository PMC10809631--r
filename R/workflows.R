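.new_integration_result <- function(cells, z2, mu, probs, fit, imputed = NULL,
                                    generated = NULL, seed = NULL) {
  structure(
    list(cells = cells, Z2 = z2, mu = mu, probs = probs, fit = fit,
         imputed = imputed, generated = generated,
         provenance = list(seed = seed,
                           config_hash = rlang::hash(fit$config),
                           fitted = Sys.time())),
    class = "integration_result"
  )
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf(
    "<integration_result> %d cells, %d datasets, K=%d clusters%s%s\n",
    nrow(x$cells), length(unique(x$cells$dataset)), ncol(x$probs),
    if (!is.null(x$imputed)) sprintf("; imputed %d feature(s)", ncol(x$imputed)) else "",
    if (!is.null(x$generated)) sprintf("; generated %d feature(s)", ncol(x$generated)) else ""
  ))
  invisible(x)
}

.cells_tibble <- function(combined) {
  lab <- rep(NA_character_, n_cells(combined))
  has <- !is.na(combined$labels)
  if (length(combined$label_levels)) {
    lab[has] <- combined$label_levels[combined$labels[has]]
  }
  tibble(
    cell_id = combined$cell_ids,
    dataset = combined$dataset_of_origin %||% rep(1L, n_cells(combined)),
    covariate = combined$covariate,
    label = lab
  )
}

#' Integrate two unpaired datasets and impute the query's missing genes
#'
#' Trains the masked conditional VAE with the unpaired-integration mask pair:
#' both datasets are encoded from the common genes, the reference is
#' supervised on all its genes and the query on the common genes only. After
#' training, a noise-free pass reads the decoder output at the query's
#' missing (reference-specific) positions as imputed values, and the
#' covariate-free latent `z2` integrates both datasets.
#'
#' @param reference,query [stacked_dataset()] objects on the same gene axis
#'   (the query's missing genes zero-filled).
#' @param common Indices (or feature names) of the genes shared by both.
#' @param config A [model_config()].
#' @param seed Integer seed governing all randomness of the run.
#' @param n_clusters Classifier width; defaults to the number of label levels.
#' @return An `integration_result`; `$imputed` holds the query cells by
#'   specific genes matrix (empty when there are no specific genes), `$cells`
#'   a tibble of per-cell annotations, `$Z2` the integrated embedding.
#' @export
integrate_and_impute <- function(reference, query, common,
                                 config = model_config(), seed = 1L,
                                 n_clusters = NULL) {
  combined <- bind_datasets(list(reference, query))
  D <- n_features(combined$layout)
  if (is.character(common)) common <- match(common, layout_features(combined$layout))
  common <- sort(as.integer(common))
  if (!length(common)) abort("Zero common genes: nothing to integrate on.")
  specific <- setdiff(seq_len(D), common)

  m_ref <- build_unpaired_masks(common, specific, "reference", D)
  m_query <- build_unpaired_masks(common, specific, "query", D)
  phases <- list(
    training_phase("reference", which(combined$dataset_of_origin == 1L), m_ref),
    training_phase("query", which(combined$dataset_of_origin == 2L), m_query)
  )
  fit <- fit_mosaic(combined, phases, config, seed = seed, n_clusters = n_clusters)

  proj <- project_cells(fit, combined, input_mask = m_ref$input_mask)
  cells <- .cells_tibble(combined)
  cells$cluster <- proj$cluster
  qrows <- which(combined$dataset_of_origin == 2L)
  imputed <- proj$output[qrows, specific, drop = FALSE]
  colnames(imputed) <- layout_features(combined$layout)[specific]
  rownames(imputed) <- combined$cell_ids[qrows]
  .new_integration_result(cells, proj$z2, proj$mu, proj$probs, fit,
                          imputed = imputed, seed = seed)
}

# default stacked-phase schedule: self-reconstruction for every measured
# (dataset, block); alternative-reconstruction from the bridge block (the
# modality measured in the most datasets) to each other measured block
.default_schedule <- function(combined) {
  lay <- combined$layout
  origin <- combined$dataset_of_origin %||% rep(1L, n_cells(combined))
  ds_ids <- sort(unique(origin))
  has_block <- vapply(seq_len(nrow(lay)), function(b) {
    vapply(ds_ids, function(d) any(combined$available[origin == d, b]), logical(1))
  }, logical(length(ds_ids)))
  has_block <- matrix(has_block, nrow = length(ds_ids))
  colnames(has_block) <- lay$name

  phases <- list()
  for (d in ds_ids) {
    for (b in lay$name[has_block[d, ]]) {
      phases[[length(phases) + 1L]] <-
        phase_for_blocks(combined, b, b, origin = d)
    }
  }
  bridge <- lay$name[which.max(colSums(has_block))]
  for (d in ds_ids) {
    if (!has_block[d, bridge]) next
    for (b in setdiff(lay$name[has_block[d, ]], bridge)) {
      phases[[length(phases) + 1L]] <-
        phase_for_blocks(combined, bridge, b, origin = d)
    }
  }
  if (length(ds_ids) > 1) {
    for (i in seq_len(length(ds_ids) - 1)) {
      for (j in seq(i + 1, length(ds_ids))) {
        if (!any(has_block[i, ] & has_block[j, ])) {
          warn(sprintf(
            "Datasets %d and %d share no modality; integration relies on translation bridges only.",
            ds_ids[i], ds_ids[j]
          ))
        }
      }
    }
  }
  list(phases = phases, bridge = bridge)
}

# project cells group-wise: each cell is encoded from `embed_block` when it
# measures it, else from its first measured block
.project_by_block <- function(fit, combined, embed_block) {
  lay <- fit$layout
  n <- n_cells(combined)
  pick <- integer(n)
  bi <- match(embed_block, lay$name)
  pick[combined$available[, bi]] <- bi
  for (b in seq_len(nrow(lay))) {
    rest <- pick == 0L & combined$available[, b]
    pick[rest] <- b
  }
  if (any(pick == 0L)) abort("Some cells measure no block at all.")

  z2 <- matrix(0, n, fit$params$dims$d_z)
  mu <- matrix(0, n, fit$params$dims$d_z)
  probs <- matrix(0, n, fit$n_clusters)
  output <- matrix(0, n, n_features(lay))
  for (b in unique(pick)) {
    rows <- which(pick == b)
    sub <- list(X = combined$X[rows, , drop = FALSE],
                covariate = combined$covariate[rows])
    mask <- numeric(n_features(lay))
    mask[block_span(lay, lay$name[b])] <- 1
    fw <- forward_pass(sub$X, mask, rep(1, n_features(lay)), sub$covariate,
                       fit$params, mode = fit$config$arithmetic,
                       deterministic = TRUE)
    z2[rows, ] <- fw$state$z2
    mu[rows, ] <- fw$state$mu
    probs[rows, ] <- fw$probs
    output[rows, ] <- fw$state$output1
  }
  list(z2 = z2, mu = mu, probs = probs, output = output,
       cluster = max.col(probs, ties.method = "first"))
}

#' Integrate multiple (multi)modal datasets on a stacked feature axis
#'
#' Binds the datasets on the union block layout and trains the stacked
#' masked VAE with a self-reconstruction phase for every measured
#' (dataset, modality) pair and an alternative-reconstruction phase from the
#' bridge modality (the one measured in the most datasets) into each other
#' measured modality — the tri-modal six-phase schedule when two datasets
#' share one bridge. Cells are then embedded from the bridge modality (their
#' first measured one otherwise) and clustered by the classifier on the
#' covariate-free latent.
#'
#' @param datasets List of [stacked_dataset()] objects.
#' @param phases Optional explicit list of [training_phase()] objects built
#'   against the combined dataset; overrides the default schedule.
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @param n_clusters Classifier width; defaults to the number of label levels.
#' @param embed_block Block used to embed cells at inference; defaults to the
#'   bridge modality.
#' @return An `integration_result` with `$Z2` and `$cells$cluster` for every
#'   cell of every dataset.
#' @export
integrate_multimodal <- function(datasets, phases = NULL,
                                 config = model_config(), seed = 1L,
                                 n_clusters = NULL, embed_block = NULL) {
  combined <- bind_datasets(datasets)
  sched <- .default_schedule(combined)
  if (is.null(phases)) phases <- sched$phases
  fit <- fit_mosaic(combined, phases, config, seed = seed, n_clusters = n_clusters)
  proj <- .project_by_block(fit, combined, embed_block %||% sched$bridge)
  cells <- .cells_tibble(combined)
  cells$cluster <- proj$cluster
  .new_integration_result(cells, proj$z2, proj$mu, proj$probs, fit, seed = seed)
}

#' Generate a missing modality for monomodal cells from paired references
#'
#' Trains the stacked masked VAE with self-reconstruction of the source
#' modality in every dataset and translation from the source into the target
#' modality in the paired references. After training, a noise-free pass from
#' the query cells' source modality reads the decoder's target block as the
#' generated modality, and reference labels are transferred to query cells
#' through shared classifier clusters.
#'
#' @param references List of paired [stacked_dataset()]s measuring both the
#'   source and the target modality (typically labeled).
#' @param query A [stacked_dataset()] measuring the source modality only.
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @param source_block,target_block Block names; default to the query's
#'   measured block and the reference-only block, respectively.
#' @param n_clusters Classifier width; defaults to the number of label levels.
#' @return An `integration_result`; `$generated` holds the query cells x
#'   target features matrix and `$cells$transferred` the transferred labels
#'   (see [transfer_labels()]). An empty query yields empty outputs.
#' @export
generate_missing_modality <- function(references, query,
                                      config = model_config(), seed = 1L,
                                      source_block = NULL, target_block = NULL,
                                      n_clusters = NULL) {
  empty_query <- n_cells(query) == 0L
  all_ds <- c(references, if (!empty_query) list(query))
  combined <- bind_datasets(all_ds)
  lay <- combined$layout
  origin <- combined$dataset_of_origin
  query_id <- if (empty_query) NA_integer_ else length(all_ds)

  measured <- function(d) {
    lay$name[vapply(seq_len(nrow(lay)), function(b)
      any(combined$available[origin == d, b]), logical(1))]
  }
  # an empty query contributes no rows: fall back on its declared layout
  q_blocks <- if (empty_query) query$layout$name else measured(query_id)
  source_block <- source_block %||% q_blocks[1]
  target_block <- target_block %||%
    setdiff(unique(unlist(lapply(seq_along(references), measured))), q_blocks)[1]
  if (is.na(source_block) || is.na(target_block) || is.null(target_block)) {
    abort("Could not infer source/target blocks; specify them explicitly.")
  }

  phases <- list()
  for (d in seq_along(all_ds)) {
    phases[[length(phases) + 1L]] <-
      phase_for_blocks(combined, source_block, source_block, origin = d)
  }
  for (d in seq_along(references)) {
    phases[[length(phases) + 1L]] <-
      phase_for_blocks(combined, source_block, target_block, origin = d)
  }
  fit <- fit_mosaic(combined, phases, config, seed = seed, n_clusters = n_clusters)

  mask <- numeric(n_features(lay))
  mask[block_span(lay, source_block)] <- 1
  proj <- project_cells(fit, combined, input_mask = mask)
  cells <- .cells_tibble(combined)
  cells$cluster <- proj$cluster

  tspan <- block_span(lay, target_block)
  if (empty_query) {
    generated <- matrix(0, 0, length(tspan),
                        dimnames = list(NULL, layout_features(lay)[tspan]))
  } else {
    qrows <- which(origin == query_id)
    generated <- proj$output[qrows, tspan, drop = FALSE]
    colnames(generated) <- layout_features(lay)[tspan]
    rownames(generated) <- combined$cell_ids[qrows]
  }
  res <- .new_integration_result(cells, proj$z2, proj$mu, proj$probs, fit,
                                 generated = generated, seed = seed)
  transfer_labels(res)
}

#' Transfer labels to unlabeled cells through shared clusters
#'
#' Every unlabeled cell receives the majority label among the labeled cells
#' assigned to the same classifier cluster. Ties break deterministically
#' toward the smallest label code; clusters containing no labeled cell yield
#' `"unassigned"`. Labeled cells keep their own label.
#'
#' @param result An `integration_result`.
#' @return The result with a `transferred` column added to `$cells`.
#' @export
transfer_labels <- function(result) {
  cells <- result$cells
  levels_all <- sort(unique(cells$label[!is.na(cells$label)]))
  vote <- function(labs) {
    labs <- labs[!is.na(labs)]
    if (!length(labs)) return("unassigned")
    counts <- table(factor(labs, levels = levels_all))
    names(counts)[which.max(counts)]  # which.max takes the first (smallest code) on ties
  }
  majority <- vapply(split(cells$label, cells$cluster), vote, character(1))
  transferred <- majority[as.character(cells$cluster)]
  transferred[!is.na(cells$label)] <- cells$label[!is.na(cells$label)]
  result$cells$transferred <- unname(transferred)
  result
}
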