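#' Tidy a fitted model's loss history
#'
#' @param x A `mosaic_fit`.
#' @param ... Unused.
#' @return A tibble with one row per (epoch, phase): `epoch`, `phase`,
#'   `recon`, `kl`, `cls`, `total`.
#' @export
tidy.mosaic_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a fitted model
#'
#' @param x A `mosaic_fit`.
#' @param ... Unused.
#' @return A one-row tibble: dimensions, weights, epochs and final losses.
#' @export
glance.mosaic_fit <- function(x, ...) {
  last <- dplyr::filter(x$history, .data$epoch == max(.data$epoch))
  tibble(
    D = x$params$dims$D, d_z = x$params$dims$d_z, K = x$n_clusters,
    n_phases = length(unique(x$history$phase)),
    epochs = max(x$history$epoch),
    beta = x$config$beta, gamma = x$config$gamma,
    final_recon = mean(last$recon), final_kl = mean(last$kl),
    final_cls = mean(last$cls), final_total = mean(last$total),
    seed = x$seed
  )
}

#' Tidy an integration result
#'
#' @param x An `integration_result`.
#' @param ... Unused.
#' @return The per-cell annotation tibble (`cell_id`, `dataset`, `covariate`,
#'   `label`, `cluster`, and `transferred` when labels were transferred).
#' @export
tidy.integration_result <- function(x, ...) {
  x$cells
}

#' One-row summary of an integration result
#'
#' @param x An `integration_result`.
#' @param ... Unused.
#' @return A one-row tibble: cell/dataset/cluster counts and, where batch
#'   structure exists, the embedding's batch entropy.
#' @export
glance.integration_result <- function(x, ...) {
  be <- if (length(unique(x$cells$dataset)) > 1) {
    batch_entropy(x$Z2, x$cells$dataset, seed = x$provenance$seed %||% 1L)
  } else {
    NA_real_
  }
  tibble(
    n_cells = nrow(x$cells),
    n_datasets = length(unique(x$cells$dataset)),
    n_clusters_used = length(unique(x$cells$cluster)),
    batch_entropy = be,
    n_imputed = if (is.null(x$imputed)) 0L else ncol(x$imputed),
    n_generated = if (is.null(x$generated)) 0L else ncol(x$generated)
  )
}

#' @export
tidy.correlation_summary <- function(x, ...) {
  x$per_feature
}

#' @export
glance.correlation_summary <- function(x, ...) {
  tibble(mpcc = x$mpcc, apcc = x$apcc, mscc = x$mscc, ascc = x$ascc,
         n_features = nrow(x$per_feature), n_excluded = length(x$excluded))
}

#' Loss-history plot for a fitted model
#'
#' @param object A `mosaic_fit`.
#' @param ... Unused.
#' @return A ggplot of per-phase loss components over epochs.
#' @export
autoplot.mosaic_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history,
                              cols = c("recon", "kl", "cls", "total"),
                              names_to = "component", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = "loss",
                  title = "Training loss by phase and component") +
    ggplot2::theme_minimal()
}

#' Embedding plot for an integration result
#'
#' Plots the first two principal components of the covariate-free latent,
#' coloured by a per-cell annotation.
#'
#' @param object An `integration_result`.
#' @param colour One of `"cluster"`, `"dataset"`, `"label"`, `"transferred"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.integration_result <- function(object, colour = "cluster", ...) {
  pc <- prcomp(object$Z2, rank. = 2)$x
  df <- dplyr::mutate(object$cells,
                      PC1 = pc[, 1], PC2 = pc[, 2],
                      .colour = factor(object$cells[[colour]]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .colour)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.7) +
    ggplot2::labs(colour = colour,
                  title = "Integrated latent embedding (PCA of Z2)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
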