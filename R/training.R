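#' Define one training phase
#'
#' A phase is a (cell subset, mask pair) combination: every epoch the trainer
#' cycles through all phases in order, drawing minibatches of the phase's
#' cells with the phase's input/output mask templates. Self-reconstruction
#' phases use the same block for input and output; alternative-reconstruction
#' phases translate one modality into another for cells where both are
#' genuinely measured.
#'
#' @param name Phase name (used in the loss history and diagnostics).
#' @param cells Integer indices of the cells this phase trains on.
#' @param masks A `mask_pair` from [build_phase_masks()] or
#'   [build_unpaired_masks()].
#' @return A `training_phase` object.
#' @export
training_phase <- function(name, cells, masks) {
  cells <- as.integer(cells)
  if (!length(cells)) abort(sprintf("Phase '%s' selects no cells.", name))
  if (!inherits(masks, "mask_pair")) abort("`masks` must be a mask_pair.")
  if (sum(masks$output_mask) == 0) {
    abort(sprintf("Phase '%s' has an all-zero output mask.", name))
  }
  structure(list(name = name, cells = cells, masks = masks),
            class = "training_phase")
}

#' Helper: phase selecting cells of given datasets with given blocks measured
#'
#' @param dataset A combined [stacked_dataset()] (see [bind_datasets()]).
#' @param input_block,output_block Block names.
#' @param origin Optional dataset-of-origin indices to restrict to.
#' @param name Optional phase name.
#' @return A [training_phase()].
#' @export
phase_for_blocks <- function(dataset, input_block, output_block,
                             origin = NULL, name = NULL) {
  lay <- dataset$layout
  bi <- match(input_block, lay$name)
  bo <- match(output_block, lay$name)
  if (is.na(bi) || is.na(bo)) {
    abort(sprintf("Unknown block in phase: %s -> %s.", input_block, output_block))
  }
  sel <- dataset$available[, bi] & dataset$available[, bo]
  if (!is.null(origin)) {
    if (is.null(dataset$dataset_of_origin)) {
      abort("`origin` given but the dataset carries no dataset_of_origin.")
    }
    sel <- sel & dataset$dataset_of_origin %in% origin
  }
  name <- name %||% paste0(
    input_block, "->", output_block,
    if (!is.null(origin)) paste0(" (d", paste(origin, collapse = ","), ")") else ""
  )
  training_phase(name, which(sel), build_phase_masks(input_block, output_block, lay))
}

# resolve beta = "auto" against the stacked dimension
.resolve_beta <- function(config, D) {
  if (identical(config$beta, "auto")) 1 / D else config$beta
}

.adam_init <- function(params) {
  nm <- setdiff(names(params), "dims")
  list(
    m = lapply(params[nm], function(p) p * 0),
    v = lapply(params[nm], function(p) p * 0),
    t = 0L
  )
}

.adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

#' Train the masked conditional VAE over a phase schedule
#'
#' Each epoch cycles through all phases in the listed order; within a phase,
#' the phase's cells are shuffled and consumed in minibatches, each step
#' computing the masked loss `recon + beta * kl + gamma * cls` and applying
#' an Adam update from the analytic gradients. All randomness (initial
#' weights, shuffling, reparameterization noise) flows from `seed`, so runs
#' are reproducible on a single-threaded BLAS.
#'
#' @param dataset A [stacked_dataset()] (typically from [bind_datasets()]).
#' @param phases List of [training_phase()] objects.
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @param n_clusters Classifier width `K`; defaults to the number of label
#'   levels when labels are present, else must be given.
#' @param verbose Print per-epoch losses.
#' @return A `mosaic_fit`: list with `params`, `config` (with `beta`
#'   resolved), `history` (tibble: epoch, phase, recon, kl, cls, total),
#'   `layout`, `n_clusters`, `label_levels`, `seed`.
#' @export
fit_mosaic <- function(dataset, phases, config = model_config(), seed = 1L,
                       n_clusters = NULL, verbose = FALSE) {
  if (!inherits(dataset, "stacked_dataset")) abort("`dataset` must be a stacked_dataset.")
  if (!length(phases)) abort("At least one training phase is required.")
  for (ph in phases) {
    if (!inherits(ph, "training_phase")) abort("`phases` must be training_phase objects.")
    if (max(ph$cells) > n_cells(dataset)) {
      abort(sprintf("Phase '%s' selects cells beyond the dataset.", ph$name))
    }
  }
  D <- n_features(dataset$layout)
  n_cov <- max(dataset$covariate)
  K <- n_clusters %||%
    (if (length(dataset$label_levels)) length(dataset$label_levels) else
      abort("`n_clusters` must be given for a fully unlabeled dataset."))
  K <- as.integer(K)
  beta_final <- .resolve_beta(config, D)

  set.seed(seed)
  params <- init_params(D, n_cov, K, config, seed = NULL)
  opt <- .adam_init(params)
  hist <- vector("list", config$epochs * length(phases))
  hi <- 0L

  for (epoch in seq_len(config$epochs)) {
    beta <- if (config$beta_warmup > 0 && epoch <= config$beta_warmup) {
      beta_final * epoch / config$beta_warmup
    } else {
      beta_final
    }
    for (ph in phases) {
      cells <- ph$cells[sample.int(length(ph$cells))]
      nb <- ceiling(length(cells) / config$batch_size)
      acc <- c(recon = 0, kl = 0, cls = 0, total = 0)
      for (b in seq_len(nb)) {
        idx <- cells[((b - 1L) * config$batch_size + 1L):min(b * config$batch_size, length(cells))]
        lg <- loss_and_grads(
          params, dataset$X[idx, , drop = FALSE],
          ph$masks$input_mask, ph$masks$output_mask,
          dataset$covariate[idx], dataset$labels[idx],
          beta = beta, gamma = config$gamma, mode = config$arithmetic
        )
        if (!is.finite(lg$loss$total)) {
          abort(sprintf(
            "Non-finite loss in phase '%s', epoch %d, step %d (recon=%.3g, kl=%.3g, cls=%.3g).",
            ph$name, epoch, b, lg$loss$recon, lg$loss$kl, lg$loss$cls
          ))
        }
        st <- .adam_step(params, lg$grads, opt, config$lr)
        params <- st$params; opt <- st$state
        acc <- acc + unlist(lg$loss)
      }
      hi <- hi + 1L
      hist[[hi]] <- tibble(
        epoch = epoch, phase = ph$name,
        recon = acc[["recon"]] / nb, kl = acc[["kl"]] / nb,
        cls = acc[["cls"]] / nb, total = acc[["total"]] / nb
      )
    }
    if (verbose && (epoch %% 10 == 0 || epoch == 1)) {
      last <- hist[[hi]]
      message(sprintf("epoch %3d  total %.4f (recon %.4f, kl %.4f, cls %.4f)",
                      epoch, last$total, last$recon, last$kl, last$cls))
    }
  }

  cfg <- config
  cfg$beta <- beta_final
  structure(
    list(params = params, config = cfg, history = dplyr::bind_rows(hist),
         layout = dataset$layout, n_clusters = K,
         label_levels = dataset$label_levels, seed = seed),
    class = "mosaic_fit"
  )
}

#' @export
print.mosaic_fit <- function(x, ...) {
  last <- utils::tail(x$history, length(unique(x$history$phase)))
  cat(sprintf(
    "<mosaic_fit> D=%d, d_z=%d, K=%d, %d epochs x %d phase(s); final total loss %.4f\n",
    x$params$dims$D, x$params$dims$d_z, x$n_clusters,
    max(x$history$epoch), length(unique(x$history$phase)), mean(last$total)
  ))
  invisible(x)
}

#' Project cells through a fitted model (noise-free)
#'
#' Deterministic inference pass: encodes cells with a given input-mask
#' template, sets `z1 = mu` (no sampling), and returns the latent mean, the
#' covariate-free latent `z2`, classifier probabilities, cluster assignments
#' and the unmasked decoder output — the readout used for imputation and
#' cross-modal generation.
#'
#' @param fit A `mosaic_fit`.
#' @param dataset A [stacked_dataset()] on the same layout.
#' @param input_mask Length-`D` binary template (defaults to all-ones).
#' @return List with `mu`, `z2`, `probs`, `cluster`, `output` (cells x D).
#' @export
project_cells <- function(fit, dataset, input_mask = NULL) {
  D <- n_features(fit$layout)
  input_mask <- input_mask %||% rep(1, D)
  fw <- forward_pass(dataset$X, input_mask, rep(1, D), dataset$covariate,
                     fit$params, mode = fit$config$arithmetic,
                     deterministic = TRUE)
  list(
    mu = fw$state$mu, z2 = fw$state$z2, probs = fw$probs,
    cluster = max.col(fw$probs, ties.method = "first"),
    output = fw$state$output1
  )
}
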