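#' Specify a synthetic multimodal simulation
#'
#' The generator emulates the statistical structure the model assumes: every
#' cell has a latent state drawn around its cell-type mean, shifted by a
#' dataset-level batch vector; each modality observes the latent state
#' through its own random linear map followed by a softplus nonlinearity and
#' additive Gaussian noise, clipped at zero. Missingness (held-out genes or
#' whole missing modalities) is imposed afterwards by zero-filling, with the
#' withheld truth retained in a ground-truth bundle.
#'
#' @param modalities Named list; each element `list(n_features =, sigma =)`
#'   (noise standard deviation defaults to 0.1). Names become block names.
#' @param datasets List; each element
#'   `list(n_cells =, blocks = <character>, label_fraction =)` giving the
#'   modalities measured in that dataset and the fraction of cells carrying
#'   a type label (semi-supervised regime; default 0.2).
#' @param n_types Number of cell types `K` (default 5).
#' @param d_sim Latent simulation dimension (default 8).
#' @param delta_type Expected pairwise distance between type means, in units
#'   of the within-type standard deviation (default 6: well-separated major
#'   populations).
#' @param batch_shift_norm Norm of each dataset's latent shift vector
#'   (default 1: batch effects smaller than type differences).
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(modalities, datasets, n_types = 5L, d_sim = 8L,
                            delta_type = 6, batch_shift_norm = 1) {
  if (is.null(names(modalities)) || any(names(modalities) == "")) {
    abort("`modalities` must be a named list.")
  }
  modalities <- lapply(modalities, function(m) {
    list(n_features = as.integer(m$n_features), sigma = m$sigma %||% 0.1)
  })
  datasets <- lapply(datasets, function(d) {
    if (!length(d$blocks)) abort("Every dataset must measure at least one block.")
    if (length(setdiff(d$blocks, names(modalities)))) {
      abort("Dataset references unknown modality blocks.")
    }
    list(n_cells = as.integer(d$n_cells), blocks = d$blocks,
         label_fraction = d$label_fraction %||% 0.2)
  })
  if (n_types < 2) abort("`n_types` must be at least 2.")
  if (delta_type <= 0) abort("`delta_type` must be positive.")
  structure(
    list(modalities = modalities, datasets = datasets,
         n_types = as.integer(n_types), d_sim = as.integer(d_sim),
         delta_type = delta_type, batch_shift_norm = batch_shift_norm),
    class = "simulation_spec"
  )
}

#' Simulate multimodal datasets with known ground truth
#'
#' Draws cell latent states `z_c ~ N(mean[type] + shift[dataset], I)`,
#' observes each modality as `softplus(A_m z_c) + noise` clipped at zero,
#' zero-fills blocks a dataset does not measure, and returns both the
#' observable [stacked_dataset()]s and a truth bundle holding the complete
#' (pre-missingness) matrices, type labels and latent states.
#'
#' @param spec A [simulation_spec()].
#' @param seed Integer seed; the same seed reproduces the fixture exactly.
#' @return List with `datasets` (list of `stacked_dataset` on the full
#'   layout, with unmeasured blocks zero-filled and flagged unavailable) and
#'   `truth` (list: per-dataset `full` matrices, `type`, `batch`, `latent`,
#'   `type_means`, `batch_shifts`, loading matrices `A`).
#' @export
simulate_multimodal <- function(spec, seed = 1L) {
  if (!inherits(spec, "simulation_spec")) abort("`spec` must be a simulation_spec.")
  .with_seed(seed, {
    d_sim <- spec$d_sim
    K <- spec$n_types
    # type means: regular simplex with edge length delta_type, randomly
    # rotated into the simulation space, so every pair of types is exactly
    # delta_type apart (the parameter is a guaranteed, not expected, separation)
    if (K > d_sim) {
      abort("`n_types` must not exceed `d_sim` for simplex-separated type means.")
    }
    V <- (diag(K) - 1 / K) * (spec$delta_type / sqrt(2))
    Q <- qr.Q(qr(matrix(rnorm(d_sim * K), d_sim, K)))
    type_means <- V %*% t(Q)
    shifts <- t(vapply(seq_along(spec$datasets), function(i) {
      v <- rnorm(d_sim)
      v / sqrt(sum(v^2)) * spec$batch_shift_norm
    }, numeric(d_sim)))
    A <- lapply(spec$modalities, function(m) {
      matrix(rnorm(m$n_features * d_sim, sd = 1 / sqrt(d_sim)), m$n_features, d_sim)
    })
    feature_ids <- lapply(names(spec$modalities), function(nm) {
      paste0(nm, "_", seq_len(spec$modalities[[nm]]$n_features))
    })
    names(feature_ids) <- names(spec$modalities)
    kind_of <- c(rna = "expression", adt = "protein", atac = "accessibility")
    kinds <- ifelse(names(spec$modalities) %in% names(kind_of),
                    kind_of[names(spec$modalities)], "generic")
    layout <- do.call(block_layout, c(feature_ids, list(kinds = unname(kinds))))

    datasets <- list()
    truth <- list(type = list(), latent = list(), full = list())
    for (di in seq_along(spec$datasets)) {
      ds <- spec$datasets[[di]]
      n <- ds$n_cells
      type <- sample.int(K, n, replace = TRUE)
      z <- type_means[type, , drop = FALSE] +
        rep(shifts[di, ], each = n) +
        matrix(rnorm(n * d_sim), n, d_sim)
      full <- lapply(names(spec$modalities), function(nm) {
        m <- spec$modalities[[nm]]
        obs <- .softplus(z %*% t(A[[nm]]))
        if (m$sigma > 0) obs <- obs + matrix(rnorm(n * m$n_features, sd = m$sigma),
                                             n, m$n_features)
        pmax(obs, 0)
      })
      names(full) <- names(spec$modalities)

      X <- matrix(0, n, n_features(layout))
      avail <- matrix(FALSE, n, nrow(layout))
      for (nm in ds$blocks) {
        X[, block_span(layout, nm)] <- full[[nm]]
        avail[, match(nm, layout$name)] <- TRUE
      }
      labels <- rep(NA_integer_, n)
      if (ds$label_fraction > 0) {
        n_lab <- max(1L, round(ds$label_fraction * n))
        idx_lab <- sample.int(n, n_lab)
        labels[idx_lab] <- type[idx_lab]
      }
      lab_factor <- factor(paste0("type", labels), levels = paste0("type", seq_len(K)))
      datasets[[di]] <- stacked_dataset(
        X, layout, covariate = rep(1L, n), labels = lab_factor, available = avail
      )
      truth$type[[di]] <- type
      truth$latent[[di]] <- z
      truth$full[[di]] <- full
    }
    truth$type_means <- type_means
    truth$batch_shifts <- shifts
    truth$A <- A
    truth$layout <- layout
    list(datasets = datasets, truth = truth)
  })
}

#' Packaged fixtures for the three benchmark scenarios
#'
#' Builds the seeded synthetic fixture matching each workflow:
#' * `fig2` — two unpaired expression datasets sharing 80% of genes; the
#'   query's remaining 20% are withheld for imputation.
#' * `fig4` — tri-modal: dataset 1 measures expression + protein, dataset 2
#'   protein + accessibility; protein is the shared bridge; each dataset has
#'   its own latent batch shift.
#' * `fig6` — two fully labeled expression + protein references plus one
#'   unlabeled expression-only query whose protein is withheld.
#'
#' @param scenario `"fig2"`, `"fig4"` or `"fig6"`.
#' @param size `"tiny"` (300 cells/dataset, CI-sized) or `"small"`
#'   (2000 cells/dataset).
#' @param seed Integer seed.
#' @return List with `datasets`, `truth`, and scenario metadata
#'   (`common_idx`/`specific_idx` for fig2; `query` index for fig6).
#' @export
make_fixture <- function(scenario = c("fig2", "fig4", "fig6"),
                         size = c("tiny", "small"), seed = 1L) {
  scenario <- match.arg(scenario)
  size <- match.arg(size)
  n <- if (size == "tiny") 300L else 2000L
  small <- size == "small"

  if (scenario == "fig2") {
    G <- if (small) 100L else 50L
    spec <- simulation_spec(
      modalities = list(rna = list(n_features = G)),
      datasets = list(
        list(n_cells = n, blocks = "rna"),
        list(n_cells = n, blocks = "rna")
      )
    )
    sim <- simulate_multimodal(spec, seed = seed)
    # withhold a random 20% of genes from the query (dataset 2)
    idx <- .with_seed(seed + 1000L, sample.int(G, round(0.2 * G)))
    specific_idx <- sort(idx)
    common_idx <- setdiff(seq_len(G), specific_idx)
    query <- sim$datasets[[2]]
    query$X[, specific_idx] <- 0
    sim$scenario <- list(common_idx = common_idx, specific_idx = specific_idx)
    sim$datasets[[2]] <- query
    return(sim)
  }

  if (scenario == "fig4") {
    spec <- simulation_spec(
      modalities = list(
        rna = list(n_features = if (small) 100L else 40L),
        adt = list(n_features = if (small) 30L else 15L),
        atac = list(n_features = if (small) 100L else 40L)
      ),
      datasets = list(
        list(n_cells = n, blocks = c("rna", "adt")),
        list(n_cells = n, blocks = c("adt", "atac"))
      )
    )
    return(simulate_multimodal(spec, seed = seed))
  }

  # fig6: 2 labeled multimodal references + 1 unlabeled monomodal query
  spec <- simulation_spec(
    modalities = list(
      rna = list(n_features = if (small) 100L else 40L),
      adt = list(n_features = if (small) 30L else 15L)
    ),
    datasets = list(
      list(n_cells = n, blocks = c("rna", "adt"), label_fraction = 1),
      list(n_cells = n, blocks = c("rna", "adt"), label_fraction = 1),
      list(n_cells = n, blocks = "rna", label_fraction = 0)
    )
  )
  sim <- simulate_multimodal(spec, seed = seed)
  sim$scenario <- list(query = 3L)
  sim
}
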