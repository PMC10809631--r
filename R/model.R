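#' Model configuration defaults
#'
#' Hyperparameters of the masked conditional VAE and its trainer. Hidden
#' widths default to values sized for stacked feature spaces of a few hundred
#' features; all are configurable.
#'
#' @param h1,h2 Encoder hidden widths (input -> h1 -> h2).
#' @param d_z Latent dimension.
#' @param h3 Decoder hidden width (d_z -> h3 -> output).
#' @param beta KL weight. `"auto"` (default) uses `1 / D_total`, which puts
#'   the per-position mean reconstruction error and the per-cell KL (summed
#'   over latent dimensions) on comparable scales.
#' @param gamma Weight of the semi-supervised classification loss.
#' @param beta_warmup Number of initial epochs over which beta ramps linearly
#'   from 0 to its final value (0 disables warm-up).
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs (each epoch cycles through all phases).
#' @param arithmetic `"subtract"` (covariate removal, default) or `"add"`.
#'
#' @return A named list of class `mosaic_config`.
#' @export
model_config <- function(h1 = 256L, h2 = 128L, d_z = 32L, h3 = 128L,
                         beta = "auto", gamma = 1, beta_warmup = 0L,
                         lr = 1e-3, batch_size = 256L, epochs = 100L,
                         arithmetic = c("subtract", "add")) {
  arithmetic <- match.arg(arithmetic)
  if (!identical(beta, "auto") && (!is.numeric(beta) || beta < 0)) {
    abort("`beta` must be \"auto\" or a nonnegative number.")
  }
  structure(
    list(h1 = as.integer(h1), h2 = as.integer(h2), d_z = as.integer(d_z),
         h3 = as.integer(h3), beta = beta, gamma = gamma,
         beta_warmup = as.integer(beta_warmup), lr = lr,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         arithmetic = arithmetic),
    class = "mosaic_config"
  )
}

#' Initialize model parameters
#'
#' Creates all weight matrices and biases of the masked conditional VAE:
#' two encoder layers (`W1`, `W2`), the linear latent heads for the mean
#' (`Wmu`) and the log standard deviation (`Wls`), the covariate embedding
#' table (`WE`), two decoder layers (`W3`, `Wout`) and the classifier (`WC`).
#' Dense weights use scaled-Gaussian (He) initialization; biases start at 0;
#' the embedding table starts at 0 so covariate correction begins neutral.
#'
#' @param D Total stacked feature dimension.
#' @param n_cov Number of covariate levels.
#' @param K Number of classifier clusters.
#' @param config A [model_config()].
#' @param seed Integer seed for the initial draw.
#' @return A named list of class `mosaic_params` with elements
#'   `W1,b1,W2,b2,Wmu,bmu,Wls,bls,WE,W3,b3,Wout,bout,WC,bC` and `dims`.
#' @export
init_params <- function(D, n_cov, K, config = model_config(), seed = 1L) {
  he <- function(n_in, n_out) {
    matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
  }
  .with_seed(seed, {
    p <- list(
      W1 = he(D, config$h1),          b1 = numeric(config$h1),
      W2 = he(config$h1, config$h2),  b2 = numeric(config$h2),
      Wmu = he(config$h2, config$d_z), bmu = numeric(config$d_z),
      Wls = 0.1 * he(config$h2, config$d_z), bls = numeric(config$d_z),
      WE = matrix(0, n_cov, config$d_z),
      W3 = he(config$d_z, config$h3), b3 = numeric(config$h3),
      Wout = he(config$h3, D),        bout = numeric(D),
      WC = he(config$d_z, K),         bC = numeric(K),
      dims = list(D = as.integer(D), h1 = config$h1, h2 = config$h2,
                  d_z = config$d_z, h3 = config$h3, K = as.integer(K),
                  n_cov = as.integer(n_cov))
    )
    class(p) <- "mosaic_params"
    p
  })
}

#' Mask modules: elementwise gating of input and output
#'
#' The input mask is multiplied elementwise with the data batch before the
#' encoder so only the selected features contribute to encoding; the output
#' mask is multiplied with the decoder output so only the selected features
#' contribute to the reconstruction loss. Masks are binary and either a full
#' matrix matching the batch or a length-`D` template row broadcast over cells.
#'
#' @param x Numeric matrix (cells x features) to gate.
#' @param mask Binary matrix of the same shape, or a length-`ncol(x)` vector.
#' @return The gated matrix `x * mask`.
#' @examples
#' apply_input_mask(matrix(1:6, 2), c(1, 0, 1))
#' @export
apply_input_mask <- function(x, mask) {
  x <- .as_row_matrix(x)
  if (!is.matrix(mask)) {
    if (length(mask) != ncol(x)) {
      abort(sprintf(
        "Shape mismatch: `x` is %dx%d but `mask` template has length %d.",
        nrow(x), ncol(x), length(mask)
      ))
    }
    return(.mask_cols(x, mask))
  }
  .check_same_shape(x, mask, "x", "mask")
  x * mask
}

#' @rdname apply_input_mask
#' @export
apply_output_mask <- function(x, mask) {
  apply_input_mask(x, mask)
}

#' Encoder: two relu layers over the masked input
#'
#' `h2 = relu(W2 %*% relu(W1 %*% x_in + b1) + b2)` (row-major convention:
#' cells are rows, so the code computes `x_in %*% W1` etc.).
#'
#' @param x_in Masked input batch (cells x D).
#' @param params A [init_params()] object.
#' @return The second hidden layer `h2` (cells x h2), all entries >= 0.
#' @export
encode <- function(x_in, params) {
  x_in <- .as_row_matrix(x_in)
  .check_matrix(x_in, "x_in")
  if (ncol(x_in) != params$dims$D) {
    abort(sprintf("`x_in` has %d columns; model expects %d.", ncol(x_in), params$dims$D))
  }
  h1 <- .relu(x_in %*% params$W1 + rep(params$b1, each = nrow(x_in)))
  .relu(h1 %*% params$W2 + rep(params$b2, each = nrow(x_in)))
}

#' Latent heads: posterior mean and log standard deviation
#'
#' Linear (activation-free) heads on `h2`. The second head is interpreted as
#' `log(sigma)` and exponentiated at sampling time, so the sampled scale is
#' always positive; with both heads at zero the posterior is N(0, I).
#'
#' @param h2 Encoder output (cells x h2).
#' @param params A [init_params()] object.
#' @return A list with matrices `mu` and `log_sigma` (cells x d_z).
#' @export
estimate_latent_params <- function(h2, params) {
  h2 <- .as_row_matrix(h2)
  n <- nrow(h2)
  list(
    mu = h2 %*% params$Wmu + rep(params$bmu, each = n),
    log_sigma = h2 %*% params$Wls + rep(params$bls, each = n)
  )
}

#' Reparameterization trick
#'
#' Draws `eps ~ N(0, I)` and returns `z1 = mu + exp(log_sigma) * eps`.
#' With `seed` supplied the draw is reproducible and the caller's RNG state
#' is untouched; with `seed = NULL` the current RNG stream is consumed
#' (as during training).
#'
#' @param mu,log_sigma Matrices (cells x d_z).
#' @param seed Optional integer seed.
#' @return A list with `z1` and `eps`.
#' @export
reparameterize <- function(mu, log_sigma, seed = NULL) {
  mu <- .as_row_matrix(mu); log_sigma <- .as_row_matrix(log_sigma)
  .check_same_shape(mu, log_sigma, "mu", "log_sigma")
  eps <- .with_seed(seed, matrix(rnorm(length(mu)), nrow(mu), ncol(mu)))
  list(z1 = mu + exp(log_sigma) * eps, eps = eps)
}

#' Covariate embedding lookup
#'
#' Embeds integer covariate codes (batch / dataset of origin) into the latent
#' space: row `c` of the learned table `WE` for a cell with code `c`
#' (one-hot times table semantics).
#'
#' @param codes Integer codes in `1..n_cov`, one per cell.
#' @param params A [init_params()] object.
#' @return Matrix `E` (cells x d_z).
#' @export
embed_covariates <- function(codes, params) {
  codes <- as.integer(codes)
  n_cov <- params$dims$n_cov
  bad <- which(is.na(codes) | codes < 1L | codes > n_cov)
  if (length(bad)) {
    abort(sprintf(
      "Covariate code %s out of range [1, %d].",
      paste(unique(codes[bad]), collapse = ", "), n_cov
    ))
  }
  params$WE[codes, , drop = FALSE]
}

#' Latent vector arithmetic
#'
#' Subtracts (or adds) the covariate embedding from the posterior mean:
#' `z2 = mu - E` removes the covariate content and is the representation used
#' for clustering and integration; `mu + E` mixes it back in.
#'
#' @param mu Posterior means (cells x d_z).
#' @param E Covariate embeddings (cells x d_z).
#' @param mode `"subtract"` (default) or `"add"`.
#' @return Matrix `z2`.
#' @export
vector_arithmetic <- function(mu, E, mode = c("subtract", "add")) {
  mode <- match.arg(mode)
  mu <- .as_row_matrix(mu); E <- .as_row_matrix(E)
  .check_same_shape(mu, E, "mu", "E")
  if (mode == "subtract") mu - E else mu + E
}

#' Classifier over the covariate-free latent
#'
#' `probs = softmax(WC %*% z2 + bC)` rowwise. Cluster assignment is the
#' argmax row-wise; with labels on a subset of cells the same head is the
#' semi-supervised classification output.
#'
#' @param z2 Covariate-free latent (cells x d_z).
#' @param params A [init_params()] object.
#' @return Matrix of probabilities (cells x K); rows sum to 1.
#' @export
classify <- function(z2, params) {
  z2 <- .as_row_matrix(z2)
  .row_softmax(z2 %*% params$WC + rep(params$bC, each = nrow(z2)))
}

#' Decoder: two relu layers back to the stacked feature space
#'
#' `output1 = relu(Wout %*% relu(W3 %*% z1 + b3) + bout)`; nonnegative by
#' construction, matching nonnegative expression/abundance inputs.
#'
#' @param z1 Sampled latent (cells x d_z).
#' @param params A [init_params()] object.
#' @return Reconstruction (cells x D), entries >= 0.
#' @export
decode <- function(z1, params) {
  z1 <- .as_row_matrix(z1)
  n <- nrow(z1)
  d1 <- .relu(z1 %*% params$W3 + rep(params$b3, each = n))
  .relu(d1 %*% params$Wout + rep(params$bout, each = n))
}

#' Full forward pass of the masked conditional VAE
#'
#' Composes mask -> encode -> latent heads -> reparameterize -> decode ->
#' output mask on the reconstruction branch, and covariate embedding ->
#' vector arithmetic -> classifier on the clustering branch. All intermediates
#' are returned for loss computation and inspection.
#'
#' @param x Data batch (cells x D).
#' @param input_mask,output_mask Binary masks (matrix matching `x`, or
#'   length-`D` template rows).
#' @param covariate Integer codes, one per row of `x`.
#' @param params A [init_params()] object.
#' @param mode Vector-arithmetic mode, `"subtract"` or `"add"`.
#' @param seed Optional seed for the `eps` draw.
#' @param deterministic If `TRUE`, skip sampling and set `z1 = mu`, `eps = 0`
#'   (the noise-free pass used for imputation/generation readout).
#' @return A list with `output` (masked reconstruction), `probs`, and
#'   `state`: a list holding `mu`, `log_sigma`, `eps`, `z1`, `E`, `z2`,
#'   `h2` and the unmasked `output1`.
#' @export
forward_pass <- function(x, input_mask, output_mask, covariate, params,
                         mode = c("subtract", "add"), seed = NULL,
                         deterministic = FALSE) {
  mode <- match.arg(mode)
  x <- .as_row_matrix(x)
  x_in <- apply_input_mask(x, input_mask)
  h2 <- encode(x_in, params)
  lp <- estimate_latent_params(h2, params)
  if (deterministic) {
    eps <- matrix(0, nrow(lp$mu), ncol(lp$mu))
    z1 <- lp$mu
  } else {
    rp <- reparameterize(lp$mu, lp$log_sigma, seed = seed)
    eps <- rp$eps; z1 <- rp$z1
  }
  output1 <- decode(z1, params)
  output <- apply_output_mask(output1, output_mask)
  E <- embed_covariates(covariate, params)
  z2 <- vector_arithmetic(lp$mu, E, mode)
  probs <- classify(z2, params)
  list(
    output = output, probs = probs,
    state = list(mu = lp$mu, log_sigma = lp$log_sigma, eps = eps, z1 = z1,
                 E = E, z2 = z2, h2 = h2, output1 = output1)
  )
}
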