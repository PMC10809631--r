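#' Loss and analytic parameter gradients for one minibatch
#'
#' Runs the forward pass and hand-derived backward pass of the full objective
#' `total = recon + beta * kl + gamma * cls` and returns both the loss
#' breakdown and the gradient of every parameter. The reconstruction branch
#' backpropagates through the output mask (masked positions send no signal to
#' the decoder) and the input mask zeroes the signal into the corresponding
#' first-layer columns; the classification branch backpropagates through the
#' covariate arithmetic into the embedding table.
#'
#' @param params A [init_params()] object.
#' @param x Data batch (cells x D); also the reconstruction target.
#' @param input_mask,output_mask Length-`D` binary templates (or matrices
#'   matching the batch).
#' @param covariate Integer codes per row.
#' @param labels Integer labels in `1..K` with `NA` for unlabeled cells, or
#'   `NULL` for a fully unlabeled batch.
#' @param beta,gamma Loss weights.
#' @param mode Vector-arithmetic mode.
#' @param eps Optional pre-drawn noise matrix (cells x d_z); by default drawn
#'   from the current RNG stream.
#' @return A list with `loss` (named list `recon`, `kl`, `cls`, `total`) and
#'   `grads` (named list matching the parameter fields).
#' @export
loss_and_grads <- function(params, x, input_mask, output_mask, covariate,
                           labels = NULL, beta = 1, gamma = 1,
                           mode = c("subtract", "add"), eps = NULL) {
  mode <- match.arg(mode)
  x <- .as_row_matrix(x)
  n <- nrow(x)
  d <- params$dims
  if (is.null(labels)) labels <- rep(NA_integer_, n)
  labels <- as.integer(labels)

  m_in <- if (is.matrix(input_mask)) input_mask else
    matrix(input_mask, n, d$D, byrow = TRUE)
  m_out <- if (is.matrix(output_mask)) output_mask else
    matrix(output_mask, n, d$D, byrow = TRUE)

  ## ---- forward ----
  x_in <- x * m_in
  h1a <- x_in %*% params$W1 + rep(params$b1, each = n)
  h1 <- .relu(h1a)
  h2a <- h1 %*% params$W2 + rep(params$b2, each = n)
  h2 <- .relu(h2a)
  mu <- h2 %*% params$Wmu + rep(params$bmu, each = n)
  ls <- h2 %*% params$Wls + rep(params$bls, each = n)
  if (is.null(eps)) eps <- matrix(rnorm(n * d$d_z), n, d$d_z)
  sig <- exp(ls)
  z1 <- mu + sig * eps
  d1a <- z1 %*% params$W3 + rep(params$b3, each = n)
  d1 <- .relu(d1a)
  oa <- d1 %*% params$Wout + rep(params$bout, each = n)
  o1 <- .relu(oa)

  E <- params$WE[covariate, , drop = FALSE]
  z2 <- if (mode == "subtract") mu - E else mu + E
  logits <- z2 %*% params$WC + rep(params$bC, each = n)
  probs <- .row_softmax(logits)

  n_sup <- sum(m_out)
  if (n_sup == 0) abort("Output mask is all-zero: no supervised positions.")
  resid <- m_out * (o1 - x)
  recon <- sum(resid^2) / n_sup
  kl <- mean(rowSums(0.5 * (sig^2 + mu^2 - 1 - 2 * ls)))

  lab <- which(!is.na(labels))
  if (length(lab)) {
    p_true <- probs[cbind(lab, labels[lab])]
    cls <- mean(-log(pmax(p_true, 1e-12)))
  } else {
    cls <- 0
  }
  total <- recon + beta * kl + gamma * cls

  ## ---- backward ----
  # reconstruction branch
  g_o1 <- 2 * resid / n_sup
  g_oa <- g_o1 * (oa > 0)
  gWout <- crossprod(d1, g_oa)
  gbout <- colSums(g_oa)
  g_d1 <- g_oa %*% t(params$Wout)
  g_d1a <- g_d1 * (d1a > 0)
  gW3 <- crossprod(z1, g_d1a)
  gb3 <- colSums(g_d1a)
  g_z1 <- g_d1a %*% t(params$W3)

  # KL
  g_mu <- g_z1 + beta * mu / n
  g_ls <- g_z1 * eps * sig + beta * (sig^2 - 1) / n

  # classification branch
  if (length(lab) && gamma != 0) {
    g_logits <- matrix(0, n, d$K)
    g_logits[lab, ] <- probs[lab, , drop = FALSE] * (gamma / length(lab))
    g_logits[cbind(lab, labels[lab])] <-
      g_logits[cbind(lab, labels[lab])] - gamma / length(lab)
    gWC <- crossprod(z2, g_logits)
    gbC <- colSums(g_logits)
    g_z2 <- g_logits %*% t(params$WC)
  } else {
    gWC <- matrix(0, d$d_z, d$K)
    gbC <- numeric(d$K)
    g_z2 <- matrix(0, n, d$d_z)
  }
  g_mu <- g_mu + g_z2
  g_E <- if (mode == "subtract") -g_z2 else g_z2
  gWE <- matrix(0, d$n_cov, d$d_z)
  acc <- rowsum(g_E, group = covariate)
  gWE[as.integer(rownames(acc)), ] <- acc

  # into the encoder
  g_h2 <- g_mu %*% t(params$Wmu) + g_ls %*% t(params$Wls)
  gWmu <- crossprod(h2, g_mu)
  gbmu <- colSums(g_mu)
  gWls <- crossprod(h2, g_ls)
  gbls <- colSums(g_ls)
  g_h2a <- g_h2 * (h2a > 0)
  gW2 <- crossprod(h1, g_h2a)
  gb2 <- colSums(g_h2a)
  g_h1 <- g_h2a %*% t(params$W2)
  g_h1a <- g_h1 * (h1a > 0)
  gW1 <- crossprod(x_in, g_h1a)
  gb1 <- colSums(g_h1a)

  list(
    loss = list(recon = recon, kl = kl, cls = cls, total = total),
    grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                 Wmu = gWmu, bmu = gbmu, Wls = gWls, bls = gbls,
                 WE = gWE, W3 = gW3, b3 = gb3, Wout = gWout, bout = gbout,
                 WC = gWC, bC = gbC)
  )
}
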