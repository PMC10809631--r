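#' Masked mean-squared reconstruction loss
#'
#' Mean squared error over positions where the output mask is 1; masked
#' positions contribute nothing and the denominator is the count of unmasked
#' positions, so the loss is a per-supervised-position average.
#'
#' @param target Target batch (cells x D), zero-filled at unobserved features.
#' @param output Decoder output after output masking (cells x D).
#' @param output_mask Binary matrix matching the batch, or length-`D` template.
#' @return Scalar loss.
#' @export
masked_recon_loss <- function(target, output, output_mask) {
  target <- .as_row_matrix(target); output <- .as_row_matrix(output)
  .check_same_shape(target, output, "target", "output")
  if (!is.matrix(output_mask)) {
    output_mask <- matrix(output_mask, nrow(target), ncol(target), byrow = TRUE)
  }
  .check_same_shape(target, output_mask, "target", "output_mask")
  n_sup <- sum(output_mask)
  if (n_sup == 0) abort("Output mask is all-zero: no supervised positions.")
  sum(output_mask * (target - output)^2) / n_sup
}

#' KL divergence of the diagonal-Gaussian posterior from N(0, I)
#'
#' Mean over cells of `0.5 * sum_d (exp(2 log_sigma) + mu^2 - 1 - 2 log_sigma)`.
#'
#' @param mu,log_sigma Posterior parameters (cells x d_z).
#' @return Scalar KL value, >= 0.
#' @export
kl_divergence <- function(mu, log_sigma) {
  mu <- .as_row_matrix(mu); log_sigma <- .as_row_matrix(log_sigma)
  .check_same_shape(mu, log_sigma, "mu", "log_sigma")
  mean(rowSums(0.5 * (exp(2 * log_sigma) + mu^2 - 1 - 2 * log_sigma)))
}

#' Semi-supervised classification loss
#'
#' Categorical cross-entropy averaged over labeled cells; unlabeled cells
#' (`NA` label) contribute zero. A batch without any labeled cell yields 0.
#'
#' @param probs Classifier probabilities (cells x K).
#' @param labels Integer labels in `1..K`, `NA` for unlabeled cells.
#' @return Scalar loss.
#' @export
classification_loss <- function(probs, labels) {
  probs <- .as_row_matrix(probs)
  labels <- as.integer(labels)
  if (length(labels) != nrow(probs)) abort("One label (or NA) per row required.")
  lab <- which(!is.na(labels))
  if (!length(lab)) return(0)
  if (any(labels[lab] < 1L | labels[lab] > ncol(probs))) {
    abort(sprintf("Labels must lie in [1, %d].", ncol(probs)))
  }
  p <- probs[cbind(lab, labels[lab])]
  mean(-log(pmax(p, 1e-12)))
}
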