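#' Per-feature correlation summaries between predicted and true profiles
#'
#' Computes, feature by feature across cells, the Pearson and Spearman
#' correlations between a predicted matrix (imputed or generated values) and
#' the ground truth, and summarizes them as median and average over features
#' (mPCC/aPCC, mSCC/aSCC). Features with zero variance in either matrix have
#' no defined correlation: they are excluded from the summaries and counted.
#'
#' @param truth,pred Numeric matrices, cells x features, equal shapes,
#'   at least 3 cells.
#' @return A `correlation_summary`: list with `per_feature` (tibble:
#'   feature, pcc, scc), `excluded` (character vector of dropped features),
#'   and scalars `mpcc`, `apcc`, `mscc`, `ascc`.
#' @export
correlation_suite <- function(truth, pred) {
  truth <- as.matrix(truth); pred <- as.matrix(pred)
  .check_same_shape(truth, pred, "truth", "pred")
  if (nrow(truth) < 3) abort("At least 3 cells are required.")
  feats <- colnames(truth) %||% paste0("f", seq_len(ncol(truth)))
  sd_t <- apply(truth, 2, stats::sd)
  sd_p <- apply(pred, 2, stats::sd)
  keep <- sd_t > 0 & sd_p > 0
  if (any(!keep)) {
    warn(sprintf(
      "%d feature(s) with zero variance excluded from correlation summaries: %s",
      sum(!keep), paste(head(feats[!keep], 5), collapse = ", ")
    ))
  }
  if (!any(keep)) abort("No feature has nonzero variance in both matrices.")
  pcc <- unname(vapply(which(keep), function(j)
    cor(truth[, j], pred[, j]), numeric(1)))
  scc <- unname(vapply(which(keep), function(j)
    cor(truth[, j], pred[, j], method = "spearman"), numeric(1)))
  structure(
    list(
      per_feature = tibble(feature = feats[keep], pcc = pcc, scc = scc),
      excluded = feats[!keep],
      mpcc = median(pcc), apcc = mean(pcc),
      mscc = median(scc), ascc = mean(scc)
    ),
    class = "correlation_summary"
  )
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf(
    "<correlation_summary> %d features (%d excluded)\n  mPCC %.3f  aPCC %.3f  mSCC %.3f  aSCC %.3f\n",
    nrow(x$per_feature), length(x$excluded), x$mpcc, x$apcc, x$mscc, x$ascc
  ))
  invisible(x)
}

#' k-nearest-neighbour batch entropy of an embedding
#'
#' Measures how well batches mix in an embedding: for a random subsample of
#' cells, the Shannon entropy of the batch composition among each cell's k
#' nearest Euclidean neighbours, normalized by `log(n_batches)` and averaged.
#' 1 means every neighbourhood reflects the global batch mixture (perfect
#' mixing); 0 means neighbourhoods are single-batch. Invariant under global
#' rotation and translation of the embedding.
#'
#' @param Z Embedding matrix, cells x dims.
#' @param batch Batch codes (factor/integer/character), one per cell.
#' @param k Number of neighbours (default 30).
#' @param n_subsample Cells scored per repeat (default 100).
#' @param n_repeat Number of subsampling repeats (default 10).
#' @param seed Integer seed for the subsampling.
#' @return Scalar in `[0, 1]`.
#' @export
batch_entropy <- function(Z, batch, k = 30L, n_subsample = 100L,
                          n_repeat = 10L, seed = 1L) {
  Z <- as.matrix(Z)
  batch <- as.integer(factor(batch))
  n <- nrow(Z)
  if (length(batch) != n) abort("One batch code per cell required.")
  nb <- max(batch)
  if (nb < 2) abort("Batch entropy needs at least 2 batches.")
  if (k >= n) abort(sprintf("`k` (%d) must be smaller than the cell count (%d).", k, n))
  sq <- rowSums(Z^2)
  .with_seed(seed, {
    per_repeat <- vapply(seq_len(n_repeat), function(r) {
      sub <- sample.int(n, min(n_subsample, n))
      d2 <- outer(sq[sub], sq, "+") - 2 * Z[sub, , drop = FALSE] %*% t(Z)
      ent <- vapply(seq_along(sub), function(i) {
        ord <- order(d2[i, ])
        nn <- setdiff(ord, sub[i])[seq_len(k)]
        p <- tabulate(batch[nn], nbins = nb) / k
        p <- p[p > 0]
        -sum(p * log(p))
      }, numeric(1))
      mean(ent)
    }, numeric(1))
    mean(per_repeat) / log(nb)
  })
}

#' Normalized mean silhouette coefficient
#'
#' Mean silhouette width over cells (Euclidean distances) for a labeling,
#' rescaled from `[-1, 1]` to `[0, 1]` as `(s + 1) / 2`, so 1 indicates
#' perfectly separated label groups and 0.5 indicates no structure. Cells in
#' singleton label groups have silhouette width 0.
#'
#' @param Z Embedding matrix, cells x dims.
#' @param labels Group labels, one per cell; at least 2 distinct.
#' @return Scalar in `[0, 1]`.
#' @export
silhouette_norm <- function(Z, labels) {
  Z <- as.matrix(Z)
  labels <- as.integer(factor(labels))
  if (length(labels) != nrow(Z)) abort("One label per cell required.")
  if (max(labels) < 2) abort("Silhouette needs at least 2 distinct labels.")
  sil <- cluster::silhouette(labels, stats::dist(Z))
  (mean(sil[, "sil_width"]) + 1) / 2
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement of two partitions of the same cells; 1 for
#' identical partitions, ~0 for independent ones.
#'
#' @param labels_a,labels_b Partition labels, one per cell.
#' @return Scalar ARI.
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) abort("Partitions must have equal length.")
  mclust::adjustedRandIndex(labels_a, labels_b)
}

#' Normalized mutual information between two partitions
#'
#' Mutual information normalized by the arithmetic mean of the two marginal
#' entropies, `NMI = 2 I(A;B) / (H(A) + H(B))`; 1 for identical partitions.
#' Two trivial one-cluster partitions are defined to agree (NMI = 1).
#'
#' @param labels_a,labels_b Partition labels, one per cell.
#' @return Scalar in `[0, 1]`.
#' @export
nmi <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) abort("Partitions must have equal length.")
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij)
  p_j <- colSums(pij)
  nz <- pij > 0
  I <- sum(pij[nz] * log(pij[nz] / outer(pi_, p_j)[nz]))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  denom <- ent(pi_) + ent(p_j)
  if (denom == 0) return(1)
  2 * I / denom
}

#' Confusion matrix of transferred versus true labels
#'
#' @param truth,pred Label vectors of equal length (factors/characters/codes).
#'   `"unassigned"` predictions form their own column.
#' @return A contingency matrix with true labels as rows.
#' @export
confusion_matrix <- function(truth, pred) {
  if (length(truth) != length(pred)) abort("Label vectors must have equal length.")
  table(truth = as.character(truth), pred = as.character(pred))
}

#' Accuracy and per-class breakdown from a confusion matrix
#'
#' Overall accuracy is the trace over the total when rows and columns are
#' aligned on the union of class names (an `"unassigned"` column never
#' matches a true class and so counts as an error).
#'
#' @param confusion A contingency matrix, true labels as rows.
#' @return List with `accuracy` and `per_class` (tibble: class, n, correct,
#'   recall).
#' @export
label_accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (is.null(rownames(confusion)) || is.null(colnames(confusion))) {
    if (nrow(confusion) != ncol(confusion)) {
      abort("An unnamed confusion matrix must be square (classes aligned).")
    }
    dimnames(confusion) <- list(paste0("class", seq_len(nrow(confusion))),
                                paste0("class", seq_len(ncol(confusion))))
  }
  classes <- union(rownames(confusion), colnames(confusion))
  full <- matrix(0, length(classes), length(classes),
                 dimnames = list(classes, classes))
  full[rownames(confusion), colnames(confusion)] <- confusion
  keep <- rownames(confusion)
  correct <- unname(diag(full)[keep])
  n_class <- unname(rowSums(full)[keep])
  list(
    accuracy = sum(diag(full)) / sum(full),
    per_class = tibble(
      class = keep, n = n_class, correct = correct,
      recall = ifelse(n_class > 0, correct / n_class, NA_real_)
    )
  )
}

#' Scale-free inter-batch centroid separation
#'
#' Mean pairwise distance between batch centroids divided by the mean
#' within-batch root-mean-square spread. Comparable across spaces with
#' different units (e.g. a latent embedding versus a raw-data PCA), which is
#' how integration quality is quantified as centroid shrinkage.
#'
#' @param Z Matrix, cells x dims.
#' @param batch Batch codes, one per cell.
#' @return Scalar >= 0.
#' @export
relative_batch_distance <- function(Z, batch) {
  Z <- as.matrix(Z)
  batch <- as.integer(factor(batch))
  if (max(batch) < 2) abort("At least 2 batches required.")
  cent <- rowsum(Z, batch) / as.vector(table(batch))
  spread <- vapply(seq_len(max(batch)), function(b) {
    rows <- Z[batch == b, , drop = FALSE]
    sqrt(mean(rowSums((rows - rep(cent[b, ], each = nrow(rows)))^2)))
  }, numeric(1))
  pairs <- utils::combn(max(batch), 2)
  cd <- mean(apply(pairs, 2, function(p) sqrt(sum((cent[p[1], ] - cent[p[2], ])^2))))
  cd / mean(spread)
}
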