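# Brute-force oracles, computed here independently of the implementations.

ari_pair_oracle <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  n11 <- sum(same_a & same_b); n00 <- sum(!same_a & !same_b)
  n10 <- sum(same_a & !same_b); n01 <- sum(!same_a & same_b)
  tot <- choose(n, 2)
  expected <- (n11 + n10) * (n11 + n01) / tot
  maxi <- ((n11 + n10) + (n11 + n01)) / 2
  (n11 - expected) / (maxi - expected)
}

silhouette_oracle <- function(Z, lab) {
  n <- nrow(Z)
  d <- as.matrix(stats::dist(Z))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(lab == lab[i]); own <- setdiff(own, i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(g) mean(d[i, lab == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

test_that("correlation summaries match hand-built fixtures", {
  set.seed(1)
  truth <- matrix(rnorm(60), 20, 3)
  expect_equal(glance(correlation_suite(truth, truth))[, 1:4],
               tibble::tibble(mpcc = 1, apcc = 1, mscc = 1, ascc = 1))
  neg <- correlation_suite(truth, -truth)
  expect_true(all(neg$per_feature$pcc == -1))
  # engineered per-feature PCCs {1, 0.5, 0}: summaries are their median/mean
  n <- 4000
  z <- rnorm(n)
  mix <- function(r) r * z + sqrt(1 - r^2) * rnorm(n)
  tr <- matrix(c(z, z, z), n, 3)
  pr <- matrix(c(z, mix(0.5), mix(0)), n, 3)
  cs <- correlation_suite(tr, pr)
  expect_lt(max(abs(cs$per_feature$pcc - c(1, 0.5, 0))), 0.05)
  expect_equal(cs$apcc, mean(cs$per_feature$pcc))
  expect_equal(cs$mpcc, median(cs$per_feature$pcc))
  # zero-variance feature excluded with a warning, and counted
  tr2 <- tr; tr2[, 2] <- 3
  expect_warning(cs2 <- correlation_suite(tr2, pr), "zero variance")
  expect_equal(nrow(cs2$per_feature), 2)
  expect_equal(cs2$excluded, "f2")
})

test_that("ARI and NMI match independent oracles on 50-cell instances", {
  set.seed(7)
  for (i in 1:5) {
    a <- sample(1:4, 50, replace = TRUE)
    b <- sample(1:3, 50, replace = TRUE)
    expect_equal(ari(a, b), ari_pair_oracle(a, b), tolerance = 1e-10)
    expect_equal(nmi(a, b),
                 igraph::compare(a, b, method = "nmi"), tolerance = 1e-10)
  }
  a <- sample(1:4, 30, replace = TRUE)
  expect_equal(ari(a, a), 1)
  expect_equal(nmi(a, a), 1)
  # all-singletons vs all-in-one has zero chance-corrected agreement
  expect_equal(ari(1:4, rep(1, 4)), 0)
  # disagreeing 2x2 contingency cases against the pair-counting oracle
  expect_equal(ari(c(1, 1, 2, 2), c(1, 2, 1, 2)),
               ari_pair_oracle(c(1, 1, 2, 2), c(1, 2, 1, 2)), tolerance = 1e-10)
})

test_that("normalized silhouette matches the brute-force oracle", {
  set.seed(5)
  Z <- matrix(rnorm(100), 50, 2)
  lab <- sample(1:3, 50, replace = TRUE)
  expect_equal(silhouette_norm(Z, lab),
               (silhouette_oracle(Z, lab) + 1) / 2, tolerance = 1e-10)
  # two tight, far-apart clusters: ~1
  Z2 <- rbind(matrix(rnorm(60, 0, 0.05), 30), matrix(rnorm(60, 10, 0.05), 30))
  expect_gte(silhouette_norm(Z2, rep(1:2, each = 30)), 0.95)
  # random labels on one blob: ~0.5
  expect_equal(silhouette_norm(matrix(rnorm(200), 100, 2),
                               sample(1:2, 100, TRUE)), 0.5, tolerance = 0.06)
  # duplicated points per label, labels far apart: matches oracle exactly
  Z3 <- rbind(matrix(1, 5, 2), matrix(50, 5, 2))
  lab3 <- rep(1:2, each = 5)
  expect_equal(silhouette_norm(Z3, lab3),
               (silhouette_oracle(Z3, lab3) + 1) / 2, tolerance = 1e-10)
})

test_that("batch entropy separates mixed from separated batches", {
  set.seed(2)
  base <- matrix(rnorm(400), 200, 2)
  # duplicated-interleaved batches: near-perfect mixing
  Z <- rbind(base, base + matrix(rnorm(400, sd = 1e-3), 200, 2))
  b <- rep(1:2, each = 200)
  e_mixed <- batch_entropy(Z, b, seed = 1)
  expect_gte(e_mixed, 0.95)
  expect_lte(e_mixed, 1)
  # linearly separated batches: near-zero mixing
  Zs <- rbind(base, base + 100)
  e_sep <- batch_entropy(Zs, b, k = 30, seed = 1)
  expect_lte(e_sep, 0.05)
  expect_gte(e_sep, 0)
  # invariance under rotation + translation
  th <- 0.6
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(batch_entropy(Z %*% R + 5, b, seed = 1), e_mixed,
               tolerance = 1e-12)
  expect_error(batch_entropy(base, rep(1, 200)), "2 batches")
})

test_that("confusion accuracy is the normalized trace with class breakdown", {
  cm <- matrix(c(3, 1, 1, 3), 2, dimnames = list(c("a", "b"), c("a", "b")))
  la <- label_accuracy(cm)
  expect_equal(la$accuracy, 0.75)
  expect_equal(la$per_class$recall, c(0.75, 0.75))
  expect_equal(label_accuracy(diag(4))$accuracy, 1)
  # permuting class order together with predictions changes nothing
  cmp <- cm[c("b", "a"), c("b", "a")]
  expect_equal(label_accuracy(cmp)$accuracy, 0.75)
  # unassigned predictions count as errors
  cm2 <- confusion_matrix(c("a", "a", "b"), c("a", "unassigned", "b"))
  expect_equal(label_accuracy(cm2)$accuracy, 2 / 3)
})

test_that("relative batch distance is scale-free", {
  set.seed(8)
  Z <- rbind(matrix(rnorm(200), 100, 2), matrix(rnorm(200, mean = 3), 100, 2))
  b <- rep(1:2, each = 100)
  r1 <- relative_batch_distance(Z, b)
  expect_equal(relative_batch_distance(Z * 17, b), r1, tolerance = 1e-12)
  expect_gt(r1, 1)
})
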