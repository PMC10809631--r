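test_that("mask modules gate elementwise and leave unmasked entries exact", {
  x <- matrix(c(1, 2, 3), 1)
  expect_equal(apply_input_mask(x, c(1, 0, 1)), matrix(c(1, 0, 3), 1))
  x2 <- random_batch(5, 8)
  expect_identical(apply_input_mask(x2, rep(1, 8)), x2)
  expect_true(all(apply_output_mask(x2, rep(0, 8)) == 0))
})

test_that("encoder is relu-composed and identity-like weights pass through", {
  p <- tiny_params(D = 4)
  expect_true(all(encode(random_batch(6, 4), p) >= 0))
  expect_equal(encode(matrix(0, 2, 4), p), matrix(0, 2, 5))
  # identity weights on nonnegative input reproduce the input
  pid <- tiny_params(D = 3)
  pid$W1 <- diag(3); pid$W2 <- diag(3)
  pid$b1 <- numeric(3); pid$b2 <- numeric(3)
  pid$dims$D <- 3L; pid$dims$h1 <- 3L; pid$dims$h2 <- 3L
  x <- random_batch(4, 3)
  expect_equal(encode(x, pid), x, ignore_attr = TRUE)
  expect_error(encode(matrix(NaN, 1, 3), pid), "non-finite")
})

test_that("latent heads are linear and match a hand-computed product", {
  p <- tiny_params()
  h2 <- random_batch(3, 5, seed = 2)
  lp <- estimate_latent_params(h2, p)
  expect_equal(lp$mu, h2 %*% p$Wmu + rep(p$bmu, each = 3))
  # zero hidden state with zero biases gives mu = 0, log_sigma = 0 (sigma = 1)
  lp0 <- estimate_latent_params(matrix(0, 2, 5), p)
  expect_equal(lp0$mu, matrix(0, 2, 3))
  expect_equal(lp0$log_sigma, matrix(0, 2, 3))
  # doubling the hidden state doubles mu (bias is zero at init)
  expect_equal(estimate_latent_params(2 * h2, p)$mu, 2 * lp$mu)
  # explicit 2x2 hand oracle
  ph <- p
  ph$Wmu <- matrix(c(1, 0, 2, -1), 2, 2); ph$bmu <- c(0.5, 0)
  ph$Wls <- matrix(0, 2, 2); ph$bls <- c(0, 0)
  hh <- matrix(c(1, 2), 1, 2)
  expect_equal(estimate_latent_params(hh, ph)$mu[1, 1:2],
               c(1 * 1 + 2 * 0 + 0.5, 1 * 2 + 2 * -1))
})

test_that("reparameterization is seeded, unbiased and collapses as sigma -> 0", {
  mu <- matrix(rnorm(10), 2, 5)
  rp1 <- reparameterize(mu, matrix(-30, 2, 5), seed = 1)
  expect_equal(rp1$z1, mu, tolerance = 1e-9)
  rp2 <- reparameterize(mu, matrix(0, 2, 5), seed = 42)
  rp3 <- reparameterize(mu, matrix(0, 2, 5), seed = 42)
  expect_identical(rp2$z1, rp3$z1)
  big <- reparameterize(matrix(0, 100, 100), matrix(0, 100, 100), seed = 3)
  expect_lt(abs(mean(big$z1)), 4 / sqrt(10000))
  expect_lt(abs(stats::var(as.vector(big$z1)) - 1), 0.06)
})

test_that("covariate embedding is a table lookup with range checking", {
  p <- tiny_params(n_cov = 3)
  p$WE[1, ] <- c(0.5, -0.5, 0)
  E <- embed_covariates(c(1, 1), p)
  expect_equal(E, rbind(c(0.5, -0.5, 0), c(0.5, -0.5, 0)))
  expect_equal(embed_covariates(c(2, 2), p)[1, ], embed_covariates(2, p)[1, ])
  expect_error(embed_covariates(5, p), "out of range")
  # single covariate level: constant embedding over any batch
  p1 <- tiny_params(n_cov = 1)
  E1 <- embed_covariates(rep(1, 7), p1)
  expect_equal(E1, matrix(E1[1, ], 7, 3, byrow = TRUE))
})

test_that("vector arithmetic removes and restores the embedding", {
  mu <- random_batch(4, 3)
  E <- random_batch(4, 3, seed = 9)
  expect_equal(vector_arithmetic(mu, matrix(0, 4, 3)), mu)
  z2 <- vector_arithmetic(mu, E, "subtract")
  expect_equal(vector_arithmetic(z2, E, "add"), mu)
  expect_error(vector_arithmetic(mu, E, "divide"))
})

test_that("classifier softmax is shift-invariant and matches closed forms", {
  p <- tiny_params(K = 3)
  z2 <- random_batch(6, 3, seed = 4)
  pr <- classify(z2, p)
  expect_equal(rowSums(pr), rep(1, 6), tolerance = 1e-5)
  p0 <- p; p0$WC <- matrix(0, 3, 3); p0$bC <- numeric(3)
  expect_equal(classify(z2, p0), matrix(1 / 3, 6, 3))
  # K = 2, logits (ln 3, 0) -> (0.75, 0.25); a constant shift changes nothing
  sm <- mosaicvae:::.row_softmax
  expect_equal(sm(matrix(c(log(3), 0), 1)), matrix(c(0.75, 0.25), 1))
  lg <- matrix(rnorm(8), 2, 4)
  expect_equal(sm(lg), sm(lg + 5))
})

test_that("decoder output is nonnegative and matches a hand product", {
  p <- tiny_params()
  expect_equal(decode(matrix(0, 2, 3), p), matrix(0, 2, 10))
  set.seed(11)
  for (i in 1:20) expect_true(all(decode(matrix(rnorm(50 * 3), 50), p) >= 0))
  ph <- tiny_params()
  ph$W3 <- matrix(1, 3, 4); ph$Wout <- matrix(0.5, 4, 10)
  z <- matrix(c(1, 1, 1), 1)
  expect_equal(decode(z, ph), matrix(0.5 * 4 * 3, 1, 10))
})

test_that("forward pass composes the branches and keeps latent invariants", {
  p <- tiny_params(D = 6, n_cov = 2, K = 3)
  x <- random_batch(8, 6)
  cov <- rep(1:2, 4)
  f1 <- forward_pass(x, rep(1, 6), rep(1, 6), cov, p, seed = 5)
  f2 <- forward_pass(x, rep(1, 6), rep(1, 6), cov, p, seed = 5)
  expect_identical(f1$output, f2$output)
  st <- f1$state
  expect_equal(st$z1, st$mu + exp(st$log_sigma) * st$eps)
  expect_equal(st$z2, st$mu - st$E)
  expect_equal(rowSums(f1$probs), rep(1, 8), tolerance = 1e-5)
  expect_true(all(st$output1 >= 0))
  # property: invariants hold across random forward calls
  set.seed(6)
  for (i in 1:10) {
    xi <- matrix(abs(rnorm(3 * 6)), 3)
    m <- sample(0:1, 6, replace = TRUE)
    fi <- forward_pass(xi, m, m, sample(1:2, 3, TRUE), p, seed = i)
    expect_equal(fi$state$z1, fi$state$mu + exp(fi$state$log_sigma) * fi$state$eps)
    expect_equal(rowSums(fi$probs), rep(1, 3), tolerance = 1e-5)
  }
})
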