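test_that("plain VAE training decreases the reconstruction loss", {
  set.seed(1)
  lay <- block_layout(rna = paste0("g", 1:20))
  # structured data: two latent groups, so there is signal to compress
  grp <- rep(1:2, each = 250)
  X <- abs(matrix(rnorm(500 * 20, mean = grp), 500, 20))
  ds <- stacked_dataset(X, lay, covariate = rep(1, 500))
  ph <- training_phase("self", 1:500, build_phase_masks("rna", "rna", lay))
  fit <- fit_mosaic(ds, list(ph), tiny_config(epochs = 50, gamma = 0),
                    seed = 2, n_clusters = 2)
  h <- tidy(fit)
  early <- mean(h$recon[h$epoch <= 5])
  late <- mean(h$recon[h$epoch > 45])
  expect_lt(late, early)
  # smoothed trend: 10-epoch window means are non-increasing overall
  win <- tapply(h$recon, (h$epoch - 1) %/% 10, mean)
  expect_lt(win[length(win)], win[1])
})

test_that("the total loss is exactly the stated weighted sum, per phase row", {
  ds <- toy_dataset()
  lay <- ds$layout
  ph <- training_phase("self", 1:60, build_phase_masks("rna", "rna", lay))
  cfg <- tiny_config(epochs = 3, beta = 0.2, gamma = 1.5, batch_size = 64)
  fit <- fit_mosaic(ds, list(ph), cfg, seed = 4)
  h <- tidy(fit)
  expect_equal(h$total, h$recon + 0.2 * h$kl + 1.5 * h$cls, tolerance = 1e-12)
})

test_that("phase gradients vanish outside the phase's blocks", {
  lay <- block_layout(rna = paste0("g", 1:4), adt = paste0("p", 1:3))
  p <- init_params(7, 1, 2, model_config(h1 = 6, h2 = 4, d_z = 3, h3 = 4),
                   seed = 3)
  x <- random_batch(5, 7)
  masks <- build_phase_masks("adt", "rna", lay)
  lg <- loss_and_grads(p, x, masks$input_mask, masks$output_mask,
                       rep(1, 5), labels = NULL, beta = 0, gamma = 0,
                       eps = matrix(0, 5, 3))
  expect_equal(max(abs(lg$grads$W1[block_span(lay, "rna"), ])), 0)
  expect_equal(max(abs(lg$grads$Wout[, block_span(lay, "adt")])), 0)
  expect_gt(max(abs(lg$grads$W1[block_span(lay, "adt"), ])), 0)
})

test_that("training is reproducible from the seed", {
  ds <- toy_dataset()
  ph <- training_phase("self", 1:60,
                       build_phase_masks("rna", "rna", ds$layout))
  cfg <- tiny_config(epochs = 4, batch_size = 32)
  f1 <- fit_mosaic(ds, list(ph), cfg, seed = 9)
  f2 <- fit_mosaic(ds, list(ph), cfg, seed = 9)
  expect_equal(f1$params$W1, f2$params$W1, tolerance = 1e-14)
  expect_equal(tidy(f1), tidy(f2), tolerance = 1e-14)
  f3 <- fit_mosaic(ds, list(ph), cfg, seed = 10)
  expect_false(isTRUE(all.equal(f1$params$W1, f3$params$W1)))
})

test_that("configuration errors are caught before training", {
  ds <- toy_dataset()
  masks <- build_phase_masks("rna", "rna", ds$layout)
  expect_error(training_phase("empty", integer(0), masks), "no cells")
  bad <- masks; bad$output_mask[] <- 0
  expect_error(training_phase("dark", 1:5, bad), "all-zero")
  ph <- training_phase("self", 1:60, masks)
  expect_error(fit_mosaic(ds, list(), tiny_config()), "at least one",
               ignore.case = TRUE)
  unl <- ds; unl$labels <- rep(NA_integer_, 60); unl$label_levels <- character(0)
  expect_error(fit_mosaic(unl, list(ph), tiny_config(epochs = 1)),
               "n_clusters")
})

test_that("beta warm-up ramps the effective KL weight", {
  ds <- toy_dataset()
  ph <- training_phase("self", 1:60,
                       build_phase_masks("rna", "rna", ds$layout))
  cfg <- tiny_config(epochs = 4, beta = 1, beta_warmup = 4, gamma = 0)
  fit <- fit_mosaic(ds, list(ph), cfg, seed = 5)
  h <- tidy(fit)
  # during warm-up epoch e, total = recon + (e/4) * kl
  expect_equal(h$total, h$recon + (h$epoch / 4) * h$kl, tolerance = 1e-12)
})
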