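# Workflow-level behaviour on tiny fixtures with short training runs; the
# full-scale recovery properties live in test-acceptance.R.

test_that("identical reference and query with no specific genes integrate cleanly", {
  fx <- make_fixture("fig2", "tiny", seed = 5)
  ref <- fx$datasets[[1]]
  res <- integrate_and_impute(ref, ref, common = seq_len(ncol(ref$X)),
                              config = tiny_config(epochs = 15), seed = 2)
  expect_equal(ncol(res$imputed), 0)
  expect_gt(batch_entropy(res$Z2, res$cells$dataset, seed = 1), 0.9)
  expect_error(integrate_and_impute(ref, ref, common = integer(0)),
               "Zero common genes")
})

test_that("imputation returns query cells by specific genes, nonnegative", {
  fx <- make_fixture("fig2", "tiny", seed = 6)
  res <- integrate_and_impute(fx$datasets[[1]], fx$datasets[[2]],
                              common = fx$scenario$common_idx,
                              config = tiny_config(epochs = 15), seed = 3)
  expect_equal(dim(res$imputed),
               c(n_cells(fx$datasets[[2]]), length(fx$scenario$specific_idx)))
  expect_true(all(res$imputed >= 0))
  expect_equal(nrow(res$Z2), 600)
  expect_true(all(res$cells$cluster %in% seq_len(ncol(res$probs))))
})

test_that("a single monomodal dataset reduces to plain VAE clustering", {
  fx <- make_fixture("fig2", "tiny", seed = 7)
  res <- integrate_multimodal(fx$datasets[1], config = tiny_config(epochs = 10),
                              seed = 4)
  expect_equal(nrow(res$cells), 300)
  expect_true(all(res$cells$cluster >= 1))
})

test_that("the default tri-modal schedule reproduces the six-phase layout", {
  fx <- make_fixture("fig4", "tiny", seed = 8)
  comb <- bind_datasets(fx$datasets)
  sched <- mosaicvae:::.default_schedule(comb)
  expect_equal(sched$bridge, "adt")
  names6 <- vapply(sched$phases, function(p) p$name, character(1))
  expect_equal(names6, c(
    "rna->rna (d1)", "adt->adt (d1)", "adt->adt (d2)", "atac->atac (d2)",
    "adt->rna (d1)", "adt->atac (d2)"
  ))
  # self phases carry identical input and output masks
  for (p in sched$phases[1:4]) {
    expect_identical(p$masks$input_mask, p$masks$output_mask)
  }
  # the translation schedule for generation: source self everywhere,
  # source -> target in the references only
  f6 <- make_fixture("fig6", "tiny", seed = 8)
  comb6 <- bind_datasets(f6$datasets)
  expect_warning(
    mosaicvae:::.default_schedule(bind_datasets(list(
      f6$datasets[[3]],
      {
        lay <- block_layout(adt = paste0("adt_", 1:15))
        stacked_dataset(matrix(1, 5, 15), lay, covariate = rep(1, 5))
      }
    ))),
    "share no modality"
  )
})

test_that("label transfer votes by cluster with deterministic tie-breaks", {
  fake <- structure(list(cells = tibble::tibble(
    cell_id = paste0("c", 1:8),
    dataset = c(1, 1, 1, 1, 2, 2, 2, 2),
    covariate = 1,
    label = c("A", "A", "B", NA, NA, NA, "B", NA),
    cluster = c(1, 1, 2, 1, 1, 3, 2, 2)
  )), class = "integration_result")
  out <- transfer_labels(fake)$cells$transferred
  expect_equal(out[4], "A")            # cluster 1 majority A
  expect_equal(out[5], "A")
  expect_equal(out[6], "unassigned")   # cluster 3 has no labeled member
  expect_equal(out[8], "B")            # cluster 2 all B
  # tie in a cluster resolves to the smallest label code
  tie <- structure(list(cells = tibble::tibble(
    cell_id = paste0("c", 1:3), dataset = 1, covariate = 1,
    label = c("B", "A", NA), cluster = c(1, 1, 1)
  )), class = "integration_result")
  expect_equal(transfer_labels(tie)$cells$transferred[3], "A")
  # labeled cells keep their own label
  expect_equal(transfer_labels(tie)$cells$transferred[1], "B")
})

test_that("an empty query yields empty generation without error", {
  f6 <- make_fixture("fig6", "tiny", seed = 9)
  lay_q <- block_layout(rna = f6$truth$layout$features[[1]])
  empty <- stacked_dataset(matrix(0, 0, n_features(lay_q)), lay_q,
                           covariate = integer(0))
  res <- generate_missing_modality(f6$datasets[1:2], empty,
                                   config = tiny_config(epochs = 3), seed = 5)
  expect_equal(nrow(res$generated), 0)
  expect_equal(ncol(res$generated), 15)
})

test_that("tidiers and plots expose the result surfaces", {
  fx <- make_fixture("fig2", "tiny", seed = 10)
  res <- integrate_and_impute(fx$datasets[[1]], fx$datasets[[2]],
                              common = fx$scenario$common_idx,
                              config = tiny_config(epochs = 5), seed = 6)
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(nrow(glance(res)), 1)
  expect_s3_class(tidy(res$fit), "tbl_df")
  expect_equal(nrow(glance(res$fit)), 1)
  expect_s3_class(autoplot(res$fit), "ggplot")
  expect_s3_class(autoplot(res, colour = "dataset"), "ggplot")
  expect_match(res$provenance$config_hash, "^[0-9a-f]+$")
})
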