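# WBC depletion classifier.

deplete_fixture <- function() {
  memo("deplete_fixture", {
    wbc <- generate_crop_dataset(75, phenotypes = wbc_phenotypes(), seed = 31)
    rare <- generate_crop_dataset(75, phenotypes = c("CTC", "CEC", "L-Nuclei"),
                                  seed = 32)
    crops <- c(wbc$crops, rare$crops)
    is_wbc <- rep(c(TRUE, FALSE), each = 225)
    model <- train_depletion(
      crops, is_wbc,
      depletion_config(widths = c(8L, 16L, 32L, 64L), epochs = 5L,
                       batch_size = 64L, lr = 5e-4),
      seed = 41)
    list(crops = crops, is_wbc = is_wbc, model = model)
  })
}

test_that("training on separable classes reaches high held-out accuracy", {
  fx <- deplete_fixture()
  expect_lt(rev(fx$model$trace$train_loss)[1], fx$model$trace$train_loss[1])
  # held-out accuracy on freshly generated crops
  test_wbc <- generate_crop_dataset(25, phenotypes = wbc_phenotypes(), seed = 33)
  test_rare <- generate_crop_dataset(25, phenotypes = c("CTC", "CEC", "L-Nuclei"),
                                     seed = 34)
  p <- wbc_probability(fx$model, c(test_wbc$crops, test_rare$crops))
  acc <- mean(c(p[1:75] > 0.5, p[76:150] < 0.5))
  expect_gt(acc, 0.9)
  # a prototypical lymphocyte scores as WBC
  expect_gt(wbc_probability(fx$model, render_crop("Lymph", 99))[1], 0.5)
})

test_that("probabilities are proper and the trace is seeded-deterministic", {
  fx <- deplete_fixture()
  p <- wbc_probability(fx$model, fx$crops[1:5])
  expect_true(all(p >= 0 & p <= 1))
  # two-class softmax sums to one by construction; re-derive from logits
  X <- cytodeep:::crops_to_batch(cytodeep:::check_crops(fx$crops[1:5]),
                                 fx$model$norm)
  lg <- cytodeep:::cpp_forward_head(X, fx$model$weights, fx$model$net_cfg)
  sm <- apply(lg, 2, function(v) exp(v - max(v)) / sum(exp(v - max(v))))
  expect_equal(colSums(sm), rep(1, 5), tolerance = 1e-6)
  expect_equal(p, sm[2, ], tolerance = 1e-6)
  # equal logits give probability one half
  cfg0 <- cytodeep:::net_config(c(8L, 16L, 32L, 64L), head_dims = c(16L, 2L))
  w0 <- cytodeep:::init_net(cfg0, seed = 1)
  w0$Whead[[2]][] <- 0; w0$bhead[[2]][] <- 0
  lg0 <- cytodeep:::cpp_forward_head(X[, 1, drop = FALSE], w0, cfg0)
  expect_equal(exp(lg0[2]) / sum(exp(lg0)), 0.5)
  # seeded retrain reproduces the loss trace
  sub <- c(1:40, 226:265)
  cfg <- depletion_config(widths = c(8L, 8L, 16L, 32L), epochs = 2L,
                          batch_size = 32L)
  m1 <- train_depletion(fx$crops[sub], fx$is_wbc[sub], cfg, seed = 5)
  m2 <- train_depletion(fx$crops[sub], fx$is_wbc[sub], cfg, seed = 5)
  expect_identical(m1$trace, m2$trace)
})

test_that("single-class input is rejected", {
  ds <- generate_crop_dataset(3, phenotypes = "Lymph", seed = 1)
  expect_error(train_depletion(ds$crops, rep(TRUE, 3)), "both classes")
})

test_that("depletion partitions, is monotone in threshold, and enriches", {
  fx <- deplete_fixture()
  # 9:1 WBC:rare mix
  mix <- c(fx$crops[1:180], fx$crops[226:245])
  truth_rare <- rep(c(FALSE, TRUE), c(180, 20))
  thresholds <- c(0.2, 0.35, 0.5, 0.65, 0.8)
  kept_sizes <- integer(0)
  prev_kept <- integer(0)
  for (th in thresholds) {
    d <- deplete(mix, fx$model, th)
    expect_equal(length(d$kept) + length(d$removed), length(mix))
    expect_true(all(prev_kept %in% d$kept_idx))   # monotone growth
    prev_kept <- d$kept_idx
    kept_sizes <- c(kept_sizes, length(d$kept))
    frac_in <- mean(truth_rare)
    frac_out <- mean(truth_rare[d$kept_idx])
    expect_gt(frac_out / frac_in, 1)              # enrichment
  }
  expect_true(all(diff(kept_sizes) >= 0))
  d_all <- deplete(mix, fx$model, 1 - 1e-9)
  expect_equal(length(d_all$kept), length(mix))
  expect_error(deplete(mix, fx$model, 0), "keep_threshold")
})
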