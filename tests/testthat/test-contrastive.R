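# NT-Xent loss, encoder mechanics, view pairs, training loop.

test_that("a single pair has exactly zero loss", {
  set.seed(1)
  for (tau in c(0.13, 0.5, 1)) {
    z <- matrix(rnorm(64), 1)
    expect_equal(nt_xent_loss(z, matrix(rnorm(64), 1), tau), 0)
  }
})

test_that("the two-pair orthogonal batch matches the closed form", {
  # pairs (e1, e1) and (e2, e2), tau = 1: every anchor contributes
  # -log(e / (e + 2)), so the mean equals that value exactly
  e1 <- c(1, 0, 0, 0); e2 <- c(0, 1, 0, 0)
  loss <- nt_xent_loss(rbind(e1, e2), rbind(e1, e2), 1)
  expect_equal(loss, -log(exp(1) / (exp(1) + 2 * exp(0))), tolerance = 1e-12)
})

test_that("loss is invariant to pair order and common rotation", {
  set.seed(2)
  z1 <- matrix(rnorm(5 * 16), 5)
  z2 <- matrix(rnorm(5 * 16), 5)
  l0 <- nt_xent_loss(z1, z2, 0.13)
  p <- sample(5)
  expect_equal(nt_xent_loss(z1[p, ], z2[p, ], 0.13), l0, tolerance = 1e-12)
  # common orthogonal rotation preserves all cosines
  q <- qr.Q(qr(matrix(rnorm(256), 16)))
  expect_equal(nt_xent_loss(z1 %*% q, z2 %*% q, 0.13), l0, tolerance = 1e-8)
})

test_that("loss strictly decreases as the positive pair aligns", {
  # fixed negatives, positive pair rotated toward alignment
  neg <- matrix(rnorm(32), 2)
  angle_loss <- function(a) {
    z1 <- rbind(c(1, rep(0, 15)), neg[1, ])
    z2 <- rbind(c(cos(a), sin(a), rep(0, 14)), neg[2, ])
    nt_xent_loss(z1, z2, 0.5)
  }
  set.seed(3)
  losses <- vapply(c(1.2, 0.8, 0.4, 0.1), angle_loss, 0)
  expect_true(all(diff(losses) < 0))
})

test_that("zero-norm projections are rejected", {
  z1 <- matrix(c(0, 0, 0, 0, 1, 1, 1, 1), 2, byrow = TRUE)
  expect_error(nt_xent_loss(z1, z1, 0.13), "zero-norm")
  expect_error(nt_xent_loss(matrix(1, 1, 4), matrix(1, 1, 4), 0), "temperature")
})

test_that("the training-path loss matches the reference implementation", {
  # the compiled single-precision loss used inside training agrees with the
  # double-precision reference within float tolerance
  set.seed(4)
  for (i in 1:20) {
    N <- sample(2:16, 1)
    z1 <- matrix(rnorm(N * 64), N)
    z2 <- matrix(rnorm(N * 64), N)
    tau <- sample(c(0.13, 0.5, 1), 1)
    expect_equal(cytodeep:::cpp_nt_xent_loss(rbind(z1, z2), tau),
                 nt_xent_loss(z1, z2, tau), tolerance = 1e-5)
  }
})

test_that("encoding is deterministic, batch-independent, duplicate-consistent", {
  enc <- fixture_random_encoder()
  crops <- fixture_crops()$crops[1:6]
  h1 <- encode(enc, crops)
  expect_equal(dim(h1), c(6L, 128L))
  expect_true(all(is.finite(h1)))
  expect_identical(feature_space(h1), "learned-128")
  h2 <- encode(enc, crops, batch = 2)
  expect_equal(h1, h2, tolerance = 1e-5)
  hdup <- encode(enc, c(crops[1], crops[1]))
  expect_equal(hdup[1, ], hdup[2, ])
  expect_identical(encode(enc, crops), h1)   # re-evaluation
})

test_that("projection maps 128 to 64 and rejects wrong widths", {
  enc <- fixture_random_encoder()
  h <- encode(enc, fixture_crops()$crops[1:3])
  z <- project(enc, h)
  expect_equal(dim(z), c(3L, 64L))
  expect_true(all(is.finite(z)))
  expect_identical(project(enc, h), z)
  expect_error(project(enc, h[, 1:100]), "128")
})

test_that("desk-scale training reduces the contrastive loss and aligns pairs", {
  ds <- generate_crop_dataset(12, seed = 77)   # 120 crops
  cfg <- encoder_config("desk", epochs = 3, batch_size = 64)
  enc <- train_encoder(ds$crops, cfg, seed = 5)
  expect_length(enc$loss_trace, 3)
  expect_lt(rev(enc$loss_trace)[1], enc$loss_trace[1])
  # positive-pair representations are more similar than random crop pairs
  set.seed(6)
  aug <- augmentation_config()
  pairs <- lapply(ds$crops[1:40], make_view_pair, config = aug)
  ha <- encode(enc, lapply(pairs, `[[`, 1))
  hb <- encode(enc, lapply(pairs, `[[`, 2))
  rsim <- function(A, B) {
    num <- rowSums(A * B)
    num / (sqrt(rowSums(A^2)) * sqrt(rowSums(B^2)))
  }
  pos_sim <- mean(rsim(ha, hb))
  perm <- c(21:40, 1:20)
  rand_sim <- mean(rsim(ha, hb[perm, ]))
  expect_gt(pos_sim, rand_sim)
})

test_that("training is reproducible under a fixed seed", {
  ds <- generate_crop_dataset(6, seed = 78)
  cfg <- encoder_config("desk", epochs = 2, batch_size = 32)
  e1 <- train_encoder(ds$crops, cfg, seed = 9)
  e2 <- train_encoder(ds$crops, cfg, seed = 9)
  expect_identical(e1$loss_trace, e2$loss_trace)
  expect_identical(e1$weights, e2$weights)
  expect_error(train_encoder(ds$crops, encoder_config("desk", batch_size = 1)),
               "batch size")
})
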