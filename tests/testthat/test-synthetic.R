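# Synthetic slide and crop generator.

test_that("marker profiles carry the assay's phenotype definitions", {
  ctc <- marker_profile("CTC")
  expect_true(ctc$positive[["CK"]])
  expect_false(ctc$positive[["VIM"]])
  expect_false(ctc$positive[["CD45CD31"]])
  ln <- marker_profile("L-Nuclei")
  expect_identical(unname(ln$positive), c(TRUE, FALSE, FALSE, FALSE))
  cec <- marker_profile("CEC")
  expect_true(cec$positive[["VIM"]] && cec$positive[["CD45CD31"]])
  expect_false(cec$positive[["CK"]])
  im <- marker_profile("imCTC")
  expect_true(all(im$positive[c("DAPI", "CK", "CD45CD31")]))
  for (ph in cyto_phenotypes()) {
    pr <- marker_profile(ph)
    expect_true(pr$positive[["DAPI"]])
    # positive location strictly exceeds the negative location per channel
    expect_true(all(pr$meanlog[pr$positive] > max(pr$meanlog[!pr$positive], -Inf)))
  }
  expect_error(marker_profile("NK"), "unknown phenotype.*NK")
})

test_that("slide generation is reproducible and mask/truth-consistent", {
  cfg <- slide_config(frame_nrow = 260, frame_ncol = 300, n_frames = 2,
                      n_cells = 120,
                      rare_fractions = setNames(rep(0.02, 7), rare_phenotypes()),
                      seed = 7)
  s1 <- generate_slide(cfg)
  s2 <- generate_slide(cfg)
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$masks, s2$masks)
  expect_identical(s1$truth, s2$truth)
  expect_false(anyDuplicated(s1$truth$cell_id) > 0)
  # every id has a nonempty mask region with centroid within 2 px of truth
  for (i in sample(nrow(s1$truth), 25)) {
    row <- s1$truth[i, ]
    pix <- which(s1$masks[[row$frame]] == row$cell_id, arr.ind = TRUE)
    expect_gt(nrow(pix), 0)
    expect_equal(nrow(pix), row$area)
    expect_lt(abs(mean(pix[, 1]) - row$row), 2)
    expect_lt(abs(mean(pix[, 2]) - row$col), 2)
  }
  # ids partition across frames: each id appears in exactly one frame
  all_ids <- unlist(lapply(s1$masks, function(m) setdiff(unique(as.vector(m)), 0)))
  expect_false(anyDuplicated(all_ids) > 0)
  expect_setequal(all_ids, s1$truth$cell_id)
})

test_that("zero rare fractions yield a WBC-only slide", {
  cfg <- slide_config(frame_nrow = 220, frame_ncol = 220, n_frames = 1,
                      n_cells = 60,
                      rare_fractions = setNames(rep(0, 7), rare_phenotypes()),
                      seed = 3)
  s <- generate_slide(cfg)
  expect_true(all(s$truth$phenotype %in% wbc_phenotypes()))
})

test_that("infeasible cell counts are rejected", {
  cfg <- slide_config(frame_nrow = 100, frame_ncol = 100, n_frames = 1,
                      n_cells = 5000, seed = 1)
  expect_error(generate_slide(cfg), "infeasible")
})

test_that("rare-cell counts are binomially consistent across seeds", {
  # Phenotype sampling drives the realized counts; over 200 seeds the mean
  # CTC count at fraction 1e-4 of 10,000 cells must sit within 3 standard
  # errors of 1, and the count distribution must pass a chi-square
  # goodness-of-fit against Binomial(10000, 1e-4) at alpha = 0.01.
  counts <- vapply(1:200, function(s) {
    set.seed(s)
    sum(sample_phenotypes(10000,
                          setNames(rep(1e-4, 7), rare_phenotypes()),
                          c(Lymph = .3, Mono = .08, Gran = .62)) == "CTC")
  }, 0)
  se <- sqrt(10000 * 1e-4 * (1 - 1e-4) / 200)
  expect_lt(abs(mean(counts) - 1), 3 * se)
  obs <- c(sum(counts == 0), sum(counts == 1), sum(counts >= 2))
  p <- dbinom(0:1, 10000, 1e-4)
  p <- c(p, 1 - sum(p))
  gof <- suppressWarnings(chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.01)
})

test_that("crop datasets are balanced, shaped, and reproducible", {
  ds <- generate_crop_dataset(10, seed = 5)
  expect_length(ds$crops, 100)
  expect_true(all(vapply(ds$crops, function(cr) all(dim(cr) == c(75, 75, 5)), TRUE)))
  expect_identical(as.vector(table(ds$labels)), rep(10L, 10))
  ds2 <- generate_crop_dataset(10, seed = 5)
  expect_identical(lapply(ds$crops, unclass), lapply(ds2$crops, unclass))
  expect_error(generate_crop_dataset(5, phenotypes = character(0)), "empty")
  expect_error(generate_crop_dataset(0), "n_per_class")
})

test_that("generated intensities separate positive from negative channels", {
  # label-conditional separation: for each channel, masked mean intensity in
  # positive-state phenotypes vs negative-state phenotypes has Cohen's d > 1
  ds <- fixture_crops()
  masked_mean <- function(cr, k) {
    m <- cr[, , 5] == 1
    mean(cr[, , k][m])
  }
  for (k in 2:4) {
    ch <- cyto_channels()[k]
    pos_ph <- names(Filter(function(p) p, vapply(cyto_phenotypes(), function(ph)
      marker_profile(ph)$positive[[ch]], TRUE)))
    pos <- neg <- c()
    for (i in seq_along(ds$crops)) {
      v <- masked_mean(ds$crops[[i]], k)
      if (as.character(ds$labels[i]) %in% pos_ph) pos <- c(pos, v)
      else neg <- c(neg, v)
    }
    d <- (mean(pos) - mean(neg)) /
      sqrt((var(pos) * (length(pos) - 1) + var(neg) * (length(neg) - 1)) /
             (length(pos) + length(neg) - 2))
    expect_gt(d, 1)
  }
  # CTC crops show brighter masked CK than Lymph crops
  ck_ctc <- mean(vapply(ds$crops[ds$labels == "CTC"], masked_mean, 0, k = 2))
  ck_lym <- mean(vapply(ds$crops[ds$labels == "Lymph"], masked_mean, 0, k = 2))
  expect_gt(ck_ctc, ck_lym)
})

test_that("rare phenotypes are rendered larger than leukocytes", {
  ds <- fixture_crops()
  areas <- vapply(ds$crops, function(cr) sum(cr[, , 5]), 0)
  rare <- areas[ds$labels %in% c("CTC", "Mega-like", "L-Nuclei")]
  wbc <- areas[ds$labels %in% wbc_phenotypes()]
  expect_gt(mean(rare), 1.5 * mean(wbc))
})
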