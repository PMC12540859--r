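# Shared fixtures, memoised so expensive objects (trained models, crop sets)
# are built once per test run and reused by every file that needs them.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# balanced 10-phenotype crop set used by feature / encoder tests
fixture_crops <- function(n_per_class = 12, seed = 421) {
  memo(paste0("crops", n_per_class, "_", seed),
       generate_crop_dataset(n_per_class, seed = seed))
}

# desk-scale encoder training set (shared by the downstream benchmarks)
fixture_train_set <- function() {
  memo("train_set", generate_crop_dataset(120, seed = 42))
}

# balanced held-out crops for probing representation quality
fixture_eval_set <- function() {
  memo("eval_set", generate_crop_dataset(30, seed = 43))
}

# trained desk encoder, one per seed; seed 1 is shared by the robustness,
# outlier, clustering and enumeration benchmarks
fixture_encoder <- function(seed = 1) {
  memo(paste0("encoder", seed), {
    ds <- fixture_train_set()
    train_encoder(ds$crops, encoder_config("desk"), seed = seed)
  })
}

fixture_random_encoder <- function(seed = 1) {
  memo(paste0("rand_encoder", seed), {
    ds <- fixture_train_set()
    random_encoder(ds$crops, encoder_config("desk"), seed = seed)
  })
}

# feature extractor pair evaluated on identical crops
fixture_extractors <- function(seed = 1) {
  enc <- fixture_encoder(seed)
  list(learned = function(crops) encode(enc, crops),
       engineered = function(crops) engineered_feature_matrix(crops))
}

# a tiny deterministic crop with a centered disc mask and flat channels
flat_disc_crop <- function(radius = 10, values = c(10000, 20000, 30000, 40000)) {
  x <- array(0, c(75, 75, 5))
  for (k in 1:4) x[, , k] <- values[k]
  ctr <- 38
  for (r in 1:75) for (cc in 1:75)
    if ((r - ctr)^2 + (cc - ctr)^2 <= radius^2) x[r, cc, 5] <- 1
  cell_crop(x)
}
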