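# Synthetic enrichment-free whole-slide simulator.
#
# Cells are rendered as anisotropic Gaussian blobs (nucleus in DAPI,
# cytoplasm-scale signal in the channels marked positive for the phenotype)
# clipped to an elliptical footprint; the instance mask is exactly that
# footprint. Negative channels emit a low autofluorescence-like amplitude so
# no plane is ever empty. A single integer seed drives a hierarchical seed
# tree (slide -> frame -> cell) so frames and individual crops are
# independently reproducible.

# Lehmer-style hash chain; keeps every derived seed in [1, 2^31 - 2].
derive_seed <- function(seed, ...) {
  h <- as.double(seed %% 2147483647)
  for (idx in c(...)) h <- (h * 48271 + as.double(idx) + 1) %% 2147483647
  as.integer(h + 1)
}

# Draw per-cell geometry and per-channel amplitudes from a profile.
# Uses the current RNG stream.
.draw_cell <- function(profile) {
  s <- max(0.7, min(1.3, rnorm(1, 1, profile$radius_cv)))
  q <- runif(1, 0.75, 1)          # anisotropy (minor/major)
  theta <- runif(1, 0, pi)
  amps <- rlnorm(4, meanlog = profile$meanlog, sdlog = profile$sdlog)
  amps <- pmin(amps, 60000)
  names(amps) <- cyto_channels()
  a_n <- profile$nucleus_r * s
  a_c <- profile$cyto_r * s
  list(a_n = a_n, b_n = a_n * q, a_c = a_c, b_c = a_c * q,
       theta = theta, amps = amps, a_f = max(a_n, a_c), b_f = max(a_n, a_c) * q)
}

# Render one cell at continuous center (cy, cx) into local coordinates.
# Returns intensity patch (h x w x 4), footprint mask, and bbox rows/cols.
.render_cell <- function(geom, cy, cx, nrow_lim, ncol_lim) {
  R <- ceiling(geom$a_f) + 2L
  r0 <- max(1L, floor(cy) - R); r1 <- min(nrow_lim, ceiling(cy) + R)
  c0 <- max(1L, floor(cx) - R); c1 <- min(ncol_lim, ceiling(cx) + R)
  rr <- (r0:r1) - cy
  cc <- (c0:c1) - cx
  ct <- cos(geom$theta); st <- sin(geom$theta)
  u <- outer(rr, cc, function(y, x) y * ct + x * st)
  v <- outer(rr, cc, function(y, x) -y * st + x * ct)
  foot <- (u / geom$a_f)^2 + (v / geom$b_f)^2 <= 1
  g_n <- exp(-0.5 * ((u / (geom$a_n / 1.6))^2 + (v / (geom$b_n / 1.6))^2))
  g_c <- exp(-0.5 * ((u / (geom$a_c / 1.6))^2 + (v / (geom$b_c / 1.6))^2))
  patch <- array(0, c(length(rr), length(cc), 4L))
  for (k in seq_len(4L)) {
    g <- if (k == 1L) g_n else g_c
    patch[, , k] <- geom$amps[k] * g * foot
  }
  list(patch = patch, foot = foot, rows = r0:r1, cols = c0:c1)
}

# Smooth random field in [0,1]: bilinear upsample of a coarse uniform grid.
.smooth_field <- function(nr, nc, knots = 5L) {
  g <- matrix(runif(knots * knots), knots, knots)
  ri <- seq(1, knots, length.out = nr)
  ci <- seq(1, knots, length.out = nc)
  r0 <- pmin(floor(ri), knots - 1L); fr <- ri - r0
  c0 <- pmin(floor(ci), knots - 1L); fc <- ci - c0
  a <- g[cbind(rep(r0, nc), rep(c0, each = nr))]
  b <- g[cbind(rep(r0 + 1, nc), rep(c0, each = nr))]
  d <- g[cbind(rep(r0, nc), rep(c0 + 1, each = nr))]
  e <- g[cbind(rep(r0 + 1, nc), rep(c0 + 1, each = nr))]
  w <- (1 - rep(fr, nc)) * (1 - rep(fc, each = nr)) * a +
    rep(fr, nc) * (1 - rep(fc, each = nr)) * b +
    (1 - rep(fr, nc)) * rep(fc, each = nr) * d +
    rep(fr, nc) * rep(fc, each = nr) * e
  matrix(w, nr, nc)
}

#' Configuration of a synthetic slide
#'
#' @param frame_nrow,frame_ncol Frame pixel dimensions (default 1004 x 1362,
#'   the scanner's native frame size).
#' @param n_frames Number of frames on the slide.
#' @param n_cells Total cell count across the slide.
#' @param rare_fractions Named expected fraction per rare phenotype; the
#'   default spikes every rare class at 1e-4 (1:10,000), the concentration
#'   used for contrived spike-in slides.
#' @param wbc_mix Composition of the non-rare remainder over the leukocyte
#'   subclasses (defaults approximate a healthy differential).
#' @param background_level,background_sd Additive background offset and noise
#'   (16-bit counts).
#' @param blur_sigma_range Range of the regional blur field sigma (px);
#'   `c(0, 0)` disables it.
#' @param gain_range Per-channel multiplicative gain range (scanner artifact).
#' @param artifacts Apply blur field and channel gains?
#' @param allow_clusters Permit touching cells (off by default; clustered
#'   cells are out of scope).
#' @param seed Integer seed fixing all downstream randomness.
#' @return A `slide_config` list.
#' @export
slide_config <- function(frame_nrow = 1004L, frame_ncol = 1362L,
                         n_frames = 4L, n_cells = 10000L,
                         rare_fractions = setNames(rep(1e-4, 7), rare_phenotypes()),
                         wbc_mix = c(Lymph = 0.30, Mono = 0.08, Gran = 0.62),
                         background_level = 200, background_sd = 60,
                         blur_sigma_range = c(0, 1.5),
                         gain_range = c(0.9, 1.1),
                         artifacts = TRUE, allow_clusters = FALSE,
                         seed = 1L) {
  if (frame_nrow <= 0 || frame_ncol <= 0) stop("frame dimensions must be positive")
  if (any(rare_fractions < 0) || any(rare_fractions > 1) || sum(rare_fractions) > 1)
    stop("rare fractions must lie in [0,1] and sum to at most 1")
  if (!all(names(rare_fractions) %in% rare_phenotypes()))
    stop("rare_fractions must be named by rare phenotypes")
  if (!all(names(wbc_mix) %in% wbc_phenotypes()) || any(wbc_mix < 0))
    stop("invalid wbc_mix")
  structure(list(
    frame_nrow = as.integer(frame_nrow), frame_ncol = as.integer(frame_ncol),
    n_frames = as.integer(n_frames), n_cells = as.integer(n_cells),
    rare_fractions = rare_fractions, wbc_mix = wbc_mix / sum(wbc_mix),
    background_level = background_level, background_sd = background_sd,
    blur_sigma_range = blur_sigma_range, gain_range = gain_range,
    artifacts = isTRUE(artifacts), allow_clusters = isTRUE(allow_clusters),
    seed = as.integer(seed)
  ), class = "slide_config")
}

#' Sample phenotype labels under a rarity map
#'
#' Draws `n` phenotype labels: each rare phenotype appears with its stated
#' fraction, and the remaining probability mass is split among the leukocyte
#' classes in proportion to `wbc_mix`. Uses the current RNG state; callers
#' wanting reproducibility should `set.seed()` first.
#'
#' @param n Number of cells.
#' @param rare_fractions Named vector of per-phenotype spike fractions
#'   (names from [rare_phenotypes()]).
#' @param wbc_mix Named vector of leukocyte mixing weights (names from
#'   [wbc_phenotypes()]); normalized internally.
#' @return Character vector of `n` phenotype labels.
#' @export
sample_phenotypes <- function(n, rare_fractions, wbc_mix) {
  p <- setNames(numeric(length(cyto_phenotypes())), cyto_phenotypes())
  p[names(rare_fractions)] <- rare_fractions
  p[names(wbc_mix)] <- p[names(wbc_mix)] + (1 - sum(rare_fractions)) * wbc_mix
  sample(cyto_phenotypes(), n, replace = TRUE, prob = p)
}

#' Generate a synthetic slide
#'
#' Renders `n_cells` cells across `n_frames` frames with
#' phenotype-conditional marker expression, additive background noise and
#' optional scanner artifacts (smooth regional blur field, per-channel gain).
#' Cell positions are placed by rejection sampling so footprints do not
#' overlap; instance masks exactly cover the rendered footprints. The same
#' config (including its seed) always reproduces bit-identical output.
#'
#' @param config A [slide_config()].
#' @return A list with `frames` (list of [if_frame()]), `masks` (list of
#'   [instance_mask()]), and `truth`, a data.frame with columns
#'   `cell_id, frame, row, col, phenotype, area` (row/col are 1-based mask
#'   centroids).
#' @export
generate_slide <- function(config) {
  stopifnot(inherits(config, "slide_config"))
  nr <- config$frame_nrow; nc <- config$frame_ncol
  set.seed(derive_seed(config$seed, 0))
  phen <- sample_phenotypes(config$n_cells, config$rare_fractions, config$wbc_mix)
  frame_of <- sample.int(config$n_frames, config$n_cells, replace = TRUE)

  # rough packing feasibility: discs of footprint radius must fit at ~55%
  profiles <- lapply(setNames(nm = cyto_phenotypes()), marker_profile)
  foot_r <- vapply(profiles, function(p) max(p$nucleus_r, p$cyto_r), 0) * 1.3
  need <- sum(pi * foot_r[phen]^2)
  if (need > 0.55 * config$n_frames * nr * nc)
    stop("requested cell count infeasible for frame area")

  frames <- vector("list", config$n_frames)
  masks <- vector("list", config$n_frames)
  truth <- vector("list", config$n_frames)
  next_id <- 1L

  for (f in seq_len(config$n_frames)) {
    img <- array(0, c(nr, nc, 4L))
    msk <- matrix(0L, nr, nc)
    idx <- which(frame_of == f)
    # place big cells first: improves packing and is deterministic
    idx <- idx[order(-foot_r[phen[idx]], idx)]
    ids <- integer(0); rows <- numeric(0); cols <- numeric(0)
    labs <- character(0); areas <- integer(0)
    # spatial hash for neighbour lookup
    bin <- 40
    nbr <- ceiling(nr / bin); nbc <- ceiling(nc / bin)
    grid <- vector("list", nbr * nbc)
    acc_y <- numeric(0); acc_x <- numeric(0); acc_r <- numeric(0)
    set.seed(derive_seed(config$seed, f))
    for (i in idx) {
      cs <- derive_seed(config$seed, f, i)
      set.seed(cs)
      geom <- .draw_cell(profiles[[phen[i]]])
      margin <- geom$a_f + 3
      placed <- FALSE
      for (try in seq_len(300L)) {
        cy <- runif(1, margin, nr - margin)
        cx <- runif(1, margin, nc - margin)
        gy <- floor(cy / bin); gx <- floor(cx / bin)
        ok <- TRUE
        for (dy in -1:1) for (dx in -1:1) {
          by <- gy + dy; bx <- gx + dx
          if (by < 0 || bx < 0 || by >= nbr || bx >= nbc) next
          cand <- grid[[by * nbc + bx + 1L]]
          if (length(cand)) {
            d2 <- (acc_y[cand] - cy)^2 + (acc_x[cand] - cx)^2
            gap <- if (config$allow_clusters) 0.6 else 1
            if (any(d2 < (gap * (acc_r[cand] + geom$a_f) + 1)^2)) { ok <- FALSE; break }
          }
        }
        if (ok) { placed <- TRUE; break }
      }
      if (!placed) next  # drop cell if frame locally saturated
      k <- length(acc_y) + 1L
      acc_y[k] <- cy; acc_x[k] <- cx; acc_r[k] <- geom$a_f
      gcell <- floor(cy / bin) * nbc + floor(cx / bin) + 1L
      grid[[gcell]] <- c(grid[[gcell]], k)
      rc <- .render_cell(geom, cy, cx, nr, nc)
      img[rc$rows, rc$cols, ] <- img[rc$rows, rc$cols, , drop = FALSE] + rc$patch
      sub <- msk[rc$rows, rc$cols]
      sub[rc$foot] <- next_id
      msk[rc$rows, rc$cols] <- sub
      pix <- which(rc$foot, arr.ind = TRUE)
      ids <- c(ids, next_id)
      rows <- c(rows, mean(rc$rows[pix[, 1]]))
      cols <- c(cols, mean(rc$cols[pix[, 2]]))
      labs <- c(labs, phen[i]); areas <- c(areas, sum(rc$foot))
      next_id <- next_id + 1L
    }
    # background and artifacts
    set.seed(derive_seed(config$seed, f, 999983L))
    img <- img + config$background_level +
      array(rnorm(nr * nc * 4L, 0, config$background_sd), c(nr, nc, 4L))
    if (config$artifacts) {
      gains <- runif(4, config$gain_range[1], config$gain_range[2])
      smax <- max(config$blur_sigma_range)
      w <- if (smax > 0) .smooth_field(nr, nc) *
        diff(range(config$blur_sigma_range)) / max(smax, 1e-9) else NULL
      for (k in 1:4) {
        pl <- img[, , k] * gains[k]
        if (!is.null(w) && smax > 0) {
          bl <- cpp_gauss_blur(pl, smax, 0L)
          pl <- (1 - w) * pl + w * bl
        }
        img[, , k] <- pl
      }
    }
    img <- round(pmin(pmax(img, 0), 65535))
    frames[[f]] <- if_frame(img)
    masks[[f]] <- instance_mask(msk)
    truth[[f]] <- data.frame(cell_id = ids, frame = f, row = rows, col = cols,
                             phenotype = labs, area = areas,
                             stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(frames = frames, masks = masks, truth = truth)
}

#' Render a single labelled cell crop
#'
#' Draws one cell of the given phenotype centered (with +/- 2 px jitter) in a
#' 75 x 75 field of view, with background noise, and returns the 75 x 75 x 5
#' crop (4 IF channels + footprint mask).
#'
#' @param phenotype One of [cyto_phenotypes()].
#' @param seed Integer seed; the same seed reproduces the crop exactly.
#' @param noise Add background offset and Gaussian noise?
#' @return A [cell_crop()].
#' @export
render_crop <- function(phenotype, seed, noise = TRUE) {
  profile <- marker_profile(phenotype)
  set.seed(seed)
  cy <- 38 + runif(1, -2, 2)
  cx <- 38 + runif(1, -2, 2)
  geom <- .draw_cell(profile)
  x <- cpp_render_crop(cy, cx, geom$a_n, geom$b_n, geom$a_c, geom$b_c,
                       geom$theta, geom$amps, 200, 60,
                       derive_seed(seed, 99L), isTRUE(noise))
  structure(x, dimnames = list(NULL, NULL, c(cyto_channels(), "mask")),
            cell_id = NA_integer_, frame = NA_integer_, class = "cell_crop")
}

#' Generate crops for a given label sequence
#'
#' Deterministic per cell: crop `i` depends only on `seed` and `i`, so large
#' cohorts can be generated (and featurized) in chunks without holding all
#' crops in memory.
#'
#' @param labels Character vector of phenotypes.
#' @param seed Integer seed.
#' @param noise Add background noise?
#' @return List of [cell_crop()]s.
#' @export
crops_for_labels <- function(labels, seed, noise = TRUE) {
  lapply(seq_along(labels), function(i)
    render_crop(labels[i], derive_seed(seed, 7L, i), noise = noise))
}

#' Generate a balanced labelled crop dataset
#'
#' @param n_per_class Crops per phenotype (>= 1).
#' @param phenotypes Subset of [cyto_phenotypes()].
#' @param seed Integer seed.
#' @param noise Add background noise?
#' @return List with `crops` (list of [cell_crop()]) and `labels` (factor).
#' @export
generate_crop_dataset <- function(n_per_class, phenotypes = cyto_phenotypes(),
                                  seed = 1L, noise = TRUE) {
  if (length(phenotypes) == 0) stop("empty phenotype set")
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  bad <- setdiff(phenotypes, cyto_phenotypes())
  if (length(bad)) stop("unknown phenotype: ", paste(bad, collapse = ", "))
  labels <- rep(phenotypes, each = n_per_class)
  crops <- crops_for_labels(labels, seed, noise = noise)
  list(crops = crops, labels = factor(labels, levels = phenotypes))
}
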