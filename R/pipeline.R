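# End-to-end pipeline driver: simulation -> segmentation evaluation -> crop
# extraction -> WBC depletion -> contrastive training -> feature extraction
# -> benchmarks, with a provenance manifest (config hash, seeds, per-stage
# output checksums). Stages are write-once and resumable: a stage whose
# output directory already carries a manifest entry is skipped.

#' Pipeline configuration
#'
#' @param out_dir Run directory.
#' @param seed Global seed.
#' @param profile `"desk"` (CPU-scale defaults) or `"full"` (full-scale
#'   hyperparameters).
#' @param n_cells,n_frames Synthetic slide size.
#' @param n_train_crops Balanced crops for encoder training.
#' @param epochs Encoder epochs override (NULL = profile default).
#' @param stages Character subset of
#'   `c("simulate", "segment", "crops", "deplete", "train", "features",
#'   "benchmark")`.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            profile = c("desk", "full"),
                            n_cells = 2000L, n_frames = 2L,
                            n_train_crops = 60L, epochs = NULL,
                            stages = c("simulate", "segment", "crops",
                                       "deplete", "train", "features",
                                       "benchmark")) {
  profile <- match.arg(profile)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 profile = profile, n_cells = as.integer(n_cells),
                 n_frames = as.integer(n_frames),
                 n_train_crops = as.integer(n_train_crops), epochs = epochs,
                 stages = stages), class = "pipeline_config")
}

.config_hash <- function(config) {
  tmp <- tempfile()
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

.stage_checksums <- function(dir) {
  fs <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  setNames(as.vector(tools::md5sum(fs)),
           sub(paste0("^", dir, "/?"), "", fs))
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in order inside `config$out_dir`, writing a
#' `manifest.json` with the config hash, global seed, package version, and
#' per-stage output checksums. A failing stage halts the run with the stage
#' name; outputs of completed stages are retained and re-used on rerun.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (list), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else
      list(config_hash = .config_hash(config), seed = config$seed,
           version = as.character(utils::packageVersion("cytodeep")),
           stages = list())
  if (!identical(manifest$config_hash, .config_hash(config)))
    stop("run directory was produced by a different config; refusing to mix")
  seed <- config$seed
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    sdir <- file.path(out, name)
    if (!name %in% config$stages) return(invisible(NULL))
    if (!is.null(manifest$stages[[name]])) {
      message("stage ", name, ": already complete, skipping")
      return(invisible(NULL))
    }
    message("stage ", name, " ...")
    t0 <- Sys.time()
    ok <- tryCatch({ fun(sdir); TRUE },
                   error = function(e) {
                     stop("stage '", name, "' failed: ", conditionMessage(e),
                          call. = FALSE)
                   })
    manifest$stages[[name]] <<- list(
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2),
      checksums = as.list(.stage_checksums(sdir)))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }

  get_slide <- function() {
    if (is.null(state$slide))
      state$slide <- generate_slide(slide_config(
        frame_nrow = 320L, frame_ncol = 400L, n_frames = config$n_frames,
        n_cells = config$n_cells,
        rare_fractions = setNames(rep(0.01, 7), rare_phenotypes()),
        seed = derive_seed(seed, 11)))
    state$slide
  }

  run_stage("simulate", function(sdir) write_slide(get_slide(), sdir))

  run_stage("segment", function(sdir) {
    dir.create(sdir, showWarnings = FALSE)
    slide <- get_slide()
    curves <- lapply(seq_along(slide$frames), function(f) {
      pred <- reference_segment(slide$frames[[f]])
      cbind(frame = f, f1_curve(slide$masks[[f]], pred,
                                seq(0.5, 0.9, by = 0.1)))
    })
    write.csv(do.call(rbind, curves), file.path(sdir, "f1_curve.csv"),
              row.names = FALSE)
  })

  run_stage("crops", function(sdir) {
    slide <- get_slide()
    crops <- lapply(seq_len(nrow(slide$truth)), function(i) {
      f <- slide$truth$frame[i]
      extract_crop(slide$frames[[f]], slide$masks[[f]],
                   slide$truth$cell_id[i])
    })
    state$crops <- crops
    state$labels <- slide$truth$phenotype
    write_crops(crops, sdir, labels = state$labels)
  })

  run_stage("deplete", function(sdir) {
    dir.create(sdir, showWarnings = FALSE)
    if (is.null(state$crops)) {
      rc <- read_crops(file.path(out, "crops"))
      state$crops <- rc$crops
      state$labels <- rc$index$label
    }
    is_wbc <- state$labels %in% wbc_phenotypes()
    model <- train_depletion(state$crops, is_wbc,
                             depletion_config(widths = c(8L, 16L, 32L, 64L),
                                              epochs = 6L),
                             seed = derive_seed(seed, 12))
    dep <- deplete(state$crops, model, 0.5)
    state$depletion <- model
    write.csv(data.frame(crop_id = seq_along(state$crops),
                         p_wbc = dep$p_wbc,
                         kept = seq_along(state$crops) %in% dep$kept_idx),
              file.path(sdir, "depletion.csv"), row.names = FALSE)
    write.csv(model$trace, file.path(sdir, "loss_trace.csv"),
              row.names = FALSE)
  })

  run_stage("train", function(sdir) {
    dir.create(sdir, showWarnings = FALSE)
    train_set <- generate_crop_dataset(config$n_train_crops,
                                       seed = derive_seed(seed, 13))
    cfg <- encoder_config(config$profile,
                          epochs = config$epochs %||%
                            if (config$profile == "desk") 8L else NULL)
    state$encoder <- train_encoder(train_set$crops, cfg,
                                   seed = derive_seed(seed, 14))
    saveRDS(state$encoder, file.path(sdir, "encoder.rds"))
    write.csv(data.frame(epoch = seq_along(state$encoder$loss_trace),
                         loss = state$encoder$loss_trace),
              file.path(sdir, "loss_trace.csv"), row.names = FALSE)
  })

  run_stage("features", function(sdir) {
    dir.create(sdir, showWarnings = FALSE)
    if (is.null(state$crops)) {
      cdir <- file.path(out, "crops")
      if (!dir.exists(cdir)) stop("missing input directory: crops")
      rc <- read_crops(cdir)
      state$crops <- rc$crops
      state$labels <- rc$index$label
    }
    if (is.null(state$encoder)) {
      ep <- file.path(out, "train", "encoder.rds")
      if (!file.exists(ep)) stop("missing input: train stage output")
      state$encoder <- readRDS(ep)
    }
    write_features(encode(state$encoder, state$crops),
                   file.path(sdir, "learned.csv"))
    write_features(engineered_feature_matrix(state$crops),
                   file.path(sdir, "engineered.csv"))
    write.csv(data.frame(crop_id = seq_along(state$crops),
                         label = state$labels),
              file.path(sdir, "labels.csv"), row.names = FALSE)
  })

  run_stage("benchmark", function(sdir) {
    dir.create(sdir, showWarnings = FALSE)
    fdir <- file.path(out, "features")
    learned <- read_features(file.path(fdir, "learned.csv"))
    engineered <- read_features(file.path(fdir, "engineered.csv"))
    labels <- read.csv(file.path(fdir, "labels.csv"))$label
    res <- lapply(list(learned = learned, engineered = engineered),
                  function(X) linear_probe(X, labels,
                                           split_seed = derive_seed(seed, 15)))
    summary <- data.frame(space = names(res),
                          accuracy = vapply(res, `[[`, 0, "accuracy"),
                          macro_roc_auc = vapply(res, `[[`, 0, "macro_roc_auc"),
                          macro_pr_auc = vapply(res, `[[`, 0, "macro_pr_auc"))
    write.csv(summary, file.path(sdir, "probe.csv"), row.names = FALSE)
  })

  invisible(manifest)
}
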