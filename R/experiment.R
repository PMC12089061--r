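#' Default end-to-end experiment configuration
#'
#' Desk-scale defaults for the full pipeline: synthesize clean volumes,
#' simulate low-field noise twice (native complex-domain injection and
#' direct Gaussian addition), build paired patch datasets, train one
#' denoiser per noise type with identical settings, and compare them on a
#' native-noise test set. All stage seeds derive from the single global
#' `seed` (see [derive_seed()]), so the whole experiment is reproducible
#' from the config alone.
#'
#' @param ... overrides, as nested lists matching the default structure
#' @return an object of class `experiment_config`
#' @export
experiment_config <- function(...) {
  cfg <- list(
    seed = 0L,
    out_dir = "nativenoise_run",
    synth = list(kind = "brain_like", size = 128L, n_volumes = 4L,
                 slices_per_volume = 4L, foreground_level = 0.5,
                 texture_scale = 8),
    profile = list(target_snr = 5, noise_std = 0.1, name = "custom"),
    sim = list(rho = 0.005, sigma = 1, tolerance = 0.02, max_iters = 10000L),
    dataset = list(patch_size = 32L, n_per_slice = 16L,
                   fractions = c(0.5, 0.25, 0.25)),
    unet = list(base_channels = 8L, depth = 4L),
    train = list(learning_rate = 0.001, batch_size = 64L, max_epochs = 15L),
    eval = list(corner_fraction = 0.1)
  )
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]])) {
    over <- over[[1]]
  }
  cfg <- utils::modifyList(cfg, over)
  errs <- config_errors(cfg)
  if (length(errs)) {
    stop_nn("nativenoise_config_error",
            paste0("invalid experiment config:\n  ",
                   paste(errs, collapse = "\n  ")),
            errors = errs)
  }
  structure(cfg, class = "experiment_config")
}

# All invariant violations, each naming the offending field path.
config_errors <- function(cfg) {
  errs <- character()
  add <- function(cond, msg) {
    if (isTRUE(cond)) errs[[length(errs) + 1]] <<- msg
    errs
  }
  num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  add(!num(cfg$seed), "seed: must be a single integer")
  add(!cfg$synth$kind %in% c("brain_like", "phantom_disk", "phantom_mesh"),
      "synth.kind: unknown image kind")
  add(!num(cfg$synth$size) || cfg$synth$size < 64,
      "synth.size: must be >= 64")
  add(!num(cfg$synth$n_volumes) || cfg$synth$n_volumes < 1,
      "synth.n_volumes: must be >= 1")
  add(!num(cfg$synth$slices_per_volume) || cfg$synth$slices_per_volume < 1,
      "synth.slices_per_volume: must be >= 1")
  add(!num(cfg$synth$foreground_level) || cfg$synth$foreground_level <= 0 ||
        cfg$synth$foreground_level > 1,
      "synth.foreground_level: must be in (0, 1]")
  add(!num(cfg$profile$target_snr) || cfg$profile$target_snr <= 0,
      "profile.target_snr: must be > 0")
  add(!num(cfg$profile$noise_std) || cfg$profile$noise_std <= 0,
      "profile.noise_std: must be > 0")
  add(!num(cfg$sim$rho) || cfg$sim$rho <= 0, "sim.rho: must be > 0")
  add(!num(cfg$sim$sigma) || cfg$sim$sigma <= 0, "sim.sigma: must be > 0")
  add(!num(cfg$sim$tolerance) || cfg$sim$tolerance <= 0,
      "sim.tolerance: must be > 0")
  add(!num(cfg$sim$max_iters) || cfg$sim$max_iters < 1,
      "sim.max_iters: must be >= 1")
  add(!num(cfg$dataset$patch_size) || cfg$dataset$patch_size < 8,
      "dataset.patch_size: must be >= 8")
  add(!num(cfg$dataset$n_per_slice) || cfg$dataset$n_per_slice < 1,
      "dataset.n_per_slice: must be >= 1")
  fr <- cfg$dataset$fractions
  add(length(fr) != 3 || any(fr < 0) || abs(sum(fr) - 1) > 1e-9,
      "dataset.fractions: must be three nonnegative numbers summing to 1")
  add(!num(cfg$unet$base_channels) || cfg$unet$base_channels < 1,
      "unet.base_channels: must be >= 1")
  add(!num(cfg$unet$depth) || cfg$unet$depth < 1, "unet.depth: must be >= 1")
  if (num(cfg$unet$depth) && num(cfg$dataset$patch_size) &&
      cfg$dataset$patch_size %% 2^cfg$unet$depth != 0) {
    add(TRUE, "dataset.patch_size: not divisible by 2^unet.depth")
  }
  add(!num(cfg$train$learning_rate) || cfg$train$learning_rate <= 0,
      "train.learning_rate: must be > 0")
  add(!num(cfg$train$batch_size) || cfg$train$batch_size < 1,
      "train.batch_size: must be >= 1")
  add(!num(cfg$train$max_epochs) || cfg$train$max_epochs < 1,
      "train.max_epochs: must be >= 1")
  add(!num(cfg$eval$corner_fraction) || cfg$eval$corner_fraction <= 0 ||
        cfg$eval$corner_fraction > 0.25,
      "eval.corner_fraction: must be in (0, 0.25]")
  errs
}

#' Validate an experiment configuration file
#'
#' Parses a YAML config and checks every invariant, reporting all
#' violations at once (each names its field path).
#'
#' @param path YAML file
#' @return an `experiment_config` on success; on failure an error of class
#'   `nativenoise_config_error` whose `errors` field lists every violation
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) {
    stop_nn("nativenoise_config_error", sprintf("no such file: %s", path),
            errors = sprintf("file: %s not readable", path))
  }
  experiment_config(yaml::read_yaml(path))
}

#' Build paired noisy/clean slices from clean volumes
#'
#' Simulates every clean slice with the requested noise type. For
#' `"native"`, the iterative complex-domain simulator targets
#' `profile$target_snr`. For `"random"`, zero-mean Gaussian noise of
#' standard deviation `noise_std` is added directly to the magnitude.
#'
#' @param volumes list of volumes (each a list of clean
#'   [magnitude_image()]), as from [make_volume()]
#' @param profile a [noise_profile()]
#' @param sim a [sim_config()]; per-slice seeds derive from `sim$seed`
#' @param noise_type `"native"` or `"random"`
#' @param noise_std Gaussian noise level for `"random"`
#' @return list of [paired_slice()]
#' @export
build_paired_slices <- function(volumes, profile, sim,
                                noise_type = c("native", "random"),
                                noise_std = NULL) {
  noise_type <- match.arg(noise_type)
  out <- list()
  k <- 0L
  for (v in seq_along(volumes)) {
    for (s in seq_along(volumes[[v]])) {
      k <- k + 1L
      clean <- volumes[[v]][[s]]
      seed_k <- derive_seed(sim$seed, k)
      if (noise_type == "native") {
        cfg <- sim
        cfg$seed <- seed_k
        res <- simulate_native_noise(clean, profile, cfg)
        noisy <- res$image
        simrec <- list(type = "native", target_snr = profile$target_snr_linear,
                       achieved_snr = res$achieved_snr,
                       iterations = nrow(res$trace), seed = seed_k)
      } else {
        noisy <- simulate_random_noise(clean, noise_std, seed = seed_k)
        simrec <- list(type = "random", noise_std = noise_std, seed = seed_k)
      }
      out[[k]] <- paired_slice(clean, noisy, volume_id = sprintf("vol%02d", v),
                               slice_index = s, simulator = simrec)
    }
  }
  out
}

write_stage <- function(manifest, path, stage) {
  manifest$files[[basename(path)]] <-
    list(stage = stage, md5 = unname(tools::md5sum(path)))
  manifest
}

#' Patch-size sweep over the full experiment
#'
#' Re-runs [run_experiment()] once per requested training patch size and
#' tabulates one row per (noise type, patch size) with the mean test
#' PSNR, output SNR (dB) and SSIM — the layout used to compare patch-wise
#' against image-wise training.
#'
#' @param config an [experiment_config()]; each run writes under
#'   `config$out_dir/patch<size>`
#' @param patch_sizes integer vector of patch sides (each divisible by
#'   `2^depth`)
#' @return data.frame with columns `noise`, `patch_size`, `psnr`,
#'   `snr_db`, `ssim`
#' @export
run_patch_sweep <- function(config, patch_sizes) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- list()
  for (ps in patch_sizes) {
    cfg <- unclass(config)
    cfg$dataset$patch_size <- as.integer(ps)
    cfg$out_dir <- file.path(config$out_dir, sprintf("patch%d", ps))
    res <- run_experiment(experiment_config(cfg))
    agg <- res$report$aggregate
    for (m in agg$method) {
      r <- agg[agg$method == m, ]
      rows[[length(rows) + 1]] <- data.frame(
        noise = m, patch_size = as.integer(ps), psnr = r$psnr_mean,
        snr_db = r$snr_out_db_mean, ssim = r$ssim_mean,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the full native-vs-random denoising experiment
#'
#' Pipeline: synthesize clean volumes; simulate each slice with native
#' (complex-domain, Rician) noise and with directly-added Gaussian noise
#' of equal measured power; split by volume; extract paired patches; train
#' one U-Net per noise type under identical settings; evaluate both on the
#' native-noise test slices. Artifacts (config, patch sets, checkpoints,
#' report) are written under `config$out_dir` along with a manifest of
#' MD5 hashes; on a stage failure the partial manifest is persisted before
#' the error (tagged with the stage name) propagates.
#'
#' @param config an [experiment_config()]
#' @return list with `report` (a `metric_report`), `checkpoints` (named
#'   list), `rnd_noise_std`, and `manifest`
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config), files = list())
  manifest_path <- file.path(config$out_dir, "manifest.json")
  flush_manifest <- function() {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA)
  }
  stage <- "init"
  tryCatch({
    cfg_path <- file.path(config$out_dir, "config.yaml")
    yaml::write_yaml(unclass(config), cfg_path)
    manifest <- write_stage(manifest, cfg_path, "config")

    stage <- "synth"
    volumes <- lapply(seq_len(config$synth$n_volumes), function(v) {
      spec <- synthetic_spec(config$synth$kind, config$synth$size,
                             config$synth$foreground_level,
                             config$synth$texture_scale,
                             seed = derive_seed(config$seed, v))
      make_volume(spec, config$synth$slices_per_volume)
    })

    stage <- "simulate"
    profile <- noise_profile(config$profile$target_snr,
                             config$profile$noise_std,
                             name = config$profile$name %||% "custom")
    sim <- sim_config(config$sim$rho, config$sim$sigma, config$sim$tolerance,
                      config$sim$max_iters,
                      seed = derive_seed(config$seed, 100))
    native <- build_paired_slices(volumes, profile, sim, "native")
    # Gaussian baseline at the noise power the native simulation reached,
    # so the two trainings differ only in noise distribution.
    rnd_std <- mean(vapply(native, function(s) {
      estimate_noise_std(s$noisy, config$eval$corner_fraction)
    }, 0))
    random <- build_paired_slices(volumes, profile, sim, "random",
                                  noise_std = rnd_std)

    stage <- "split"
    seed_split <- derive_seed(config$seed, 200)
    split_n <- split_dataset(native, config$dataset$fractions, seed_split)
    split_r <- split_dataset(random, config$dataset$fractions, seed_split)

    stage <- "build-dataset"
    seed_patch <- derive_seed(config$seed, 300)
    sets <- list()
    for (nm in c("train", "val")) {
      sets[[paste0("nnd_", nm)]] <-
        extract_patches(split_n[[nm]], config$dataset$patch_size,
                        config$dataset$n_per_slice, seed_patch, split = nm)
      sets[[paste0("rnd_", nm)]] <-
        extract_patches(split_r[[nm]], config$dataset$patch_size,
                        config$dataset$n_per_slice, seed_patch, split = nm)
    }
    for (nm in names(sets)) {
      p <- file.path(config$out_dir, paste0(nm, ".patches.rds"))
      write_patchset(sets[[nm]], p)
      manifest <- write_stage(manifest, p, "build-dataset")
    }
    flush_manifest()

    stage <- "train"
    ucfg <- unet_config(config$unet$base_channels, config$unet$depth,
                        config$dataset$patch_size)
    tcfg <- train_config(config$train$learning_rate, config$train$batch_size,
                         config$train$max_epochs,
                         seed = derive_seed(config$seed, 400))
    seed_init <- derive_seed(config$seed, 500)
    ckpts <- list(
      nnd = train_denoiser(build_unet(ucfg, seed_init),
                           sets$nnd_train, sets$nnd_val, tcfg),
      rnd = train_denoiser(build_unet(ucfg, seed_init),
                           sets$rnd_train, sets$rnd_val, tcfg)
    )
    for (nm in names(ckpts)) {
      p <- file.path(config$out_dir, paste0(nm, ".ckpt.rds"))
      save_checkpoint(ckpts[[nm]], p)
      manifest <- write_stage(manifest, p, "train")
    }
    flush_manifest()

    stage <- "evaluate"
    report <- evaluate_methods(ckpts, split_n$test,
                               corner_fraction = config$eval$corner_fraction)
    rep_dir <- file.path(config$out_dir, "report")
    write_metric_report(report, rep_dir)
    for (f in list.files(rep_dir, full.names = TRUE)) {
      manifest <- write_stage(manifest, f, "evaluate")
    }
    flush_manifest()

    list(report = report, checkpoints = ckpts, rnd_noise_std = rnd_std,
         manifest = manifest)
  }, error = function(e) {
    flush_manifest()
    if (inherits(e, "nativenoise_error")) {
      stop_nn("nativenoise_stage_error",
              sprintf("experiment failed at stage '%s': %s", stage,
                      conditionMessage(e)),
              stage = stage)
    }
    stop(e)
  })
}
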