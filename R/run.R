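#' Scale presets
#'
#' `"desk"` sizes the whole pipeline for a workstation run on synthetic data
#' (32^3 grid with a few thousand WM voxels, width-scaled networks, 200
#' RF-voting runs, 5 RF trials); `"paper"` reproduces the study-scale
#' configuration (a ~64k-voxel WM feature space, the 2000-1000-500-250-2 and
#' 500-250-125-60-2 networks, 5000 voting runs, 100 RF trials) for hardware
#' that can afford it.
#'
#' @param scale `"desk"` or `"paper"`.
#' @return List with `generator`, `selection_fscore`, `selection_rfvote`,
#'   and `classifier` config constructors' arguments filled in.
#' @export
scale_preset <- function(scale = c("desk", "paper")) {
  scale <- match.arg(scale)
  if (scale == "desk") {
    list(scale = scale,
         generator = generator_config(),
         selection_fscore = selection_config("fscore"),
         selection_rfvote = selection_config("rfvote", n_runs = 200L),
         n_trials_rf = 5L)
  } else {
    list(scale = scale,
         generator = generator_config(grid_shape = c(72L, 72L, 72L)),
         selection_fscore = selection_config("fscore"),
         selection_rfvote = selection_config("rfvote", n_runs = 5000L),
         n_trials_rf = 100L)
  }
}

#' Generate and write a synthetic dataset directory
#'
#' @param config a [generator_config()].
#' @param out_dir output directory.
#' @return The dataset, invisibly; the directory holds NIfTI volumes, the
#'   CSV manifest and the JSON ground-truth/config sidecars.
#' @export
run_synthesize <- function(config = generator_config(), out_dir) {
  ds <- generate_dataset(config)
  write_dataset(ds, out_dir)
  invisible(ds)
}

#' Run a full evaluation over classifiers, selection and modes
#'
#' @param data a [strain_dataset()] or a dataset directory path.
#' @param classifiers character subset of `c("deep", "svm", "rf")`.
#' @param selection `"none"`, `"fscore"` or `"rfvote"` (a single method used
#'   for every classifier), or a [selection_config()].
#' @param modes subset of `c("loocv", "bootstrap", "permtest")`.
#' @param n_boot bootstrap trials, `n_trials` permutation trials.
#' @param n_trials permutation trials.
#' @param scale `"desk"` or `"paper"`.
#' @param seed global seed.
#' @param out_dir optional directory; when given the report bundle is
#'   written there.
#' @return A `strain_report`.
#' @export
run_evaluate <- function(data, classifiers = c("deep", "svm", "rf"),
                         selection = "fscore",
                         modes = "loocv", n_boot = 100L, n_trials = 50L,
                         scale = "desk", seed = 1L, out_dir = NULL) {
  if (is.character(data)) data <- read_manifest(data)
  preset <- scale_preset(scale)
  sel <- if (inherits(selection, "selection_config")) selection
         else switch(selection,
                     none = NULL,
                     fscore = preset$selection_fscore,
                     rfvote = preset$selection_rfvote,
                     stop("unknown selection method: ", selection))
  loocv <- list(); boot <- list(); perm <- list(); smaps <- list()
  for (m in classifiers) {
    cfg <- classifier_config(m, scale = scale,
                             n_trials = preset$n_trials_rf)
    if ("loocv" %in% modes) {
      cv <- loocv_run(data, cfg, sel, seed = derive_seed(seed, m, "loocv"))
      loocv[[m]] <- cv
      if (!is.null(sel))
        smaps[[m]] <- selection_probability_map(cv$masks, data$grid)
    }
    if ("bootstrap" %in% modes)
      boot[[m]] <- bootstrap_run(data, cfg, sel, n_boot = n_boot,
                                 seed = derive_seed(seed, m, "boot"))
    if ("permtest" %in% modes)
      perm[[m]] <- randomized_label_test(data, cfg, sel,
                                         n_trials = n_trials,
                                         seed = derive_seed(seed, m, "perm"))
  }
  report <- assemble_report(loocv = loocv, boot = boot, permtest = perm,
                            maps = smaps)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write selection probability maps as NIfTI overlays
#'
#' For each classifier's per-fold selection masks, writes the per-voxel
#' selection frequency volume, the thresholded display mask
#' (`frequency > min_frequency`), and a CSV of `(feature_index, frequency)`.
#'
#' @param report a `strain_report` from [run_evaluate()] (LOOCV with
#'   selection enabled), or a named list of
#'   [selection_probability_map()] objects.
#' @param grid the study [volume_grid()].
#' @param out_dir output directory.
#' @param min_frequency display threshold (default 0.5).
#' @return `out_dir`, invisibly.
#' @export
run_maps <- function(report, grid, out_dir, min_frequency = 0.5) {
  maps <- if (inherits(report, "strain_report")) report$maps else report
  if (length(maps) == 0L)
    stop("no selection probability maps: run LOOCV with selection enabled")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(maps)) {
    map <- maps[[nm]]
    vol <- unflatten_wm(map$frequency, grid)
    write_volume(vol, file.path(out_dir, paste0("selection_prob_", nm,
                                                ".nii.gz")),
                 grid$voxel_size)
    keep <- threshold_map(map, min_frequency)
    mask_vol <- unflatten_wm(as.numeric(seq_len(grid$n_wm) %in% keep), grid)
    write_volume(mask_vol, file.path(out_dir, paste0("selection_mask_", nm,
                                                     ".nii.gz")),
                 grid$voxel_size, datatype = "uint8")
    write.csv(data.frame(feature_index = seq_len(grid$n_wm),
                         frequency = map$frequency),
              file.path(out_dir, paste0("selection_freq_", nm, ".csv")),
              row.names = FALSE)
  }
  invisible(out_dir)
}
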