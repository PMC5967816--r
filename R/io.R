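#' Read a 3D NIfTI volume
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param grid optional [volume_grid()]; if given, the file's dimensions must
#'   match the grid's.
#' @return A numeric 3D array with attributes `voxel_size` (mm) recorded from
#'   the NIfTI header.
#' @export
read_volume <- function(path, grid = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("expected a 3D volume, got ", length(dim(arr)), "D: ", path)
  if (!is.null(grid) && !identical(dim(arr), as.integer(grid$shape)))
    stop("volume dimensions (", paste(dim(arr), collapse = "x"),
         ") do not match grid (", paste(grid$shape, collapse = "x"), "): ",
         path)
  arr <- arr + 0  # strip image class, keep a plain array
  attr(arr, "voxel_size") <- RNifti::pixdim(img)[1:3]
  arr
}

#' Write a 3D volume as NIfTI
#'
#' Continuous volumes are stored as 32-bit floats, masks/labels as 8-bit
#' integers (standard neuroimaging practice; adequate for strains of order
#' 0.1).
#'
#' @param vol numeric or logical/integer 3D array.
#' @param path output path (`.nii.gz` recommended).
#' @param voxel_size voxel edge length(s) in mm.
#' @param datatype NIfTI storage type; default `"float"` for continuous data,
#'   use `"uint8"` for masks and labels.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, voxel_size = 2, datatype = "float") {
  vol <- array(as.numeric(vol), dim(vol))
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep_len(voxel_size, 3L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Construct a strain case
#'
#' One head impact: a fiber-strain volume (nonzero only in WM), a maximum
#' principal strain (MPS) volume (nonzero only in the brain mask), per-axis
#' peak angular velocity magnitudes, and a binary injury label.
#'
#' @param case_id unique string id.
#' @param fiber_strain,mps numeric 3D arrays on `grid`.
#' @param peak_ang_vel numeric length-3, per-axis peak angular velocity
#'   magnitude (rad/s), all `>= 0`.
#' @param label 1 = concussion, 0 = non-injury.
#' @param grid a [volume_grid()] used to validate the invariants.
#' @param tol numeric tolerance for the zero-padding and projection-bound
#'   checks (single-precision storage round-off).
#' @return An object of class `strain_case`.
#' @export
strain_case <- function(case_id, fiber_strain, mps, peak_ang_vel, label,
                        grid, tol = 1e-5) {
  stopifnot(inherits(grid, "volume_grid"))
  if (!identical(dim(fiber_strain), as.integer(grid$shape)) ||
      !identical(dim(mps), as.integer(grid$shape)))
    stop("case ", case_id, ": volume dimensions do not match grid")
  if (any(fiber_strain < -tol) || any(mps < -tol))
    stop("case ", case_id, ": strains must be non-negative")
  if (any(abs(fiber_strain[!grid$wm_mask]) > tol))
    stop("case ", case_id, ": fiber strain must be zero outside the WM mask")
  if (any(abs(mps[!grid$brain_mask]) > tol))
    stop("case ", case_id, ": MPS must be zero outside the brain mask")
  if (any(fiber_strain > mps + tol))
    stop("case ", case_id,
         ": fiber strain exceeds MPS (projection bound violated)")
  peak_ang_vel <- as.numeric(peak_ang_vel)
  if (length(peak_ang_vel) != 3L || any(peak_ang_vel < 0))
    stop("case ", case_id, ": peak_ang_vel must be 3 non-negative values")
  label <- as.integer(label)
  if (!label %in% c(0L, 1L)) stop("label must be 0 or 1")
  structure(list(case_id = as.character(case_id),
                 fiber_strain = fiber_strain, mps = mps,
                 peak_ang_vel = peak_ang_vel, label = label),
            class = "strain_case")
}

#' Construct a dataset of strain cases
#'
#' @param grid shared [volume_grid()].
#' @param cases list of [strain_case()] objects.
#' @param provenance free-form list (generator config and seed, or source
#'   file paths).
#' @return An object of class `strain_dataset`.
#' @export
strain_dataset <- function(grid, cases, provenance = list()) {
  stopifnot(inherits(grid, "volume_grid"))
  ids <- vapply(cases, function(cc) cc$case_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate case_id: ",
                               paste(unique(ids[duplicated(ids)]),
                                     collapse = ", "))
  labs <- vapply(cases, function(cc) cc$label, integer(1))
  if (length(unique(labs)) < 2L)
    stop("dataset must contain both classes (concussion and non-injury)")
  structure(list(grid = grid, cases = cases, provenance = provenance),
            class = "strain_dataset")
}

#' @export
print.strain_dataset <- function(x, ...) {
  labs <- dataset_labels(x)
  cat("strain_dataset:", length(x$cases), "cases (",
      sum(labs == 1), "concussion /", sum(labs == 0), "non-injury ) on a",
      paste(x$grid$shape, collapse = "x"), "grid with",
      x$grid$n_wm, "WM voxels\n")
  invisible(x)
}

#' @rdname strain_dataset
#' @param dataset a `strain_dataset`.
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset$cases, function(cc) cc$label, integer(1))
}

#' Flatten a case's WM fiber strain into the canonical feature vector
#'
#' Entry `i` of the result is the fiber strain at the `i`-th WM voxel in the
#' grid's canonical voxel order; these vectors are the classifier inputs.
#'
#' @param case a [strain_case()] (or a bare 3D array).
#' @param grid the case's [volume_grid()].
#' @return Numeric vector of length `grid$n_wm`.
#' @export
flatten_wm <- function(case, grid) {
  vol <- if (inherits(case, "strain_case")) case$fiber_strain else case
  if (!identical(dim(vol), as.integer(grid$shape)))
    stop("volume dimensions do not match grid")
  as.numeric(vol[grid$wm_index])
}

#' Restore a WM feature vector to a zero-padded volume
#'
#' Inverse of [flatten_wm()]: values are placed at the canonical WM voxel
#' positions and all voxels outside the WM mask are zero.
#'
#' @param v numeric vector of length `grid$n_wm`.
#' @param grid a [volume_grid()].
#' @return Numeric 3D array.
#' @export
unflatten_wm <- function(v, grid) {
  if (length(v) != grid$n_wm)
    stop("feature vector length ", length(v),
         " does not match N_WM = ", grid$n_wm)
  vol <- array(0, grid$shape)
  vol[grid$wm_index] <- v
  vol
}

#' Case-by-voxel feature matrix of a dataset
#'
#' @param dataset a [strain_dataset()].
#' @return Numeric matrix, one row per case in dataset order, one column per
#'   WM voxel in canonical order; row names are case ids.
#' @export
dataset_features <- function(dataset) {
  x <- t(vapply(dataset$cases, flatten_wm, numeric(dataset$grid$n_wm),
                grid = dataset$grid))
  rownames(x) <- vapply(dataset$cases, function(cc) cc$case_id, character(1))
  x
}

#' Write a dataset directory
#'
#' Lays out a dataset as one grid bundle (WM mask, brain mask, ROI labels as
#' NIfTI), two NIfTI volumes per case, a CSV manifest with columns
#' `case_id,label,wx,wy,wz,fiber_path,mps_path`, and JSON sidecars echoing
#' the generator config and ground truth when present.
#'
#' @param dataset a [strain_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- dataset$grid
  vs <- g$voxel_size
  write_volume(g$wm_mask, file.path(dir, "wm_mask.nii.gz"), vs, "uint8")
  write_volume(g$brain_mask, file.path(dir, "brain_mask.nii.gz"), vs, "uint8")
  write_volume(g$roi_labels, file.path(dir, "roi_labels.nii.gz"), vs, "uint8")
  rows <- lapply(dataset$cases, function(cc) {
    fp <- paste0("fiber_", cc$case_id, ".nii.gz")
    mp <- paste0("mps_", cc$case_id, ".nii.gz")
    write_volume(cc$fiber_strain, file.path(dir, fp), vs)
    write_volume(cc$mps, file.path(dir, mp), vs)
    data.frame(case_id = cc$case_id, label = cc$label,
               wx = cc$peak_ang_vel[1], wy = cc$peak_ang_vel[2],
               wz = cc$peak_ang_vel[3], fiber_path = fp, mps_path = mp,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (length(dataset$provenance)) {
    prov <- dataset$provenance
    if (!is.null(prov$config))
      jsonlite::write_json(prov$config, file.path(dir, "config.json"),
                           auto_unbox = TRUE, digits = NA)
    gt <- prov[setdiff(names(prov), "config")]
    if (length(gt))
      jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a dataset from a manifest
#'
#' Reads a CSV manifest (columns `case_id,label,wx,wy,wz,fiber_path,mps_path`;
#' volume paths relative to the manifest's directory), the grid bundle
#' (`wm_mask.nii.gz`, `roi_labels.nii.gz`, optional `brain_mask.nii.gz`) from
#' the same directory, and validates every dataset invariant: unique ids,
#' both classes present, zero padding outside masks, fiber strain bounded by
#' MPS.
#'
#' @param path path to `manifest.csv` or to the dataset directory.
#' @return A validated [strain_dataset()].
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  dir <- dirname(path)
  man <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("case_id", "label", "wx", "wy", "wz", "fiber_path", "mps_path")
  if (!all(needed %in% names(man)))
    stop("manifest is missing columns: ",
         paste(setdiff(needed, names(man)), collapse = ", "))
  wm <- read_volume(file.path(dir, "wm_mask.nii.gz"))
  roi <- read_volume(file.path(dir, "roi_labels.nii.gz"))
  brain_path <- file.path(dir, "brain_mask.nii.gz")
  brain <- if (file.exists(brain_path)) read_volume(brain_path) else wm
  vs <- attr(wm, "voxel_size")
  grid <- volume_grid(wm != 0, round(roi), brain != 0,
                      voxel_size = if (all(vs > 0)) vs else 2)
  cases <- lapply(seq_len(nrow(man)), function(i) {
    fpath <- file.path(dir, man$fiber_path[i])
    mpath <- file.path(dir, man$mps_path[i])
    for (p in c(fpath, mpath))
      if (!file.exists(p)) stop("missing volume file: ", p)
    strain_case(man$case_id[i],
                read_volume(fpath, grid), read_volume(mpath, grid),
                c(man$wx[i], man$wy[i], man$wz[i]), man$label[i], grid)
  })
  prov <- list(manifest = normalizePath(path))
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path))
    prov <- c(prov, jsonlite::read_json(gt_path, simplifyVector = TRUE))
  cfg_path <- file.path(dir, "config.json")
  if (file.exists(cfg_path))
    prov$config <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  strain_dataset(grid, cases, provenance = prov)
}
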