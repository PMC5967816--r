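#' ROI label codebook
#'
#' Small-integer labels used in ROI label volumes: 0 = non-WM, 1 = corpus
#' callosum (CC), 2 = right superior longitudinal fasciculus (SLF-R),
#' 3 = SLF-L, 4 = left external capsule (EC-L), 5 = EC-R, 6 = brainstem,
#' 7 = other WM.
#'
#' @export
roi_labels_codebook <- function() {
  c("non-WM" = 0L, "CC" = 1L, "SLF-R" = 2L, "SLF-L" = 3L,
    "EC-L" = 4L, "EC-R" = 5L, "brainstem" = 6L, "other-WM" = 7L)
}

#' Construct a volume grid
#'
#' A `volume_grid` bundles the shared 3D voxel lattice of a study: shape,
#' voxel size, brain and white-matter masks, an ROI label volume, and the
#' canonical ordering of WM voxels used to map volumes to feature vectors.
#' The canonical order is ascending linear index (first array dimension
#' fastest) restricted to WM, so feature index `i` refers to the same voxel
#' in every case, fold and run.
#'
#' @param wm_mask logical 3D array, white-matter voxels.
#' @param roi_labels integer 3D array with codes from [roi_labels_codebook()].
#' @param brain_mask logical 3D array, superset of `wm_mask`. Defaults to
#'   `wm_mask` if omitted.
#' @param voxel_size numeric length-1 or 3, voxel edge length in mm.
#' @return An object of class `volume_grid` with fields `shape`, `voxel_size`,
#'   `wm_mask`, `brain_mask`, `roi_labels`, `wm_index` (linear indices of WM
#'   voxels in canonical order) and `n_wm`.
#' @export
volume_grid <- function(wm_mask, roi_labels, brain_mask = NULL,
                        voxel_size = 2) {
  if (length(dim(wm_mask)) != 3L) stop("wm_mask must be a 3D array")
  if (is.null(brain_mask)) brain_mask <- wm_mask
  storage.mode(roi_labels) <- "integer"
  if (!identical(dim(wm_mask), dim(roi_labels)) ||
      !identical(dim(wm_mask), dim(brain_mask)))
    stop("wm_mask, roi_labels and brain_mask must share dimensions")
  wm_mask <- wm_mask != 0
  brain_mask <- brain_mask != 0
  if (any(roi_labels > 0 & !wm_mask))
    stop("labeled (> 0) voxels must lie inside the WM mask")
  if (any(wm_mask & !brain_mask))
    stop("wm_mask must be a subset of brain_mask")
  wm_index <- which(wm_mask)
  if (length(wm_index) == 0L) stop("WM mask is empty")
  g <- list(shape = dim(wm_mask),
            voxel_size = rep_len(as.numeric(voxel_size), 3L),
            wm_mask = wm_mask, brain_mask = brain_mask,
            roi_labels = roi_labels,
            wm_index = wm_index, n_wm = length(wm_index))
  class(g) <- "volume_grid"
  g
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("volume_grid:", paste(x$shape, collapse = " x "),
      "voxels;", x$n_wm, "WM voxels,",
      sum(x$brain_mask), "brain voxels\n")
  tab <- table(factor(x$roi_labels[x$roi_labels > 0],
                      levels = 1:7,
                      labels = names(roi_labels_codebook())[-1]))
  print(tab)
  invisible(x)
}

#' Voxel indices of one ROI, in canonical WM feature order
#'
#' @param grid a [volume_grid()].
#' @param labels integer ROI codes (see [roi_labels_codebook()]).
#' @return Integer vector of feature indices (positions in the canonical WM
#'   voxel order) belonging to the requested ROI(s).
#' @export
roi_feature_index <- function(grid, labels) {
  stopifnot(inherits(grid, "volume_grid"))
  which(grid$roi_labels[grid$wm_index] %in% labels)
}

# ellipsoid indicator on a normalized [-1, 1]^3 lattice
.ellipsoid_mask <- function(shape, center, radii) {
  cx <- (seq_len(shape[1]) - (shape[1] + 1) / 2) / (shape[1] / 2)
  cy <- (seq_len(shape[2]) - (shape[2] + 1) / 2) / (shape[2] / 2)
  cz <- (seq_len(shape[3]) - (shape[3] + 1) / 2) / (shape[3] / 2)
  X <- ((cx - center[1]) / radii[1])^2
  Y <- ((cy - center[2]) / radii[2])^2
  Z <- ((cz - center[3]) / radii[3])^2
  outer(outer(X, Y, `+`), Z, `+`) <= 1
}

# normalized-coordinate ROI seed points and radii; x = posterior-anterior,
# y = right-left, z = inferior-superior
.roi_geometry <- function() {
  list(
    list(label = 1L, center = c(0.00,  0.00,  0.12)),  # CC
    list(label = 2L, center = c(0.12, -0.42,  0.18)),  # SLF-R
    list(label = 3L, center = c(0.12,  0.42,  0.18)),  # SLF-L
    list(label = 4L, center = c(0.00,  0.38, -0.02)),  # EC-L
    list(label = 5L, center = c(0.00, -0.38, -0.02)),  # EC-R
    list(label = 6L, center = c(-0.06, 0.00, -0.50))   # brainstem
  )
}

#' Generate a synthetic brain/WM grid with ROI blobs
#'
#' Builds a deterministic, procedurally generated [volume_grid()]: the brain
#' mask is an ellipsoid, the WM mask a concentric smaller ellipsoid with a
#' central (ventricular) core removed, and six compact spherical ROI blobs
#' (CC, SLF-R/L, EC-L/R, brainstem) are carved inside the WM; remaining WM
#' voxels get the other-WM label.
#'
#' @param config a [generator_config()]; only `grid_shape` and `voxel_size`
#'   are used.
#' @return A [volume_grid()].
#' @export
make_grid <- function(config = generator_config()) {
  shape <- as.integer(config$grid_shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("grid_shape must be three integers, each >= 8")
  brain <- .ellipsoid_mask(shape, c(0, 0, 0), c(0.88, 0.78, 0.82))
  wm <- .ellipsoid_mask(shape, c(0, 0, 0), 0.72 * c(0.88, 0.78, 0.82))
  core <- .ellipsoid_mask(shape, c(0, 0, 0.05), c(0.16, 0.14, 0.16))
  wm <- wm & !core & brain

  roi <- array(0L, shape)
  half <- shape / 2
  r_norm <- max(0.20, 3.2 / min(half))  # blob radius, normalized units
  for (b in .roi_geometry()) {
    blob <- .ellipsoid_mask(shape, b$center, rep(r_norm, 3)) & wm & roi == 0L
    if (sum(blob) < 4L)
      stop("grid too small to fit 7 disjoint ROIs (label ", b$label,
           " got ", sum(blob), " voxels)")
    roi[blob] <- b$label
  }
  roi[wm & roi == 0L] <- 7L
  volume_grid(wm, roi, brain, voxel_size = config$voxel_size)
}
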