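#' Preprocessing specification
#'
#' Controls volume preparation: whole-volume versus tumour-ROI processing,
#' volumetric CLAHE, the resampling target shape and the mask sanity filter.
#' Default target shapes follow the convention of 180x180x64 for whole
#' volumes and 96x96x32 for the tumour ROI.
#'
#' @param mode `"whole"` or `"roi"`.
#' @param target_shape Integer triple the processed volume is resampled to.
#'   Defaults to `c(180, 180, 64)` in whole mode, `c(96, 96, 32)` in ROI
#'   mode.
#' @param clahe_enabled Apply contrast-limited adaptive histogram
#'   equalization before normalization.
#' @param clahe_clip_limit Clip limit as a fraction of the per-tile mean
#'   histogram count, on intensities rescaled to `[0, 1]`.
#' @param clahe_tile_shape Tile grid cell size in voxels; `NULL` means about
#'   one eighth of the volume shape per axis.
#' @param clahe_bins Number of histogram bins.
#' @param roi_margin Isotropic fractional padding added around the tumour
#'   bounding box before resampling (ROI mode).
#' @param augment Enable on-the-fly augmentation during training.
#' @param max_roi_volume_fraction Reject masks whose label bounding box
#'   exceeds this fraction of the full field of view.
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(mode = c("roi", "whole"),
                            target_shape = NULL,
                            clahe_enabled = TRUE,
                            clahe_clip_limit = 0.01,
                            clahe_tile_shape = NULL,
                            clahe_bins = 64L,
                            roi_margin = 0.10,
                            augment = FALSE,
                            max_roi_volume_fraction = 0.5) {
  mode <- match.arg(mode)
  if (is.null(target_shape))
    target_shape <- if (mode == "whole") c(180L, 180L, 64L) else c(96L, 96L, 32L)
  if (length(target_shape) != 3L || any(target_shape < 1L))
    stopf("target_shape must be a positive integer triple")
  if (clahe_clip_limit <= 0) stopf("clahe_clip_limit must be positive")
  if (max_roi_volume_fraction <= 0 || max_roi_volume_fraction > 1)
    stopf("max_roi_volume_fraction must lie in (0, 1]")
  structure(list(mode = mode, target_shape = as.integer(target_shape),
                 clahe_enabled = isTRUE(clahe_enabled),
                 clahe_clip_limit = clahe_clip_limit,
                 clahe_tile_shape = clahe_tile_shape,
                 clahe_bins = as.integer(clahe_bins),
                 roi_margin = roi_margin,
                 augment = isTRUE(augment),
                 max_roi_volume_fraction = max_roi_volume_fraction),
            class = "preprocess_spec")
}

#' Standardize a volume over its non-zero voxels
#'
#' Computes mean and standard deviation over non-zero voxels only (the
#' head, in skull-stripped data), transforms those voxels to
#' `(x - mean) / sd` and leaves background zeros untouched. The population
#' (divide-by-n) standard deviation is used.
#'
#' @param volume 3D numeric array.
#' @return List with `volume` (normalized) and `stats`
#'   (`mean_nonzero`, `std_nonzero`).
#' @export
normalize_nonzero <- function(volume) {
  check_volume(volume)
  nz <- volume != 0
  if (!any(nz)) stopf("normalization error: volume is all zero")
  x <- volume[nz]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s < 1e-12)
    stopf("normalization error: non-zero voxels have zero variance")
  out <- volume
  out[nz] <- (x - m) / s
  list(volume = out, stats = list(mean_nonzero = m, std_nonzero = s))
}

# Trilinear gather of `values` (array) at fractional coordinates given by
# vectors cx, cy, cz (1-based, clamped to the array extent).
trilinear_gather <- function(values, cx, cy, cz) {
  d <- dim(values)
  cx <- pmin(pmax(cx, 1), d[1]); cy <- pmin(pmax(cy, 1), d[2])
  cz <- pmin(pmax(cz, 1), d[3])
  x0 <- pmax(pmin(floor(cx), d[1] - 1L), 1L)
  y0 <- pmax(pmin(floor(cy), d[2] - 1L), 1L)
  z0 <- pmax(pmin(floor(cz), d[3] - 1L), 1L)
  fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
  x1 <- pmin(x0 + 1L, d[1]); y1 <- pmin(y0 + 1L, d[2]); z1 <- pmin(z0 + 1L, d[3])
  idx <- function(i, j, k) ((k - 1) * d[2] + (j - 1)) * d[1] + i
  v <- as.vector(values)
  v[idx(x0, y0, z0)] * (1 - fx) * (1 - fy) * (1 - fz) +
    v[idx(x1, y0, z0)] * fx * (1 - fy) * (1 - fz) +
    v[idx(x0, y1, z0)] * (1 - fx) * fy * (1 - fz) +
    v[idx(x1, y1, z0)] * fx * fy * (1 - fz) +
    v[idx(x0, y0, z1)] * (1 - fx) * (1 - fy) * fz +
    v[idx(x1, y0, z1)] * fx * (1 - fy) * fz +
    v[idx(x0, y1, z1)] * (1 - fx) * fy * fz +
    v[idx(x1, y1, z1)] * fx * fy * fz
}

#' Resample a volume to a target shape
#'
#' Linear interpolation for intensity volumes, nearest-neighbour for label
#' masks (so mask values stay in the BraTS label set).
#'
#' @param volume 3D array.
#' @param target_shape Integer triple.
#' @param method `"linear"` or `"nearest"`.
#' @return Resampled 3D array of dimension `target_shape`.
#' @export
resize_volume <- function(volume, target_shape,
                          method = c("linear", "nearest")) {
  method <- match.arg(method)
  check_volume(volume)
  d <- dim(volume); t <- as.integer(target_shape)
  if (all(d == t)) return(volume)
  g <- voxel_grid(t)
  # align voxel centres: output centre (i - 0.5)/t maps to input coordinate
  cx <- (g$x - 0.5) * d[1] / t[1] + 0.5
  cy <- (g$y - 0.5) * d[2] / t[2] + 0.5
  cz <- (g$z - 0.5) * d[3] / t[3] + 0.5
  if (method == "nearest") {
    ix <- pmin(pmax(round(cx), 1), d[1])
    iy <- pmin(pmax(round(cy), 1), d[2])
    iz <- pmin(pmax(round(cz), 1), d[3])
    out <- volume[cbind(ix, iy, iz)]
  } else {
    out <- trilinear_gather(volume, cx, cy, cz)
  }
  array(out, dim = t)
}

#' Volumetric contrast-limited adaptive histogram equalization
#'
#' Tile-based 3D CLAHE: intensities are rescaled to `[0, 1]`, a clipped
#' histogram with redistributed excess is equalized within each tile of a
#' 3D grid, and per-voxel mappings are trilinearly interpolated between
#' neighbouring tile mappings to avoid block artifacts. Constant volumes
#' are returned unchanged and `clahe_enabled = FALSE` is the identity.
#'
#' @param volume 3D numeric array with finite values.
#' @param spec A [preprocess_spec()].
#' @return Enhanced volume with values in `[0, 1]` (original intensity
#'   range is not preserved), same shape.
#' @export
contrast_enhance <- function(volume, spec = preprocess_spec()) {
  check_volume(volume)
  if (any(!is.finite(volume))) stopf("volume contains non-finite voxels")
  if (!spec$clahe_enabled) return(volume)
  rng <- range(volume)
  if (rng[2] - rng[1] < 1e-12) return(volume)
  d <- dim(volume)
  v01 <- (volume - rng[1]) / (rng[2] - rng[1])

  tile <- spec$clahe_tile_shape %||% pmax(d %/% 8L, 4L)
  tile <- pmin(as.integer(tile), d)
  nt <- pmax(d %/% tile, 1L)             # tiles per axis
  nbin <- spec$clahe_bins
  bin <- pmin(pmax(ceiling(as.vector(v01) * nbin), 1L), nbin)

  g <- voxel_grid(d)
  tx <- pmin((g$x - 1L) %/% (ceiling(d[1] / nt[1])) + 1L, nt[1])
  ty <- pmin((g$y - 1L) %/% (ceiling(d[2] / nt[2])) + 1L, nt[2])
  tz <- pmin((g$z - 1L) %/% (ceiling(d[3] / nt[3])) + 1L, nt[3])
  tid <- ((tz - 1L) * nt[2] + (ty - 1L)) * nt[1] + tx
  ntile <- prod(nt)

  # per-tile clipped-histogram CDF mapping: M[tile, bin]
  counts <- matrix(0, ntile, nbin)
  tab <- tapply(seq_along(bin), tid, function(ii) tabulate(bin[ii], nbin))
  for (t_i in seq_len(ntile)) {
    h <- tab[[as.character(t_i)]]
    if (is.null(h)) h <- numeric(nbin)
    clip <- max(spec$clahe_clip_limit * sum(h), 1)
    excess <- sum(pmax(h - clip, 0))
    h <- pmin(h, clip) + excess / nbin
    counts[t_i, ] <- cumsum(h) / sum(h)
  }

  # tile-centre coordinates in "tile index space" for interpolation
  ctr_x <- (tx - 0.5); ctr_y <- (ty - 0.5); ctr_z <- (tz - 0.5)
  # voxel position in tile space
  px <- (g$x - 0.5) / (ceiling(d[1] / nt[1]))
  py <- (g$y - 0.5) / (ceiling(d[2] / nt[2]))
  pz <- (g$z - 0.5) / (ceiling(d[3] / nt[3]))
  lookup <- function(ix, iy, iz) {
    id <- ((iz - 1L) * nt[2] + (iy - 1L)) * nt[1] + ix
    counts[cbind(id, bin)]
  }
  interp_axis <- function(p, n) {
    c0 <- pmin(pmax(floor(p + 0.5), 1L), n)
    c1 <- pmin(c0 + 1L, n)
    f <- pmin(pmax(p + 0.5 - c0, 0), 1)
    list(lo = as.integer(c0), hi = as.integer(c1), f = f)
  }
  ax <- interp_axis(px, nt[1]); ay <- interp_axis(py, nt[2])
  az <- interp_axis(pz, nt[3])
  out <-
    lookup(ax$lo, ay$lo, az$lo) * (1 - ax$f) * (1 - ay$f) * (1 - az$f) +
    lookup(ax$hi, ay$lo, az$lo) * ax$f * (1 - ay$f) * (1 - az$f) +
    lookup(ax$lo, ay$hi, az$lo) * (1 - ax$f) * ay$f * (1 - az$f) +
    lookup(ax$hi, ay$hi, az$lo) * ax$f * ay$f * (1 - az$f) +
    lookup(ax$lo, ay$lo, az$hi) * (1 - ax$f) * (1 - ay$f) * az$f +
    lookup(ax$hi, ay$lo, az$hi) * ax$f * (1 - ay$f) * az$f +
    lookup(ax$lo, ay$hi, az$hi) * (1 - ax$f) * ay$f * az$f +
    lookup(ax$hi, ay$hi, az$hi) * ax$f * ay$f * az$f
  out[as.vector(volume == 0)] <- 0       # keep skull-stripped background at 0
  array(out, dim = d)
}

# Bounding box (inclusive voxel index ranges) of mask voxels with labels in
# the tumour set {1, 2, 4}.
mask_bounding_box <- function(mask) {
  pos <- which(mask == 1L | mask == 2L | mask == 4L, arr.ind = TRUE)
  if (nrow(pos) == 0L) return(NULL)
  rbind(lo = apply(pos, 2, min), hi = apply(pos, 2, max))
}

#' Mask sanity filter
#'
#' Rejects segmentation masks that are empty or whose tumour bounding box
#' occupies more than `max_roi_volume_fraction` of the field of view
#' (implausibly large boxes typically indicate a failed segmentation).
#'
#' @param mask 3D integer mask with BraTS labels.
#' @param spec A [preprocess_spec()].
#' @return List with `accept` (logical) and `reason` (string, `NA` when
#'   accepted) plus the measured `box_fraction`.
#' @export
filter_mask_anomaly <- function(mask, spec = preprocess_spec()) {
  check_volume(mask)
  bb <- mask_bounding_box(mask)
  if (is.null(bb))
    return(list(accept = FALSE, reason = "empty mask", box_fraction = 0))
  frac <- prod(bb["hi", ] - bb["lo", ] + 1) / prod(dim(mask))
  if (frac > spec$max_roi_volume_fraction)
    return(list(accept = FALSE,
                reason = sprintf("bounding box fraction %.3f exceeds cap %.3f",
                                 frac, spec$max_roi_volume_fraction),
                box_fraction = frac))
  list(accept = TRUE, reason = NA_character_, box_fraction = frac)
}

#' Extract and resample the tumour region of interest
#'
#' Crops all modalities (and the mask) to the bounding box of the union of
#' tumour labels \{1, 2, 4\}, pads it by `roi_margin` isotropically, and
#' resamples to `spec$target_shape` (linear for intensities, nearest for
#' the mask).
#'
#' @param volumes Named list of 3D arrays (one per modality).
#' @param mask 3D integer mask.
#' @param spec A [preprocess_spec()].
#' @return List with `volumes` (cropped+resized, same names), `mask`
#'   (resized) and `box` (the padded bounding box used).
#' @export
extract_roi <- function(volumes, mask, spec = preprocess_spec()) {
  check_volume(mask)
  bb <- mask_bounding_box(mask)
  if (is.null(bb)) stopf("ROI error: empty mask")
  d <- dim(mask)
  span <- bb["hi", ] - bb["lo", ] + 1
  pad <- ceiling(span * spec$roi_margin)
  lo <- pmax(bb["lo", ] - pad, 1)
  hi <- pmin(bb["hi", ] + pad, d)
  crop <- function(v) v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  out <- lapply(volumes, function(v) {
    check_volume(v)
    if (!all(dim(v) == d)) stopf("volume/mask shape mismatch")
    resize_volume(crop(v), spec$target_shape, method = "linear")
  })
  list(volumes = out,
       mask = resize_volume(crop(mask), spec$target_shape, method = "nearest"),
       box = rbind(lo = lo, hi = hi))
}

# Separable Gaussian blur along each axis (reflecting boundaries), used by
# augmentation.
gaussian_blur3d <- function(volume, sigma = 1) {
  if (sigma <= 0) return(volume)
  r <- max(1L, ceiling(2 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma); k <- k / sum(k)
  d <- dim(volume)
  blur_axis <- function(v, axis) {
    out <- array(0, dim = d)
    for (o in seq(-r, r)) {
      idx <- seq_len(d[axis]) + o
      idx <- pmin(pmax(idx, 1L), d[axis])          # replicate edges
      sl <- switch(axis,
                   v[idx, , , drop = FALSE],
                   v[, idx, , drop = FALSE],
                   v[, , idx, drop = FALSE])
      out <- out + k[o + r + 1] * sl
    }
    out
  }
  blur_axis(blur_axis(blur_axis(volume, 1L), 2L), 3L)
}

# In-plane rotation of a volume by `angle` degrees about the z axis,
# trilinear resampling, zeros outside.
rotate_xy <- function(volume, angle) {
  if (abs(angle) < 1e-12) return(volume)
  d <- dim(volume)
  th <- angle * pi / 180
  g <- voxel_grid(d)
  cx0 <- g$x - (d[1] + 1) / 2
  cy0 <- g$y - (d[2] + 1) / 2
  sx <- cos(th) * cx0 + sin(th) * cy0 + (d[1] + 1) / 2
  sy <- -sin(th) * cx0 + cos(th) * cy0 + (d[2] + 1) / 2
  inside <- sx >= 1 & sx <= d[1] & sy >= 1 & sy <= d[2]
  out <- trilinear_gather(volume, sx, sy, g$z)
  out[!inside] <- 0
  array(out, dim = d)
}

shift_volume <- function(volume, by) {
  d <- dim(volume)
  out <- array(0, dim = d)
  src <- lapply(1:3, function(a) {
    i <- seq_len(d[a]) - by[a]
    ok <- i >= 1 & i <= d[a]
    list(dst = seq_len(d[a])[ok], src = i[ok])
  })
  out[src[[1]]$dst, src[[2]]$dst, src[[3]]$dst] <-
    volume[src[[1]]$src, src[[2]]$src, src[[3]]$src]
  out
}

#' Augmentation configuration
#'
#' Probabilities and magnitudes for the on-the-fly training augmentations:
#' additive Gaussian noise, Gaussian blur, small-angle in-plane rotation,
#' integer voxel shifts and axis flips. Magnitudes are expressed in
#' normalized-intensity units (apply after [normalize_nonzero()]).
#'
#' @param p_noise,p_blur,p_rotate,p_shift,p_flip Per-transform
#'   probabilities; set all to 0 for the identity.
#' @param noise_sd Additive noise standard deviation (normalized units).
#' @param blur_sigma_max Maximum blur sigma in voxels.
#' @param rotate_max_deg Maximum absolute rotation angle (degrees).
#' @param shift_max Maximum absolute shift per axis (voxels).
#' @return List of class `augment_config`.
#' @export
augment_config <- function(p_noise = 0.5, p_blur = 0.3, p_rotate = 0.5,
                           p_shift = 0.5, p_flip = 0.5,
                           noise_sd = 0.05, blur_sigma_max = 1.0,
                           rotate_max_deg = 15, shift_max = 3L) {
  structure(list(p_noise = p_noise, p_blur = p_blur, p_rotate = p_rotate,
                 p_shift = p_shift, p_flip = p_flip, noise_sd = noise_sd,
                 blur_sigma_max = blur_sigma_max,
                 rotate_max_deg = rotate_max_deg,
                 shift_max = as.integer(shift_max)),
            class = "augment_config")
}

#' Apply a seeded random augmentation to a set of modality volumes
#'
#' Draws one random geometric/intensity transform per call and applies the
#' same geometric transform to every modality (so modalities stay
#' co-registered); noise is drawn independently per modality. Identical
#' seeds give identical outputs; labels and percentages attached to the
#' record are untouched by construction.
#'
#' @param volumes Named list of 3D arrays.
#' @param seed Integer seed.
#' @param config An [augment_config()].
#' @return Named list of augmented volumes, same shapes.
#' @export
augment_volumes <- function(volumes, seed, config = augment_config()) {
  with_seed(seed, {
    d <- dim(volumes[[1]])
    do_flip <- runif(1) < config$p_flip
    flip_axis <- sample(1:2, 1)
    do_rot <- runif(1) < config$p_rotate
    ang <- runif(1, -config$rotate_max_deg, config$rotate_max_deg)
    do_shift <- runif(1) < config$p_shift
    sh <- sample(seq(-config$shift_max, config$shift_max), 3, replace = TRUE)
    do_blur <- runif(1) < config$p_blur
    sig <- runif(1, 0.3, config$blur_sigma_max)
    do_noise <- runif(1) < config$p_noise
    lapply(volumes, function(v) {
      check_volume(v)
      if (do_rot) v <- rotate_xy(v, ang)
      if (do_shift) v <- shift_volume(v, sh)
      if (do_flip) {
        v <- if (flip_axis == 1L) v[rev(seq_len(d[1])), , , drop = FALSE]
             else v[, rev(seq_len(d[2])), , drop = FALSE]
        v <- array(v, dim = d)
      }
      if (do_blur) v <- gaussian_blur3d(v, sig)
      if (do_noise) v <- v + array(rnorm(prod(d), sd = config$noise_sd), dim = d)
      v
    })
  })
}

#' Preprocess one patient record
#'
#' The package's standard pipeline: optional mask sanity filtering, ROI
#' extraction or whole-volume resampling, contrast enhancement (before
#' normalization) and non-zero standardization, per modality.
#'
#' @param record A `patient_record`.
#' @param spec A [preprocess_spec()].
#' @return List with `volumes` (processed arrays), `mask` (resampled),
#'   `stats` (per-modality normalization stats) and `filter` (the mask
#'   filter verdict).
#' @export
preprocess_record <- function(record, spec = preprocess_spec()) {
  verdict <- filter_mask_anomaly(record$mask, spec)
  if (!verdict$accept)
    stopf("record %s rejected by mask filter: %s",
          record$patient_id, verdict$reason)
  if (spec$mode == "roi") {
    roi <- extract_roi(record$volumes, record$mask, spec)
    vols <- roi$volumes; mk <- roi$mask
  } else {
    vols <- lapply(record$volumes, resize_volume, target_shape = spec$target_shape)
    mk <- resize_volume(record$mask, spec$target_shape, method = "nearest")
  }
  stats <- list()
  for (m in names(vols)) {
    v <- contrast_enhance(vols[[m]], spec)
    nn <- normalize_nonzero(v)
    vols[[m]] <- nn$volume
    stats[[m]] <- nn$stats
  }
  list(volumes = vols, mask = mk, stats = stats, filter = verdict)
}
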