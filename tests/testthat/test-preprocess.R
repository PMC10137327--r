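make_head_volume <- function(dims = c(12L, 12L, 6L), seed = 1) {
  set.seed(seed)
  v <- array(0, dim = dims)
  core <- array(runif(prod(dims - 4L), 0.2, 1), dim = dims - 4L)
  v[3:(dims[1] - 2), 3:(dims[2] - 2), 3:(dims[3] - 2)] <- core
  v
}

test_that("non-zero standardization has exact moments and keeps zeros", {
  v <- make_head_volume()
  out <- normalize_nonzero(v)
  nz <- out$volume[out$volume != 0 | v != 0]   # the original support
  nz <- out$volume[v != 0]
  expect_lt(abs(mean(nz)), 1e-6)
  expect_lt(abs(sqrt(mean((nz - mean(nz))^2)) - 1), 1e-6)
  expect_true(all(out$volume[v == 0] == 0))
})

test_that("two-valued volume maps to plus/minus one (population std)", {
  v <- array(0, dim = c(4, 4, 2))
  v[1, 1, 1] <- 2; v[2, 1, 1] <- 4
  out <- normalize_nonzero(v)$volume
  expect_equal(out[1, 1, 1], -1)
  expect_equal(out[2, 1, 1], 1)
})

test_that("standardization is idempotent and shift/scale-equivariant", {
  v <- make_head_volume(seed = 4)
  once <- normalize_nonzero(v)$volume
  twice <- normalize_nonzero(once)$volume
  expect_equal(twice, once, tolerance = 1e-10)
  # affine changes of the non-zero support give the same standardized volume
  w <- v; w[v != 0] <- 3 * v[v != 0] + 5
  expect_equal(normalize_nonzero(w)$volume, once, tolerance = 1e-10)
})

test_that("degenerate volumes are rejected by normalization", {
  expect_error(normalize_nonzero(array(0, dim = c(4, 4, 2))), "all zero")
  const <- array(0, dim = c(4, 4, 2)); const[1:8] <- 2
  expect_error(normalize_nonzero(const), "zero variance")
})

test_that("contrast enhancement is well-behaved at the edges", {
  spec <- preprocess_spec("roi", target_shape = c(8, 8, 4))
  const <- array(0.7, dim = c(16, 16, 8))
  expect_identical(contrast_enhance(const, spec), const)
  spec_off <- preprocess_spec("roi", target_shape = c(8, 8, 4),
                              clahe_enabled = FALSE)
  v <- make_head_volume(c(16L, 16L, 8L))
  expect_identical(contrast_enhance(v, spec_off), v)
  v[1] <- NaN
  expect_error(contrast_enhance(v, spec), "non-finite")
})

test_that("CLAHE increases the per-tile intensity spread of a flat gradient", {
  dims <- c(16L, 16L, 8L)
  g <- array(rep(seq(0.45, 0.55, length.out = dims[1]), times = prod(dims[2:3])),
             dim = dims)
  set.seed(2)
  g <- g + array(runif(prod(dims), 0, 0.005), dim = dims)
  spec <- preprocess_spec("roi", clahe_tile_shape = c(8L, 16L, 8L),
                          clahe_clip_limit = 0.05)
  out <- contrast_enhance(g, spec)
  expect_identical(dim(out), dims)
  expect_true(all(out >= 0 & out <= 1))
  for (half in list(1:8, 9:16)) {
    expect_gt(sd(out[half, , ]), sd(g[half, , ]))
  }
  # deterministic
  expect_identical(out, contrast_enhance(g, spec))
})

test_that("resampling is exact on trivial cases and label-preserving", {
  v <- make_head_volume()
  expect_identical(resize_volume(v, dim(v)), v)
  m <- array(sample(c(0L, 1L, 2L, 4L), 12 * 12 * 6, TRUE), dim = c(12, 12, 6))
  rm_ <- resize_volume(m, c(8, 8, 4), method = "nearest")
  expect_true(all(rm_ %in% c(0L, 1L, 2L, 4L)))
  # constant volumes stay constant under linear interpolation
  cv <- array(3.5, dim = c(6, 6, 4))
  expect_true(all(abs(resize_volume(cv, c(9, 9, 5)) - 3.5) < 1e-12))
})

test_that("ROI extraction contains every tumour voxel", {
  cfg <- small_cohort()
  rec <- generate_phantom(30, 1, cfg, 17)
  spec <- preprocess_spec("roi", target_shape = c(8, 8, 4))
  roi <- extract_roi(rec$volumes, rec$mask, spec)
  pos <- which(rec$mask > 0, arr.ind = TRUE)
  expect_true(all(pos[, 1] >= roi$box["lo", 1] & pos[, 1] <= roi$box["hi", 1]))
  expect_true(all(pos[, 2] >= roi$box["lo", 2] & pos[, 2] <= roi$box["hi", 2]))
  expect_true(all(pos[, 3] >= roi$box["lo", 3] & pos[, 3] <= roi$box["hi", 3]))
  expect_identical(dim(roi$volumes$FLAIR), c(8L, 8L, 4L))
})

test_that("single-voxel masks give a centred box; full masks reduce to resize", {
  dims <- c(12L, 12L, 6L)
  m <- array(0L, dim = dims); m[6, 7, 3] <- 4L
  v <- list(a = make_head_volume(dims))
  spec <- preprocess_spec("roi", target_shape = c(4, 4, 2), roi_margin = 0)
  roi <- extract_roi(v, m, spec)
  expect_identical(unname(roi$box["lo", ]), c(6, 7, 3))
  expect_identical(unname(roi$box["hi", ]), c(6, 7, 3))

  full <- array(1L, dim = dims)
  roi_full <- extract_roi(v, full, spec)
  expect_equal(roi_full$volumes$a, resize_volume(v$a, c(4, 4, 2)),
               tolerance = 1e-12)
  expect_error(extract_roi(v, array(0L, dim = dims), spec), "empty mask")
})

test_that("mask anomaly filter applies the bounding-box fraction rule", {
  dims <- c(16L, 16L, 8L)
  spec <- preprocess_spec("roi", max_roi_volume_fraction = 0.5)
  expect_false(filter_mask_anomaly(array(0L, dim = dims), spec)$accept)
  small <- array(0L, dim = dims); small[7:9, 7:9, 4:5] <- 1L
  verdict <- filter_mask_anomaly(small, spec)
  expect_true(verdict$accept)
  expect_lt(verdict$box_fraction, 0.1)
  all1 <- array(1L, dim = dims)
  expect_false(filter_mask_anomaly(all1, spec)$accept)
  expect_equal(filter_mask_anomaly(all1, spec)$box_fraction, 1)
})

test_that("augmentation is seeded, optional and involutive for flips", {
  cfg <- small_cohort()
  rec <- generate_phantom(20, 1, cfg, 23)
  vols <- rec$volumes
  none <- augment_config(p_noise = 0, p_blur = 0, p_rotate = 0,
                         p_shift = 0, p_flip = 0)
  expect_identical(augment_volumes(vols, 5, none), vols)
  a1 <- augment_volumes(vols, 5, augment_config())
  a2 <- augment_volumes(vols, 5, augment_config())
  expect_identical(a1, a2)
  flip_only <- augment_config(p_noise = 0, p_blur = 0, p_rotate = 0,
                              p_shift = 0, p_flip = 1)
  f1 <- augment_volumes(vols, 9, flip_only)
  f2 <- augment_volumes(f1, 9, flip_only)
  expect_equal(f2, vols, tolerance = 1e-12)
})

test_that("the full preprocessing pipeline is modality-order invariant", {
  cfg <- small_cohort()
  rec <- generate_phantom(40, 1, cfg, 31)
  spec <- preprocess_spec("roi", target_shape = c(8, 8, 4))
  out1 <- preprocess_record(rec, spec)
  rec_perm <- rec
  rec_perm$volumes <- rec$volumes[rev(names(rec$volumes))]
  out2 <- preprocess_record(rec_perm, spec)
  expect_identical(out1$volumes$FLAIR, out2$volumes$FLAIR)
  expect_identical(out1$volumes$T1wCE, out2$volumes$T1wCE)
})
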