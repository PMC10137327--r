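#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic operations in the
# package go through this so that cohorts, training runs and perturbations
# are bit-reproducible given their seeds.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream of per-item seeds from a master seed, kept within the
# 32-bit integer range.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coordinate grids for a 3D array, returned as vectors aligned with
# as.vector(array) ordering (first index fastest).
voxel_grid <- function(dims) {
  list(
    x = rep.int(seq_len(dims[1]), times = dims[2] * dims[3]),
    y = rep.int(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]),
    z = rep(seq_len(dims[3]), each = dims[1] * dims[2])
  )
}

is_volume <- function(v) is.array(v) && length(dim(v)) == 3L
check_volume <- function(v, what = "volume") {
  if (!is_volume(v)) stopf("%s must be a 3D array", what)
  invisible(v)
}
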