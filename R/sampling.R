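# Quasi-random point sampling for the stochastic metric.

# run expr with a temporary RNG state; the caller's stream is untouched
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

# deterministic small-integer seed derived from a (seed, iteration) pair
derive_seed <- function(seed, iteration) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(iteration) * 7919 +
                12345) %% 2147483647)
}

# van der Corput radical inverse for a vector of 0-based indices
radical_inverse <- function(i, base) {
  r <- numeric(length(i))
  f <- 1 / base
  ii <- as.numeric(i)
  while (any(ii > 0)) {
    r <- r + f * (ii %% base)
    ii <- ii %/% base
    f <- f / base
  }
  r
}

# n x 3 Halton points (bases 2, 3, 5) starting at sequence index `start`
halton_points <- function(n, start = 1L) {
  idx <- seq.int(start, length.out = n)
  cbind(radical_inverse(idx, 2), radical_inverse(idx, 3),
        radical_inverse(idx, 5))
}

#' Draw metric sample points inside a mask
#'
#' Points are taken from the Halton sequence (bases 2, 3, 5) mapped onto the
#' mask bounding box with a per-iteration random offset derived from
#' `(seed, iteration)`; candidates falling outside the mask are rejected and
#' the sequence advanced. The draw is deterministic given `(seed,
#' iteration)`. When the mask holds fewer than `10 * n` voxels, the sampler
#' falls back to seeded with-replacement draws of jittered voxel centres.
#'
#' @param mask a [segment_bone()] `bone_mask` (or any list with logical
#'   `mask`, `spacing`, `origin`).
#' @param n number of points.
#' @param seed,iteration integers identifying the draw.
#' @param warn emit the fallback warning (drivers disable it after the first
#'   iteration).
#' @return n x 3 matrix of world coordinates, all strictly inside mask
#'   voxels.
#' @export
sample_points <- function(mask, n = 2000, seed = 0L, iteration = 0L,
                          warn = TRUE) {
  stopifnot(n >= 1)
  m <- mask$mask
  d <- dim(m)
  vox <- which(m)
  if (!length(vox)) stop("cannot sample from an empty mask")
  if (length(vox) < 10 * n) {
    if (warn)
      warning("mask holds fewer than 10x the sample count; ",
              "falling back to with-replacement voxel draws")
    pts <- with_seed(derive_seed(seed, iteration), {
      pick <- vox[sample.int(length(vox), n, replace = TRUE)]
      jit <- matrix(runif(3 * n, -0.499, 0.499), n, 3)
      k <- (pick - 1L) %/% (d[1] * d[2])
      j <- ((pick - 1L) %/% d[1]) %% d[2]
      i <- (pick - 1L) %% d[1]
      cbind(i, j, k) + jit
    })
    return(sweep(sweep(pts, 2L, mask$spacing, "*"), 2L, mask$origin, "+"))
  }
  # index bounding box of the mask
  k <- (vox - 1L) %/% (d[1] * d[2])
  j <- ((vox - 1L) %/% d[1]) %% d[2]
  i <- (vox - 1L) %% d[1]
  lo <- c(min(i), min(j), min(k))
  hi <- c(max(i), max(j), max(k))
  ext <- hi - lo + 1
  offset <- with_seed(derive_seed(seed, iteration), runif(3))
  got <- matrix(0, 0, 3)
  start <- 1L
  tried <- 0L
  while (nrow(got) < n) {
    batch <- max(2L * (n - nrow(got)), 1000L)
    u <- halton_points(batch, start)
    start <- start + batch
    tried <- tried + batch
    u <- (u + rep(offset, each = batch)) %% 1
    cand <- sweep(sweep(u, 2L, ext, "*"), 2L, lo - 0.5, "+")
    ci <- pmin(pmax(round(cand[, 1]), 0), d[1] - 1)
    cj <- pmin(pmax(round(cand[, 2]), 0), d[2] - 1)
    ck <- pmin(pmax(round(cand[, 3]), 0), d[3] - 1)
    keep <- m[1L + ci + d[1] * (cj + d[2] * ck)]
    got <- rbind(got, cand[keep, , drop = FALSE])
    if (tried >= 10000L && nrow(got) / tried < 1e-4)
      stop("degenerate mask: Halton acceptance rate below 1e-4")
  }
  pts <- got[seq_len(n), , drop = FALSE]
  sweep(sweep(pts, 2L, mask$spacing, "*"), 2L, mask$origin, "+")
}

# trivial all-TRUE mask over an image grid, for full-grid sampling
full_grid_mask <- function(image) {
  structure(list(mask = array(TRUE, img_dim(image)),
                 bone = NULL, prosthesis_excluded = FALSE, empty = FALSE,
                 spacing = image$spacing, origin = image$origin),
            class = "bone_mask")
}
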