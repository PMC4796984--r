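#' Count nuclei in a confocal z-stack
#'
#' Embryo cell number is scored from a DAPI-style z-stack: voxels at or
#' above `threshold_frac` of the stack maximum are foreground, foreground
#' is partitioned into 26-connected 3D components, components smaller than
#' `min_volume` voxels are discarded, and the surviving component count is
#' returned. Because the threshold is relative to the stack maximum the
#' count is invariant under uniform intensity scaling.
#'
#' @param zstack Numeric 3D array `(y, x, z)`.
#' @param threshold_frac Fraction of the stack maximum used as the
#'   intensity threshold (default 0.5).
#' @param min_volume Minimum component volume in voxels (default 27, a
#'   3x3x3 neighbourhood).
#' @return Integer nucleus count; an all-zero stack returns 0.
#' @export
count_nuclei <- function(zstack, threshold_frac = 0.5, min_volume = 27L) {
  stopifnot(is.array(zstack), length(dim(zstack)) == 3L)
  mx <- max(zstack)
  if (mx <= 0) return(0L)
  fg <- zstack >= threshold_frac * mx
  sizes <- label_components_3d(fg)
  sum(sizes >= min_volume)
}

#' 26-connected component labelling of a 3D mask
#'
#' Breadth-first flood fill over foreground voxels; two voxels are
#' connected when all coordinate offsets are in `{-1, 0, 1}` (faces, edges
#' and corners).
#'
#' @param fg Logical 3D array.
#' @return Integer vector of component sizes (voxels), one per component.
#' @keywords internal
label_components_3d <- function(fg) {
  d <- dim(fg)
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  off <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  off <- off[!(off$dy == 0 & off$dx == 0 & off$dz == 0), ]
  lin_off <- off$dy + off$dx * ny + off$dz * ny * nx

  unvisited <- fg
  sizes <- integer(0)
  todo <- which(fg)
  for (seed in todo) {
    if (!unvisited[seed]) next
    unvisited[seed] <- FALSE
    frontier <- seed
    size <- 0L
    while (length(frontier)) {
      size <- size + length(frontier)
      # neighbour candidates, filtered to stay inside the box (linear
      # offsets wrap across faces, so check coordinates explicitly)
      i0 <- rep(frontier, each = length(lin_off))
      cand <- i0 + lin_off
      y0 <- (i0 - 1L) %% ny
      x0 <- ((i0 - 1L) %/% ny) %% nx
      z0 <- (i0 - 1L) %/% (ny * nx)
      dy <- rep(off$dy, times = length(frontier))
      dx <- rep(off$dx, times = length(frontier))
      dz <- rep(off$dz, times = length(frontier))
      ok <- (y0 + dy) >= 0 & (y0 + dy) < ny &
            (x0 + dx) >= 0 & (x0 + dx) < nx &
            (z0 + dz) >= 0 & (z0 + dz) < nz
      cand <- unique(cand[ok])
      cand <- cand[unvisited[cand]]
      unvisited[cand] <- FALSE
      frontier <- cand
    }
    sizes <- c(sizes, size)
  }
  sizes
}

#' Simulate a nucleus z-stack with known count
#'
#' Places `n_nuclei` non-overlapping Gaussian blobs (spherical, standard
#' deviation `sigma_px`) on a dark background and adds Gaussian noise.
#' Centers are rejection-sampled with a minimum separation of
#' `4 * sigma_px`, which guarantees the half-maximum surfaces of distinct
#' nuclei never merge, so a noiseless stack thresholded at half max has
#' exactly `n_nuclei` 26-connected components.
#'
#' @param n_nuclei Number of nuclei (0 allowed: empty stack).
#' @param dim_yxz Stack dimensions `(y, x, z)` in voxels.
#' @param sigma_px Blob standard deviation, voxels.
#' @param peak Blob peak intensity, counts.
#' @param noise_sd Gaussian noise, counts.
#' @param seed Integer seed.
#' @param max_tries Total rejection-sampling attempts before giving up.
#' @return List: `stack` (3D array), `count` (true nucleus count),
#'   `centers` (n x 3 matrix of 0-based `(y, x, z)` centers).
#' @export
simulate_nucleus_stack <- function(n_nuclei, dim_yxz = c(96, 96, 24),
                                   sigma_px = 2, peak = 1000, noise_sd = 0,
                                   seed = 1L, max_tries = 20000L) {
  set.seed(seed)
  ny <- dim_yxz[1]; nx <- dim_yxz[2]; nz <- dim_yxz[3]
  margin <- ceiling(2 * sigma_px)
  min_sep2 <- (4 * sigma_px)^2
  if (n_nuclei > 0 &&
      (ny <= 2 * margin || nx <= 2 * margin || nz <= 2 * margin)) {
    stop("frame too small for blob margin; use a larger frame", call. = FALSE)
  }
  centers <- matrix(numeric(0), ncol = 3)
  tries <- 0L
  while (nrow(centers) < n_nuclei) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not place ", n_nuclei, " non-overlapping nuclei after ",
           max_tries, " attempts; use a larger frame", call. = FALSE)
    }
    cand <- c(stats::runif(1, margin, ny - 1 - margin),
              stats::runif(1, margin, nx - 1 - margin),
              stats::runif(1, margin, nz - 1 - margin))
    if (nrow(centers) == 0 ||
        all(colSums((t(centers) - cand)^2) >= min_sep2)) {
      centers <- rbind(centers, cand)
    }
  }
  stack <- array(0, dim = c(ny, nx, nz))
  if (n_nuclei > 0) {
    ys <- 0:(ny - 1); xs <- 0:(nx - 1); zs <- 0:(nz - 1)
    for (i in seq_len(n_nuclei)) {
      cy <- centers[i, 1]; cx <- centers[i, 2]; cz <- centers[i, 3]
      gy <- exp(-(ys - cy)^2 / (2 * sigma_px^2))
      gx <- exp(-(xs - cx)^2 / (2 * sigma_px^2))
      gz <- exp(-(zs - cz)^2 / (2 * sigma_px^2))
      blob <- peak * (gy %o% gx) %o% gz
      blob[blob < 1e-4 * peak] <- 0  # truncate far tails
      stack <- stack + blob
    }
  }
  if (noise_sd > 0) {
    stack <- stack + array(stats::rnorm(length(stack), sd = noise_sd), dim(stack))
  }
  dimnames(centers) <- NULL
  list(stack = stack, count = as.integer(n_nuclei), centers = centers)
}
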