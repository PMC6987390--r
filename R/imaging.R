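# Confocal-like stack rendering and projection.  Coordinate convention:
# x = lateral, y = vertical (rotation) axis, z = optical axis; voxel arrays
# are indexed [x, y, z] with half-open voxel extents and physical position
# (i - 1) * d .. i * d relative to `origin`.

#' Calibrated image stack
#'
#' @param voxels 3D numeric array indexed `[x, y, z]`, finite and >= 0.
#' @param voxel_size `(dx, dy, dz)` um.
#' @param origin physical position of the low corner of voxel (1,1,1).
#' @return Object of class `image_stack`.
#' @export
image_stack <- function(voxels, voxel_size, origin = c(0, 0, 0)) {
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  if (any(!is.finite(voxels)) || any(voxels < 0))
    stop("intensities must be finite and non-negative")
  structure(list(voxels = voxels, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin),
                 depth_um = dim(voxels)[3] * voxel_size[3]),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "Image stack: %d x %d x %d voxels (%.3g x %.3g x %.3g um), depth %.3g um\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    x$depth_um))
  invisible(x)
}

#' Detection (modality) models
#'
#' `"IF"` detects every structure.  `"DAB"` emulates the lower sensitivity
#' of chromogenic labelling for very thin processes: whole segments whose
#' mean radius falls below `threshold` are lost with probability `prob`.
#' The defaults were calibrated once against the control simulator regime
#' so that the induced length-detection deficit is about 30%.
#'
#' @param modality `"IF"` or `"DAB"`.
#' @param threshold radius threshold, um.
#' @param prob dropout probability for sub-threshold segments.
#' @return List with the detection parameters.
#' @export
modality_model <- function(modality = c("IF", "DAB"),
                           threshold = 0.26, prob = 0.66) {
  modality <- match.arg(modality)
  list(modality = modality,
       threshold = if (modality == "DAB") threshold else 0,
       prob = if (modality == "DAB") prob else 0)
}

#' Apply a detection model to a segment set
#'
#' @param segments segment matrix (columns include `r1`, `r2`).
#' @param model a [modality_model()].
#' @param seed optional integer seed.
#' @return The surviving segments.
#' @export
apply_modality <- function(segments, model, seed = NULL) {
  if (model$prob <= 0 || nrow(segments) == 0) return(segments)
  with_seed(seed, {
    rmean <- (segments[, 7] + segments[, 8]) / 2
    thin <- rmean < model$threshold
    drop <- thin & runif(nrow(segments)) < model$prob
    segments[!drop, , drop = FALSE]
  })
}

#' Render a section's curves into a calibrated stack
#'
#' Process centrelines are rasterised with radius-dependent intensity
#' (voxels within a segment's radius are filled), optionally blurred with
#' an isotropic Gaussian PSF and degraded with additive Gaussian noise.
#' The DAB modality drops thin segments before rasterisation (see
#' [modality_model()]).  An empty section yields an all-background stack.
#'
#' @param section a `tissue_section` or a 3D segment matrix.
#' @param window list `xlim`, `ylim` of the rendered frame, um.
#' @param z_range `(z0, z1)` rendered depth range, um.
#' @param voxel_size `(dx, dy, dz)` um.
#' @param modality a [modality_model()] or modality name.
#' @param psf_sigma Gaussian PSF sigma, um (0 = none).
#' @param noise_sd additive Gaussian noise SD (0 = none).
#' @param seed integer seed (dropout and noise).
#' @return An [image_stack()].
#' @export
render_stack <- function(section, window = NULL, z_range = NULL,
                         voxel_size = c(0.5, 0.5, 0.5),
                         modality = "IF", psf_sigma = 0, noise_sd = 0,
                         seed = NULL) {
  segs <- if (inherits(section, "tissue_section")) section$segments else section
  if (inherits(section, "tissue_section")) {
    if (is.null(window))
      window <- list(xlim = c(0, section$xy_dims[1]),
                     ylim = c(0, section$xy_dims[2]))
    if (is.null(z_range)) z_range <- c(0, section$t_measured)
  }
  if (is.null(window) || is.null(z_range))
    stop("window and z_range required for raw segment input")
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  if (is.character(modality)) modality <- modality_model(modality)
  with_seed(seed, {
    segs <- apply_modality(segs, modality)
    nx <- max(1L, ceiling(diff(window$xlim) / voxel_size[1]))
    ny <- max(1L, ceiling(diff(window$ylim) / voxel_size[2]))
    nz <- max(1L, ceiling(diff(z_range) / voxel_size[3]))
    arr <- array(0, c(nx, ny, nz))
    origin <- c(window$xlim[1], window$ylim[1], z_range[1])
    if (nrow(segs) > 0) {
      step <- min(voxel_size) / 2
      for (i in seq_len(nrow(segs))) {
        p <- segs[i, 1:3]; q <- segs[i, 4:6]
        len <- sqrt(sum((q - p)^2))
        if (len == 0) next
        k <- max(1L, ceiling(len / step))
        t <- (seq_len(k) - 0.5) / k
        pts <- cbind(p[1] + t * (q[1] - p[1]), p[2] + t * (q[2] - p[2]),
                     p[3] + t * (q[3] - p[3]))
        r <- segs[i, 7] + t * (segs[i, 8] - segs[i, 7])
        ix <- floor((pts[, 1] - origin[1]) / voxel_size[1]) + 1L
        iy <- floor((pts[, 2] - origin[2]) / voxel_size[2]) + 1L
        iz <- floor((pts[, 3] - origin[3]) / voxel_size[3]) + 1L
        # dilate deposits laterally when the radius exceeds half a voxel
        reach <- floor(max(r) / voxel_size[1] + 0.5)
        offs <- expand.grid(ox = -reach:reach, oy = -reach:reach)
        offs <- offs[offs$ox^2 + offs$oy^2 <= (reach + 0.25)^2, , drop = FALSE]
        for (o in seq_len(nrow(offs))) {
          jx <- ix + offs$ox[o]; jy <- iy + offs$oy[o]
          ok <- jx >= 1 & jx <= nx & jy >= 1 & jy <= ny & iz >= 1 & iz <= nz
          if (any(ok)) {
            lin <- cbind(jx[ok], jy[ok], iz[ok])
            arr[lin] <- pmax(arr[lin], r[ok])
          }
        }
      }
    }
    if (psf_sigma > 0) {
      sig_px <- psf_sigma / voxel_size[1]
      for (z in seq_len(nz))
        arr[, , z] <- EBImage::gblur(arr[, , z], sigma = sig_px)
      if (nz > 1) {
        sig_z <- psf_sigma / voxel_size[3]
        hw <- max(1L, ceiling(3 * sig_z))
        kern <- dnorm(-hw:hw, sd = sig_z)
        kern <- kern / sum(kern)
        arr <- array(apply(arr, c(1, 2), function(v) {
          as.numeric(filter(c(rep(0, hw), v, rep(0, hw)), kern,
                            sides = 2))[(hw + 1):(hw + nz)]
        }), c(nz, nx, ny))
        arr <- aperm(arr, c(2, 3, 1))
      }
      arr[is.na(arr)] <- 0
      arr <- pmax(arr, 0)   # FFT blur can leave tiny negative ringing
    }
    if (noise_sd > 0) arr <- pmax(0, arr + rnorm(length(arr), 0, noise_sd))
    image_stack(arr, voxel_size, origin)
  })
}

#' Extract a sub-stack of given depth
#'
#' @param stack an [image_stack()].
#' @param depth depth to keep, um.
#' @param from `"top"` (highest z, default) or `"bottom"`; `offset` shifts
#'   the window, um.
#' @param offset offset from the chosen face, um.
#' @return An [image_stack()].
#' @export
substack <- function(stack, depth, from = c("top", "bottom"), offset = 0) {
  from <- match.arg(from)
  nz <- dim(stack$voxels)[3]
  k <- max(1L, round(depth / stack$voxel_size[3]))
  koff <- round(offset / stack$voxel_size[3])
  idx <- if (from == "top") seq(nz - koff - k + 1, nz - koff)
  else seq(koff + 1, koff + k)
  idx <- idx[idx >= 1 & idx <= nz]
  org <- stack$origin
  org[3] <- org[3] + (idx[1] - 1) * stack$voxel_size[3]
  image_stack(stack$voxels[, , idx, drop = FALSE], stack$voxel_size, org)
}

#' Rotate a stack about the vertical (y) axis
#'
#' Trilinear (here: bilinear in the x-z plane, exact in y) interpolation
#' with zero padding; the output grid covers the rotated bounding box at
#' the same voxel size.
#'
#' @param stack an [image_stack()].
#' @param angle_deg rotation angle, degrees, normalised modulo 180.
#' @return An [image_stack()] on the rotated frame (origin centred).
#' @export
rotate_stack <- function(stack, angle_deg) {
  angle_deg <- angle_deg %% 180
  arr <- stack$voxels
  d <- dim(arr)
  dx <- stack$voxel_size[1]; dz <- stack$voxel_size[3]
  if (angle_deg == 0) return(stack)
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  # physical x/z coordinates of voxel centres, about the stack centre
  xc <- ((seq_len(d[1]) - 0.5) - d[1] / 2) * dx
  zc <- ((seq_len(d[3]) - 0.5) - d[3] / 2) * dz
  ex <- abs(d[1] * dx / 2 * ca) + abs(d[3] * dz / 2 * sa)
  ez <- abs(d[1] * dx / 2 * sa) + abs(d[3] * dz / 2 * ca)
  nxo <- max(1L, ceiling(2 * ex / dx))
  nzo <- max(1L, ceiling(2 * ez / dz))
  xo <- ((seq_len(nxo) - 0.5) - nxo / 2) * dx
  zo <- ((seq_len(nzo) - 0.5) - nzo / 2) * dz
  # inverse map: source coords of each output (x', z')
  g <- expand.grid(x = xo, z = zo)
  xs <- g$x * ca - g$z * sa
  zs <- g$x * sa + g$z * ca
  fx <- (xs - xc[1]) / dx + 1
  fz <- (zs - zc[1]) / dz + 1
  x0 <- floor(fx); z0 <- floor(fz)
  wx <- fx - x0; wz <- fz - z0
  val_at <- function(ix, iz, slice) {
    ok <- ix >= 1 & ix <= d[1] & iz >= 1 & iz <= d[3]
    v <- numeric(length(ix))
    v[ok] <- slice[cbind(ix[ok], iz[ok])]
    v
  }
  out <- array(0, c(nxo, d[2], nzo))
  for (y in seq_len(d[2])) {
    sl <- arr[, y, ]
    if (is.null(dim(sl))) sl <- matrix(sl, d[1], d[3])
    v <- (1 - wx) * (1 - wz) * val_at(x0, z0, sl) +
      wx * (1 - wz) * val_at(x0 + 1, z0, sl) +
      (1 - wx) * wz * val_at(x0, z0 + 1, sl) +
      wx * wz * val_at(x0 + 1, z0 + 1, sl)
    out[, y, ] <- matrix(v, nxo, nzo)
  }
  image_stack(out, stack$voxel_size,
              c(-ex, stack$origin[2], -ez))
}

#' 2D projection of a stack
#'
#' @param pixels 2D matrix indexed `[x, y]`.
#' @param pixel_size um.
#' @param angle rotation angle the projection was taken at, degrees.
#' @param origin physical low corner.
#' @return Object of class `projection2d`.
#' @export
projection2d <- function(pixels, pixel_size, angle = 0, origin = c(0, 0)) {
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 angle = angle %% 180, origin = origin),
            class = "projection2d")
}

#' Rotate a stack and take the maximum-intensity projection
#'
#' Rotates about the vertical (y) axis by `angle` (normalised modulo 180)
#' and projects along the viewing (z) axis by voxelwise maximum; pixel
#' calibration is preserved.
#'
#' @param stack an [image_stack()] (already depth-limited for TVP work;
#'   see [substack()]).
#' @param angle degrees.
#' @return A [projection2d()].
#' @export
rotate_and_project <- function(stack, angle) {
  rs <- rotate_stack(stack, angle)
  px <- apply(rs$voxels, c(1, 2), max)
  projection2d(px, rs$voxel_size[1], angle, rs$origin[1:2])
}

#' @export
print.projection2d <- function(x, ...) {
  cat(sprintf("Projection at %g deg: %d x %d px, %.3g um/px\n",
              x$angle, dim(x$pixels)[1], dim(x$pixels)[2], x$pixel_size))
  invisible(x)
}

# Zhang-Suen thinning to a 1-pixel-wide skeleton (vectorised over the
# image; deterministic for a fixed input).
zhang_suen_thin <- function(m) {
  m <- m * 1L
  n1 <- dim(m)[1]; n2 <- dim(m)[2]
  pad <- matrix(0L, n1 + 2, n2 + 2)
  pad[2:(n1 + 1), 2:(n2 + 1)] <- m
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p <- pad[2:(n1 + 1), 2:(n2 + 1)]
      nb <- function(di, dj) pad[2:(n1 + 1) + di, 2:(n2 + 1) + dj]
      p2 <- nb(-1, 0); p3 <- nb(-1, 1); p4 <- nb(0, 1); p5 <- nb(1, 1)
      p6 <- nb(1, 0); p7 <- nb(1, -1); p8 <- nb(0, -1); p9 <- nb(-1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      cond <- p == 1 & b >= 2 & b <= 6 & a == 1
      if (phase == 1) cond <- cond & (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      else cond <- cond & (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      if (any(cond)) {
        changed <- TRUE
        q <- pad[2:(n1 + 1), 2:(n2 + 1)]
        q[cond] <- 0L
        pad[2:(n1 + 1), 2:(n2 + 1)] <- q
      }
    }
    if (!changed) break
  }
  pad[2:(n1 + 1), 2:(n2 + 1)] == 1L
}

#' Binarise a projection and reduce it to a 1-pixel skeleton
#'
#' Thresholds the projection (Otsu by default; manual visual
#' discrimination is inherently interactive) and thins the mask to its central
#' spine with the Zhang-Suen algorithm.  Deterministic for fixed input.
#'
#' @param projection a [projection2d()] or numeric matrix.
#' @param threshold intensity threshold; `NULL` for Otsu.
#' @param pixel_size um (taken from the projection object when available).
#' @return Object of class `skeleton_image`: `mask`, `skeleton` (logical
#'   matrices `[x, y]`), `threshold`, `pixel_size`, `origin`.
#' @export
binarize_and_skeletonize <- function(projection, threshold = NULL,
                                     pixel_size = NULL) {
  if (inherits(projection, "projection2d")) {
    px <- projection$pixels
    pixel_size <- projection$pixel_size
    origin <- projection$origin
  } else {
    px <- projection
    origin <- c(0, 0)
  }
  rng <- range(px)
  if (rng[2] <= rng[1]) {
    empty <- matrix(FALSE, nrow(px), ncol(px))
    return(structure(list(mask = empty, skeleton = empty,
                          threshold = NA_real_, pixel_size = pixel_size,
                          origin = origin),
                     class = "skeleton_image"))
  }
  if (is.null(threshold)) {
    norm <- (px - rng[1]) / (rng[2] - rng[1])
    threshold <- rng[1] + EBImage::otsu(norm) * (rng[2] - rng[1])
  } else if (threshold < rng[1] || threshold > rng[2])
    stop("threshold outside the intensity range")
  mask <- px > threshold
  skel <- if (any(mask)) zhang_suen_thin(mask) else mask
  structure(list(mask = mask, skeleton = skel, threshold = threshold,
                 pixel_size = pixel_size, origin = origin),
            class = "skeleton_image")
}

#' Skeleton length estimate
#'
#' Sums inter-pixel links (1 per orthogonal, sqrt(2) per diagonal link,
#' diagonals only when no orthogonal 2-step path exists) times the pixel
#' size.
#'
#' @param skeleton a `skeleton_image` or logical matrix.
#' @param pixel_size um.
#' @return Length, um.
#' @export
skeleton_length <- function(skeleton, pixel_size = NULL) {
  if (inherits(skeleton, "skeleton_image")) {
    pixel_size <- skeleton$pixel_size
    m <- skeleton$skeleton
  } else m <- skeleton
  if (!any(m)) return(0)
  n1 <- dim(m)[1]; n2 <- dim(m)[2]
  horiz <- m[-n1, ] & m[-1, ]
  vert <- m[, -n2] & m[, -1]
  d1 <- m[-n1, -n2] & m[-1, -1]
  d2 <- m[-1, -n2] & m[-n1, -1]
  # suppress a diagonal when the two orthogonal neighbours complete it
  d1 <- d1 & !(m[-1, -n2] | m[-n1, -1])
  d2 <- d2 & !(m[-n1, -n2] | m[-1, -1])
  (sum(horiz) + sum(vert) + sqrt(2) * (sum(d1) + sum(d2))) * pixel_size
}

#' Count skeleton endpoints
#'
#' Skeleton pixels with exactly one 8-connected neighbour.
#'
#' @param skeleton a `skeleton_image` or logical matrix.
#' @return Integer count.
#' @export
skeleton_endpoints <- function(skeleton) {
  m <- if (inherits(skeleton, "skeleton_image")) skeleton$skeleton
  else skeleton
  if (!any(m)) return(0L)
  n1 <- dim(m)[1]; n2 <- dim(m)[2]
  pad <- matrix(FALSE, n1 + 2, n2 + 2)
  pad[2:(n1 + 1), 2:(n2 + 1)] <- m
  nb <- matrix(0L, n1, n2)
  for (di in -1:1) for (dj in -1:1)
    if (di || dj) nb <- nb + pad[2:(n1 + 1) + di, 2:(n2 + 1) + dj]
  sum(m & nb == 1L)
}

#' Write / read an image stack as multi-page TIFF
#'
#' Pages are z-slices; the x resolution is stored in the TIFF header
#' (pixels per cm).  Requires the `tiff` package.
#'
#' @param stack an [image_stack()].
#' @param path file path.
#' @return `read_stack_tiff` returns an [image_stack()]; voxel z size must
#'   be supplied since TIFF has no z calibration.
#' @export
write_stack_tiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF I/O")
  arr <- stack$voxels
  mx <- max(arr, 1e-12)
  pages <- lapply(seq_len(dim(arr)[3]), function(z) t(arr[, , z]) / mx)
  tiff::writeTIFF(pages, path,
                  reduce = TRUE)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param voxel_size `(dx, dy, dz)` um used to calibrate the read stack.
#' @export
read_stack_tiff <- function(path, voxel_size) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF I/O")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- t(pages[[z]])
  image_stack(arr, voxel_size)
}
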