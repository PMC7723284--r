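# Three-view patch (TVP) extraction: axial/coronal/sagittal windows at a
# voxel, stacked into a 3-channel 2.5-D patch; exhaustive training
# enumeration over labeled voxels; semirandom test sampling that avoids
# region boundaries; light geometric/intensity augmentation.
#
# All indices are 1-based voxel coordinates.  A window of size s centered
# at c covers indices (c - s/2):(c - s/2 + s - 1) -- exactly s pixels with
# the center at in-window position s/2 + 1.  Windows that do not fit are
# an error (no padding): phantom structures are kept interior, and padding
# semantics would be an invention.

#' Patch size specification
#'
#' @param alpha,beta patch width and height in pixels; both even and >= 4.
#'   Default 32 x 32.
#' @return a `patch_spec` list.
#' @export
patch_spec <- function(alpha = 32, beta = 32) {
  if (alpha < 4 || beta < 4 || alpha %% 2 != 0 || beta %% 2 != 0) {
    stopf("alpha and beta must be even and >= 4")
  }
  structure(list(alpha = as.integer(alpha), beta = as.integer(beta)),
    class = "patch_spec"
  )
}

window_indices <- function(center, size, extent) {
  start <- center - size %/% 2L
  stop_ <- start + size - 1L
  if (start < 1L || stop_ > extent) {
    return(NULL)
  }
  start:stop_
}

#' Extract one 2-D view patch at a voxel
#'
#' The three principal planes through voxel `v = (vx, vy, vz)`:
#' axial fixes `z = vz` with in-plane axes `(x, y)`; coronal fixes
#' `y = vy` with axes `(x, z)`; sagittal fixes `x = vx` with axes
#' `(y, z)`.  The first in-plane axis uses an `alpha`-wide window, the
#' second a `beta`-wide window.
#'
#' @param vol 3-D numeric array.
#' @param v integer voxel coordinate `c(x, y, z)` (1-based).
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @param spec a [patch_spec()].
#' @return an `alpha x beta` numeric matrix.
#' @export
extract_view_patch <- function(vol, v, plane = c("axial", "coronal", "sagittal"),
                               spec = patch_spec()) {
  check_volume(vol)
  plane <- match.arg(plane)
  v <- as.integer(v)
  stopifnot(length(v) == 3)
  d <- dim(vol)
  if (any(v < 1L | v > d)) stopf("voxel (%s) outside volume", paste(v, collapse = ","))
  bounds_err <- function(axis) {
    stopf(
      "patch window does not fit at voxel (%s) along %s (no padding)",
      paste(v, collapse = ","), axis
    )
  }
  switch(plane,
    axial = {
      xs <- window_indices(v[1], spec$alpha, d[1])
      ys <- window_indices(v[2], spec$beta, d[2])
      if (is.null(xs)) bounds_err("x")
      if (is.null(ys)) bounds_err("y")
      vol[xs, ys, v[3]]
    },
    coronal = {
      xs <- window_indices(v[1], spec$alpha, d[1])
      zs <- window_indices(v[3], spec$beta, d[3])
      if (is.null(xs)) bounds_err("x")
      if (is.null(zs)) bounds_err("z")
      vol[xs, v[2], zs]
    },
    sagittal = {
      ys <- window_indices(v[2], spec$alpha, d[2])
      zs <- window_indices(v[3], spec$beta, d[3])
      if (is.null(ys)) bounds_err("y")
      if (is.null(zs)) bounds_err("z")
      vol[v[1], ys, zs]
    }
  )
}

#' Extract a three-view patch (TVP)
#'
#' Stacks the axial, coronal and sagittal view patches at `v` into an
#' `alpha x beta x 3` array (channel order: axial, coronal, sagittal).
#'
#' @inheritParams extract_view_patch
#' @param roi_code,class_label optional annotations stored on the patch.
#' @return a `tvp` list: `data` (`alpha x beta x 3`), `center`,
#'   `roi_code`, `class_label`.
#' @export
extract_tvp <- function(vol, v, spec = patch_spec(),
                        roi_code = NA_integer_, class_label = NA_character_) {
  ax <- extract_view_patch(vol, v, "axial", spec)
  co <- extract_view_patch(vol, v, "coronal", spec)
  sa <- extract_view_patch(vol, v, "sagittal", spec)
  structure(
    list(
      data = array(c(ax, co, sa), c(spec$alpha, spec$beta, 3L)),
      center = as.integer(v), roi_code = roi_code, class_label = class_label
    ),
    class = "tvp"
  )
}

#' Is a voxel on the boundary of its labeled region?
#'
#' TRUE iff any 6-connected neighbor carries a different label;
#' out-of-grid neighbors count as different, so voxels on the volume face
#' are always boundary.
#'
#' @param seg 3-D integer segmentation array.
#' @param v integer voxel coordinate `c(x, y, z)`.
#' @return logical flag.
#' @export
is_boundary_voxel <- function(seg, v) {
  check_volume(seg)
  v <- as.integer(v)
  d <- dim(seg)
  if (any(v < 1L | v > d)) stopf("voxel outside grid")
  lab <- seg[v[1], v[2], v[3]]
  shifts <- rbind(
    c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)
  )
  for (k in seq_len(6)) {
    nb <- v + shifts[k, ]
    if (any(nb < 1L | nb > d)) {
      return(TRUE)
    }
    if (seg[nb[1], nb[2], nb[3]] != lab) {
      return(TRUE)
    }
  }
  FALSE
}

# Logical mask of voxels of `code` whose 6-neighborhood is entirely the
# same code (vectorized interior/eligibility computation).
interior_mask <- function(seg, code) {
  m <- seg == code
  d <- dim(seg)
  shift_and <- function(mask, axis, by) {
    out <- array(FALSE, d)
    idx_src <- vector("list", 3)
    idx_dst <- vector("list", 3)
    for (a in 1:3) {
      idx_src[[a]] <- seq_len(d[a])
      idx_dst[[a]] <- seq_len(d[a])
    }
    if (by == 1) {
      idx_dst[[axis]] <- seq_len(d[axis] - 1)
      idx_src[[axis]] <- 2:d[axis]
    } else {
      idx_dst[[axis]] <- 2:d[axis]
      idx_src[[axis]] <- seq_len(d[axis] - 1)
    }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      mask[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  res <- m
  for (axis in 1:3) {
    for (by in c(1, -1)) {
      res <- res & shift_and(m, axis, by)
    }
  }
  res
}

# Coordinates (n x 3 integer matrix) of voxels with a given code,
# optionally restricted to window-fitting and/or interior voxels.
roi_voxels <- function(seg, code, spec = NULL, interior = FALSE) {
  mask <- if (interior) interior_mask(seg, code) else seg == code
  coords <- which(mask, arr.ind = TRUE)
  colnames(coords) <- c("x", "y", "z")
  if (!is.null(spec) && nrow(coords)) {
    d <- dim(seg)
    s2a <- spec$alpha %/% 2L
    s2b <- spec$beta %/% 2L
    ok <-
      coords[, 1] - s2a >= 1 & coords[, 1] - s2a + spec$alpha - 1 <= d[1] &
      coords[, 2] - s2a >= 1 & coords[, 2] - s2a + spec$alpha - 1 <= d[2] &
      coords[, 2] - s2b >= 1 & coords[, 2] - s2b + spec$beta - 1 <= d[2] &
      coords[, 3] - s2b >= 1 & coords[, 3] - s2b + spec$beta - 1 <= d[3]
    coords <- coords[ok, , drop = FALSE]
  }
  coords
}

# Extract TVPs at a coordinate matrix into a compact dataset:
# data [alpha, beta, 3, n] plus an info data frame.
extract_tvp_dataset <- function(vol, coords, spec,
                                roi_codes, class_label, subject_id = NA_character_) {
  n <- nrow(coords)
  data <- array(0, c(spec$alpha, spec$beta, 3L, n))
  for (i in seq_len(n)) {
    v <- coords[i, ]
    data[, , 1, i] <- extract_view_patch(vol, v, "axial", spec)
    data[, , 2, i] <- extract_view_patch(vol, v, "coronal", spec)
    data[, , 3, i] <- extract_view_patch(vol, v, "sagittal", spec)
  }
  info <- data.frame(
    subject_id = subject_id,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    roi_code = roi_codes, class_label = class_label,
    stringsAsFactors = FALSE
  )
  structure(list(data = data, info = info, spec = spec), class = "tvp_dataset")
}

#' @export
print.tvp_dataset <- function(x, ...) {
  cat(sprintf(
    "<tvp_dataset: %d patches (%dx%dx3), %d subject(s), labels [%s]>\n",
    nrow(x$info), x$spec$alpha, x$spec$beta,
    length(unique(x$info$subject_id)),
    paste(unique(x$info$class_label), collapse = ",")
  ))
  invisible(x)
}

# Bind tvp_datasets (same spec).
rbind_tvp_datasets <- function(datasets) {
  datasets <- Filter(function(d) nrow(d$info) > 0, datasets)
  if (!length(datasets)) stopf("no patches to bind")
  spec <- datasets[[1]]$spec
  total <- sum(vapply(datasets, function(d) nrow(d$info), integer(1)))
  data <- array(0, c(spec$alpha, spec$beta, 3L, total))
  at <- 0L
  for (d in datasets) {
    k <- nrow(d$info)
    data[, , , at + seq_len(k)] <- d$data
    at <- at + k
  }
  info <- do.call(rbind, lapply(datasets, `[[`, "info"))
  rownames(info) <- NULL
  structure(list(data = data, info = info, spec = spec), class = "tvp_dataset")
}

#' Enumerate all training TVPs of a scan
#'
#' Walks every voxel whose segmentation code appears in the catalog and
#' whose three patch windows fit inside the volume, and emits one TVP per
#' voxel labeled with the scan's class and the voxel's region code.
#' Voxels whose windows do not fit are skipped and counted in the
#' `n_skipped` attribute.
#'
#' @param scan a `cohort_scan` (or any list with `volume`, `segmentation`,
#'   `class_label`, `subject_id`).
#' @param catalog an `roi_catalog`.
#' @param spec a [patch_spec()].
#' @param codes optional subset of catalog codes to enumerate.
#' @return a `tvp_dataset`; attribute `n_skipped` counts out-of-bounds
#'   voxels.
#' @export
enumerate_training_tvps <- function(scan, catalog = default_roi_catalog(),
                                    spec = patch_spec(), codes = NULL) {
  codes <- codes %||% catalog$code
  per_code <- list()
  n_skipped <- 0L
  for (code in codes) {
    all_vox <- roi_voxels(scan$segmentation, code)
    fit_vox <- roi_voxels(scan$segmentation, code, spec = spec)
    n_skipped <- n_skipped + nrow(all_vox) - nrow(fit_vox)
    if (nrow(fit_vox) == 0) next
    per_code[[as.character(code)]] <- extract_tvp_dataset(
      scan$volume, fit_vox, spec,
      roi_codes = rep(code, nrow(fit_vox)),
      class_label = scan$class_label, subject_id = scan$subject_id
    )
  }
  if (!length(per_code)) {
    out <- structure(
      list(
        data = array(0, c(spec$alpha, spec$beta, 3L, 0L)),
        info = data.frame(
          subject_id = character(0), x = integer(0), y = integer(0),
          z = integer(0), roi_code = integer(0), class_label = character(0),
          stringsAsFactors = FALSE
        ),
        spec = spec
      ),
      class = "tvp_dataset"
    )
  } else {
    out <- rbind_tvp_datasets(per_code)
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Sample test TVPs from one region
#'
#' Draws `n` distinct voxels uniformly without replacement from the
#' eligible voxels of the region -- those that are not boundary voxels
#' (6-connectivity) and whose patch windows fit -- and extracts their
#' TVPs.  "Semirandom" sampling: uniform subject to the boundary-avoidance
#' constraint.
#'
#' @inheritParams enumerate_training_tvps
#' @param roi_code region code to sample from.
#' @param n number of patches (default 32).
#' @param seed RNG seed.
#' @return a `tvp_dataset` with `n` patches.
#' @export
sample_test_tvps <- function(scan, roi_code, n = 32, seed = 1,
                             spec = patch_spec()) {
  eligible <- roi_voxels(scan$segmentation, roi_code, spec = spec, interior = TRUE)
  if (nrow(eligible) < n) {
    stopf(
      "region %d has only %d eligible voxel(s), %d requested",
      roi_code, nrow(eligible), n
    )
  }
  pick <- with_seed(seed, sample.int(nrow(eligible), n))
  extract_tvp_dataset(
    scan$volume, eligible[pick, , drop = FALSE], spec,
    roi_codes = rep(as.integer(roi_code), n),
    class_label = scan$class_label %||% NA_character_,
    subject_id = scan$subject_id %||% NA_character_
  )
}

#' Augment a TVP by shear, zoom and intensity rescale
#'
#' Applies, identically to all three channels: a shear with angle drawn
#' uniformly in `+/- shear_deg` degrees, a zoom with factor uniform in
#' `[1 - zoom, 1 + zoom]` (bilinear resampling back to the original
#' grid, edge-clamped), and an intensity rescale with factor uniform in
#' `[1 - rescale, 1 + rescale]`.  With all parameters zero the output
#' equals the input exactly.
#'
#' @param tvp a `tvp`, or a bare `alpha x beta x 3` array.
#' @param seed RNG seed for the drawn factors; `NULL` uses the current RNG
#'   stream (for use inside seeded training loops).
#' @param shear_deg,zoom,rescale augmentation ranges (defaults 10 degrees,
#'   0.1, 0.1).
#' @return same type as the input, same shape.
#' @export
augment_tvp <- function(tvp, seed = NULL, shear_deg = 10, zoom = 0.1,
                        rescale = 0.1) {
  arr <- if (inherits(tvp, "tvp")) tvp$data else tvp
  stopifnot(length(dim(arr)) == 3)
  draw <- function() {
    c(
      shear = stats::runif(1, -shear_deg, shear_deg) * pi / 180,
      zoom = stats::runif(1, 1 - zoom, 1 + zoom),
      rescale = stats::runif(1, 1 - rescale, 1 + rescale)
    )
  }
  pars <- if (is.null(seed)) draw() else with_seed(seed, draw())
  out <- arr
  if (pars[["shear"]] != 0 || pars[["zoom"]] != 1) {
    for (ch in seq_len(dim(arr)[3])) {
      out[, , ch] <- warp_bilinear(arr[, , ch], pars[["shear"]], pars[["zoom"]])
    }
  }
  out <- out * pars[["rescale"]]
  if (inherits(tvp, "tvp")) {
    tvp$data <- out
    tvp
  } else {
    out
  }
}

# Inverse-map bilinear warp about the image center: output pixel (u, v)
# samples the input at Z^-1 S^-1 (u, v), where S shears the first axis by
# tan(theta) of the second and Z scales both axes by the zoom factor.
warp_bilinear <- function(mat, shear_rad, zoom_factor) {
  nr <- nrow(mat)
  nc <- ncol(mat)
  c1 <- (nr + 1) / 2
  c2 <- (nc + 1) / 2
  u <- matrix(seq_len(nr) - c1, nr, nc)
  v <- matrix(rep(seq_len(nc) - c2, each = nr), nr, nc)
  # inverse zoom then inverse shear
  ui <- u / zoom_factor
  vi <- v / zoom_factor
  ui <- ui - tan(shear_rad) * vi
  x <- ui + c1
  y <- vi + c2
  x <- pmin(pmax(x, 1), nr)
  y <- pmin(pmax(y, 1), nc)
  x0 <- floor(x)
  y0 <- floor(y)
  x1 <- pmin(x0 + 1, nr)
  y1 <- pmin(y0 + 1, nc)
  fx <- x - x0
  fy <- y - y0
  idx <- function(i, j) mat[cbind(as.vector(i), as.vector(j))]
  val <- (1 - fx) * (1 - fy) * idx(x0, y0) +
    fx * (1 - fy) * idx(x1, y0) +
    (1 - fx) * fy * idx(x0, y1) +
    fx * fy * idx(x1, y1)
  matrix(val, nr, nc)
}
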