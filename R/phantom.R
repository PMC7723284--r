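# Synthetic phantom cohorts: labeled volumes plus Gaussian morphometry
# tables with controllable class effects.
#
# The phantoms are deliberately simple: six ellipsoidal "structures" at
# fixed bilateral centers on a Gaussian-noise background.  Disease stage
# shrinks each structure (atrophy, a fractional radius reduction) and
# shifts its mean intensity, with effect sizes ordered hippocampi >
# amygdalae > insulae.  That is everything the downstream pipeline needs
# (compact labeled regions whose size and appearance depend on class);
# realistic anatomy is a non-goal.

PHANTOM_CLASSES <- c("NC", "aAD", "mAD", "ADD")

# Reference geometry on a 96-voxel grid; scaled linearly for other sizes.
# Chosen so every structure voxel admits a full 32x32 patch window on all
# three axes and no two ellipsoids touch at any supported atrophy level.
phantom_geometry <- function(grid_size) {
  g <- grid_size / 96
  geo <- data.frame(
    name = c(
      "left_hippocampus", "right_hippocampus",
      "left_amygdala", "right_amygdala",
      "left_insula", "right_insula"
    ),
    code = c(17L, 53L, 18L, 54L, 1035L, 2035L),
    structure = rep(c("hippocampus", "amygdala", "insula"), each = 2),
    cx = c(34, 62, 34, 62, 30, 66) * g,
    cy = c(46, 46, 60, 60, 46, 46) * g,
    cz = c(44, 44, 44, 44, 60, 60) * g,
    rx = c(6, 6, 5, 5, 6, 6) * g,
    ry = c(5, 5, 4, 4, 5, 5) * g,
    rz = c(5, 5, 4, 4, 4, 4) * g,
    stringsAsFactors = FALSE
  )
  geo
}

#' Configuration of the phantom cohort generator
#'
#' The defaults encode the study conditions the rest of the package is
#' exercised under: four stages with monotonically increasing atrophy and
#' intensity effects, the aAD stage nearly indistinguishable from NC, and
#' per-structure effect scaling ordered hippocampi > amygdalae > insulae.
#'
#' @param grid_size voxels per axis (cubic grid, >= 48; default 96).
#' @param n_per_class named counts of scans for NC, aAD, mAD, ADD.
#' @param atrophy_factor named fractional radius reduction per class, each
#'   in `[0, 0.5)`.
#' @param intensity_shift named within-structure mean intensity offset per
#'   class, in units of `noise_sd`.
#' @param noise_sd background Gaussian noise standard deviation.
#' @param region_effect_scale named per-structure multiplier applied to
#'   both atrophy and intensity effects.
#' @param roi_contrast class-independent brightness of every structure over
#'   the background, in units of `noise_sd` (makes structures visible in
#'   intensity as they are in real scans).
#' @param measure_effect named per-class standardized effect size used by
#'   [generate_measure_table()].
#' @param seed master RNG seed for the cohort.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(grid_size = 96,
                           n_per_class = c(NC = 4, aAD = 4, mAD = 4, ADD = 4),
                           atrophy_factor = c(NC = 0, aAD = 0.02, mAD = 0.10, ADD = 0.20),
                           intensity_shift = c(NC = 0, aAD = 0.1, mAD = 0.75, ADD = 1.5),
                           noise_sd = 1.0,
                           region_effect_scale = c(hippocampus = 1.0, amygdala = 0.7, insula = 0.4),
                           roi_contrast = 1.0,
                           measure_effect = c(NC = 0, aAD = 0.1, mAD = 1.0, ADD = 2.0),
                           seed = 20201208) {
  if (grid_size < 48) stopf("grid_size must be >= 48")
  for (nm in list(n_per_class, atrophy_factor, intensity_shift, measure_effect)) {
    if (!all(PHANTOM_CLASSES %in% names(nm))) {
      stopf("per-class settings need names %s", paste(PHANTOM_CLASSES, collapse = ", "))
    }
  }
  if (any(n_per_class < 1)) stopf("n_per_class must be >= 1 for every class")
  if (any(atrophy_factor < 0 | atrophy_factor >= 0.5)) {
    stopf("atrophy_factor must lie in [0, 0.5)")
  }
  if (!all(c("hippocampus", "amygdala", "insula") %in% names(region_effect_scale))) {
    stopf("region_effect_scale needs hippocampus, amygdala and insula entries")
  }
  cfg <- list(
    grid_size = as.integer(grid_size),
    n_per_class = n_per_class[PHANTOM_CLASSES],
    atrophy_factor = atrophy_factor[PHANTOM_CLASSES],
    intensity_shift = intensity_shift[PHANTOM_CLASSES],
    noise_sd = noise_sd,
    region_effect_scale = region_effect_scale,
    roi_contrast = roi_contrast,
    measure_effect = measure_effect[PHANTOM_CLASSES],
    seed = as.integer(seed)
  )
  class(cfg) <- "phantom_config"
  check_phantom_geometry(cfg)
  cfg
}

# Conservative separation check: bounding boxes of the full-size (NC)
# ellipsoids, padded by one voxel, must not intersect.
check_phantom_geometry <- function(config) {
  geo <- phantom_geometry(config$grid_size)
  n <- nrow(geo)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sep <- abs(geo$cx[i] - geo$cx[j]) > geo$rx[i] + geo$rx[j] + 1 ||
        abs(geo$cy[i] - geo$cy[j]) > geo$ry[i] + geo$ry[j] + 1 ||
        abs(geo$cz[i] - geo$cz[j]) > geo$rz[i] + geo$rz[j] + 1
      if (!sep) {
        stopf(
          "phantom structures %s and %s overlap at grid_size %d",
          geo$name[i], geo$name[j], config$grid_size
        )
      }
    }
  }
  invisible(config)
}

#' Generate one phantom scan
#'
#' Builds a Gaussian-noise volume with six ellipsoidal structures whose
#' radii are scaled by `1 - atrophy_factor[class] * region_effect_scale`
#' and whose mean intensity is raised by
#' `(roi_contrast + intensity_shift[class] * region_effect_scale) * noise_sd`.
#' The segmentation carries the catalog code inside each ellipsoid and 0
#' elsewhere.  Deterministic given `(class_label, config, subject_seed)`.
#'
#' @param class_label one of `"NC"`, `"aAD"`, `"mAD"`, `"ADD"`.
#' @param config a [phantom_config()].
#' @param subject_seed integer seed for this scan's noise.
#' @param subject_id optional identifier stored on the scan.
#' @return a `cohort_scan` list with elements `subject_id`, `class_label`,
#'   `volume` and `segmentation`.
#' @export
generate_phantom_scan <- function(class_label, config, subject_seed,
                                  subject_id = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  class_label <- match.arg(class_label, PHANTOM_CLASSES)
  g <- config$grid_size
  geo <- phantom_geometry(g)
  vol <- with_seed(subject_seed, array(stats::rnorm(g^3, 0, config$noise_sd), c(g, g, g)))
  seg <- array(0L, c(g, g, g))
  atro <- config$atrophy_factor[[class_label]]
  shift <- config$intensity_shift[[class_label]]
  for (i in seq_len(nrow(geo))) {
    scale_i <- config$region_effect_scale[[geo$structure[i]]]
    shrink <- 1 - atro * scale_i
    rx <- geo$rx[i] * shrink
    ry <- geo$ry[i] * shrink
    rz <- geo$rz[i] * shrink
    xs <- max(1L, floor(geo$cx[i] - rx)):min(g, ceiling(geo$cx[i] + rx))
    ys <- max(1L, floor(geo$cy[i] - ry)):min(g, ceiling(geo$cy[i] + ry))
    zs <- max(1L, floor(geo$cz[i] - rz)):min(g, ceiling(geo$cz[i] + rz))
    dx2 <- ((xs - geo$cx[i]) / rx)^2
    dy2 <- ((ys - geo$cy[i]) / ry)^2
    dz2 <- ((zs - geo$cz[i]) / rz)^2
    inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
    mean_add <- (config$roi_contrast + shift * scale_i) * config$noise_sd
    sub <- vol[xs, ys, zs]
    sub[inside] <- sub[inside] + mean_add
    vol[xs, ys, zs] <- sub
    sseg <- seg[xs, ys, zs]
    sseg[inside] <- geo$code[i]
    seg[xs, ys, zs] <- sseg
  }
  scan <- list(
    subject_id = subject_id %||% sprintf("%s_%d", class_label, subject_seed),
    class_label = class_label,
    volume = vol,
    segmentation = seg
  )
  class(scan) <- "cohort_scan"
  scan
}

#' Generate a phantom cohort
#'
#' One scan per requested subject, with per-subject seeds derived
#' deterministically from `config$seed`.
#'
#' @param config a [phantom_config()].
#' @return a list with `scans` (list of `cohort_scan`) and `manifest`
#'   (data frame: `subject_id`, `class_label`, `subject_seed`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  classes <- rep(PHANTOM_CLASSES, times = config$n_per_class)
  n <- length(classes)
  seeds <- vapply(seq_len(n), function(i) derive_seed(config$seed, i), integer(1))
  ids <- sprintf("subj%03d_%s", seq_len(n), classes)
  scans <- vector("list", n)
  for (i in seq_len(n)) {
    scans[[i]] <- generate_phantom_scan(classes[i], config, seeds[i], ids[i])
  }
  manifest <- data.frame(
    subject_id = ids, class_label = classes, subject_seed = seeds,
    stringsAsFactors = FALSE
  )
  list(scans = scans, manifest = manifest)
}

# Per-structure baselines for the morphometry measures: V is the regional
# volume as a percentile of intracranial volume, T a thickness in mm, P a
# pure volume in mm^3 derived from V by a fixed monotone map (ICV taken as
# 1.5e6 mm^3).
MEASURE_BASELINES <- list(
  V = c(hippocampus = 0.26, amygdala = 0.11, insula = 0.44),
  T = c(hippocampus = 2.6, amygdala = 1.9, insula = 3.0),
  sd_V = 0.025,
  sd_T = 0.15,
  icv = 1.5e6
)

#' Generate a per-subject, per-region morphometry table
#'
#' For every subject and region, `V` and `T` are Gaussian with class means
#' shifted downwards by `effect[class] * region_scale[structure]` standard
#' deviations (atrophy lowers both volume and thickness); `P` is a fixed
#' monotone map of `V` (`P = V / 100 * ICV`).
#'
#' @param config a [phantom_config()].
#' @param n_per_class named subject counts; defaults to `config$n_per_class`.
#'   Only the named classes are generated, so two-group tables are easy to
#'   build.
#' @param effect named per-class standardized effect sizes; defaults to
#'   `config$measure_effect`.
#' @param region_scale named per-structure multipliers; defaults to
#'   `config$region_effect_scale`.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return a data frame (`subject_id`, `class_label`, `region_name`,
#'   `structure`, `V`, `T`, `P`).
#' @export
generate_measure_table <- function(config,
                                   n_per_class = NULL,
                                   effect = NULL,
                                   region_scale = NULL,
                                   seed = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  n_per_class <- n_per_class %||% config$n_per_class
  effect <- effect %||% config$measure_effect
  region_scale <- region_scale %||% config$region_effect_scale
  seed <- seed %||% config$seed
  stopifnot(all(names(n_per_class) %in% PHANTOM_CLASSES))
  stopifnot(all(names(n_per_class) %in% names(effect)))
  geo <- phantom_geometry(config$grid_size)
  classes <- rep(names(n_per_class), times = n_per_class)
  n <- length(classes)
  ids <- sprintf("subj%03d_%s", seq_len(n), classes)
  rows <- vector("list", nrow(geo))
  with_seed(seed, {
    for (r in seq_len(nrow(geo))) {
      stru <- geo$structure[r]
      sc <- region_scale[[stru]]
      d <- unname(effect[classes]) * sc
      V <- stats::rnorm(n, MEASURE_BASELINES$V[[stru]] - d * MEASURE_BASELINES$sd_V,
                        MEASURE_BASELINES$sd_V)
      Tm <- stats::rnorm(n, MEASURE_BASELINES$T[[stru]] - d * MEASURE_BASELINES$sd_T,
                         MEASURE_BASELINES$sd_T)
      rows[[r]] <- data.frame(
        subject_id = ids, class_label = classes,
        region_name = geo$name[r], structure = stru,
        V = V, T = Tm, P = V / 100 * MEASURE_BASELINES$icv,
        stringsAsFactors = FALSE
      )
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.cohort_scan <- function(x, ...) {
  cat(sprintf(
    "<cohort_scan %s: class %s, grid %s, %d labeled voxels>\n",
    x$subject_id, x$class_label,
    paste(dim(x$volume), collapse = "x"), sum(x$segmentation > 0)
  ))
  invisible(x)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf(
    "<phantom_config: grid %d^3, n/class [%s], atrophy [%s], shift [%s], seed %d>\n",
    x$grid_size, paste(x$n_per_class, collapse = ","),
    paste(x$atrophy_factor, collapse = ","),
    paste(x$intensity_shift, collapse = ","), x$seed
  ))
  invisible(x)
}
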