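# Synthetic lung-phantom cohorts with class-conditional nodule morphology.
#
# A phantom is an HU-valued anisotropic grid containing a single solid
# nodule. Benign-like lesions (label 0) carry mild low-frequency lobulation;
# malignant-like lesions (label 1) carry stronger lobulation plus sparse
# high-frequency radial spikes emulating spiculation. Arrays are ordered
# (z, y, x) with z the slice axis; voxel centres are half-voxel offset from
# the volume origin.

#' Configuration for synthetic lung phantoms
#'
#' Defaults place the cohort in a realistic regime for thin-slice chest CT:
#' aerated-lung background around -800 HU, solid soft-tissue nodules around
#' +30 HU, nodule diameters uniform on 7-30 mm, and anisotropic voxels of
#' (0.7, 0.7) mm in-plane with 2.3 mm slices.
#'
#' @param volume_shape integer vector (nz, ny, nx), voxels per axis
#' @param spacing_mm numeric vector (z, y, x) voxel size in mm, all positive
#' @param lung_hu_mean,lung_hu_sd background (aerated lung) HU mean and
#'   additive Gaussian noise sd
#' @param nodule_hu_mean,nodule_hu_sd lesion HU mean and noise sd
#' @param diameter_range_mm nodule diameter range; must lie within [7, 30]
#' @param spiculation_strength amplitude of label-1 radial spikes as a
#'   fraction of the base radius
#' @param lobulation_count integer vector of length 2: number of low-frequency
#'   surface lobes for label 0 and label 1 respectively
#' @param lobulation_amplitude amplitude of lobulation bumps (fraction of
#'   base radius)
#' @param spike_count number of label-1 spikes
#' @param lobe_kappa,spike_kappa von Mises-Fisher concentrations of the broad
#'   lobulation bumps and the narrow spikes
#' @param center_jitter_mm max absolute uniform jitter of the lesion centre
#'   around the volume centre, per axis
#' @param seed master seed; together with a case index it fully determines a
#'   case (see [derive_seed()])
#' @return an object of class `phantom_config`
#' @export
phantom_config <- function(volume_shape = c(80L, 128L, 128L),
                           spacing_mm = c(2.3, 0.7, 0.7),
                           lung_hu_mean = -800, lung_hu_sd = 40,
                           nodule_hu_mean = 30, nodule_hu_sd = 25,
                           diameter_range_mm = c(7, 30),
                           spiculation_strength = 0.55,
                           lobulation_count = c(2L, 6L),
                           lobulation_amplitude = 0.12,
                           spike_count = 24L,
                           lobe_kappa = 4,
                           spike_kappa = 25,
                           center_jitter_mm = 4,
                           seed = 1L) {
  if (length(volume_shape) != 3L || any(volume_shape < 8))
    stop("volume_shape must be 3 axis sizes of at least 8 voxels")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be strictly positive on every axis")
  if (length(diameter_range_mm) != 2L ||
      diameter_range_mm[1] < 7 || diameter_range_mm[2] > 30 ||
      diameter_range_mm[1] > diameter_range_mm[2])
    stop("diameter_range_mm must be an increasing range within [7, 30] mm")
  if (diameter_range_mm[2] > 50)
    stop("nodule diameter exceeds the 50 mm ROI physical extent")
  if (length(lobulation_count) == 1L)
    lobulation_count <- rep(lobulation_count, 2L)
  cfg <- list(volume_shape = as.integer(volume_shape),
              spacing_mm = as.numeric(spacing_mm),
              lung_hu_mean = lung_hu_mean, lung_hu_sd = lung_hu_sd,
              nodule_hu_mean = nodule_hu_mean, nodule_hu_sd = nodule_hu_sd,
              diameter_range_mm = as.numeric(diameter_range_mm),
              spiculation_strength = spiculation_strength,
              lobulation_count = as.integer(lobulation_count),
              lobulation_amplitude = lobulation_amplitude,
              spike_count = as.integer(spike_count),
              lobe_kappa = lobe_kappa, spike_kappa = spike_kappa,
              center_jitter_mm = center_jitter_mm,
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  cfg
}

random_unit_vectors <- function(n) {
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

# Sample the case-level geometry (diameter, centre, lobe and spike axes).
# The RNG draw order here is part of the determinism contract: diameter,
# centre jitter, lobe axes, spike axes, then volume noise.
nodule_geometry <- function(config, label, case_seed) {
  stopifnot(label %in% c(0L, 1L))
  with_seed(case_seed, {
    d <- stats::runif(1, config$diameter_range_mm[1], config$diameter_range_mm[2])
    jitter <- stats::runif(3, -config$center_jitter_mm, config$center_jitter_mm)
    center <- config$volume_shape * config$spacing_mm / 2 + jitter
    n_lobes <- config$lobulation_count[label + 1L]
    lobes <- random_unit_vectors(n_lobes)
    spikes <- if (label == 1L) random_unit_vectors(config$spike_count)
              else matrix(numeric(0), 0, 3)
    list(diameter_mm = d, r0 = d / 2, center_mm = center,
         lobe_axes = lobes, spike_axes = spikes,
         label = as.integer(label), case_seed = as.integer(case_seed))
  })
}

# Directional surface radius r(u) of the nodule model:
# r(u) = r0 * (1 + min(a_lob * sum_j vMF(u; lobe_j, kappa_lob)
#                       + s * sum_k vMF(u; spike_k, kappa_spk), cap))
# with vMF(u; d, kappa) = exp(kappa * (u . d - 1)), a broad bump for small
# kappa and a narrow spike for large kappa. The cap (lobulation total plus
# two spike amplitudes) prevents degenerate growth when several narrow
# spikes happen to align, and gives a tight bound for the voxel search box.
radius_bump_cap <- function(geom, config) {
  config$lobulation_amplitude * nrow(geom$lobe_axes) +
    2 * config$spiculation_strength * (nrow(geom$spike_axes) > 0)
}

radius_at_directions <- function(geom, config, u) {
  bump <- rep(0, nrow(u))
  if (nrow(geom$lobe_axes) > 0 && config$lobulation_amplitude != 0) {
    dots <- u %*% t(geom$lobe_axes)
    bump <- bump + config$lobulation_amplitude *
      rowSums(exp(config$lobe_kappa * (dots - 1)))
  }
  if (nrow(geom$spike_axes) > 0 && config$spiculation_strength != 0) {
    dots <- u %*% t(geom$spike_axes)
    bump <- bump + config$spiculation_strength *
      rowSums(exp(config$spike_kappa * (dots - 1)))
  }
  geom$r0 * (1 + pmin(bump, radius_bump_cap(geom, config)))
}

#' Brute-force surface radii of a phantom nodule
#'
#' Evaluates the directional radius model of the case identified by
#' `(config, label, case_seed)` at the supplied (or randomly drawn) unit
#' directions. Used as a simple shape statistic: spiculated (label 1)
#' surfaces have larger radial variance than smooth/lobulated ones.
#'
#' @param config a [phantom_config()]
#' @param label 0 (benign-like) or 1 (malignant-like)
#' @param case_seed per-case seed
#' @param directions n x 3 matrix of unit vectors, or an integer count to
#'   draw that many uniform directions (seeded independently of the case)
#' @param direction_seed seed for drawn directions
#' @param normalize if `TRUE`, radii are divided by the base radius, giving
#'   a scale-free shape statistic (useful when diameters vary across cases)
#' @return numeric vector of surface radii (mm, or unitless if normalised)
#' @export
surface_radii <- function(config, label, case_seed, directions = 1000L,
                          direction_seed = 99L, normalize = FALSE) {
  geom <- nodule_geometry(config, label, case_seed)
  if (is.numeric(directions) && length(directions) == 1L)
    directions <- with_seed(direction_seed, random_unit_vectors(directions))
  r <- radius_at_directions(geom, config, directions)
  if (normalize) r / geom$r0 else r
}

#' Generate one synthetic phantom case
#'
#' Builds an HU-valued (z, y, x) volume containing exactly one nodule whose
#' surface radius is modulated by low-frequency lobulation bumps and, for
#' label 1, additional high-frequency radial spikes. Additive Gaussian HU
#' noise is applied everywhere (background and lesion use their own sd).
#' Identical `(config, label, case_seed)` give bit-identical output.
#'
#' @inheritParams surface_radii
#' @param case_id optional case identifier string
#' @return an object of class `phantom_case` with fields `volume`,
#'   `spacing_mm`, `lesion_center_mm`, `diameter_mm`, `label`, `case_id`,
#'   `case_seed`
#' @export
generate_case <- function(config, label, case_seed, case_id = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (!label %in% c(0, 1)) stop("label must be 0 or 1")
  geom <- nodule_geometry(config, label, case_seed)

  shp <- config$volume_shape
  sp <- config$spacing_mm
  # axis coordinates of voxel centres (half-voxel convention)
  zc <- (seq_len(shp[1]) - 0.5) * sp[1]
  yc <- (seq_len(shp[2]) - 0.5) * sp[2]
  xc <- (seq_len(shp[3]) - 0.5) * sp[3]

  # the bump cap bounds the voxels that need the direction test
  rmax <- geom$r0 * (1 + radius_bump_cap(geom, config))
  zi <- which(abs(zc - geom$center_mm[1]) <= rmax + sp[1])
  yi <- which(abs(yc - geom$center_mm[2]) <= rmax + sp[2])
  xi <- which(abs(xc - geom$center_mm[3]) <= rmax + sp[3])
  if (length(zi) == 0 || length(yi) == 0 || length(xi) == 0)
    stop("lesion centre lies outside the volume")

  dz <- zc[zi] - geom$center_mm[1]
  dy <- yc[yi] - geom$center_mm[2]
  dx <- xc[xi] - geom$center_mm[3]
  nb <- c(length(zi), length(yi), length(xi))
  off <- cbind(rep(dz, times = nb[2] * nb[3]),
               rep(rep(dy, each = nb[1]), times = nb[3]),
               rep(dx, each = nb[1] * nb[2]))
  dist <- sqrt(rowSums(off^2))
  # bumps are non-negative, so dist <= r0 is always inside; only the shell
  # r0 < dist <= rmax needs the directional surface test
  inside <- dist <= geom$r0
  shell <- which(dist > geom$r0 & dist <= rmax)
  if (length(shell)) {
    u <- off[shell, , drop = FALSE] / dist[shell]
    rad <- radius_at_directions(geom, config, u)
    inside[shell] <- dist[shell] <= rad
  }
  inside_box <- array(inside, dim = nb)

  mask <- array(FALSE, dim = shp)
  mask[zi, yi, xi] <- inside_box

  # noise uses the same seeded stream, drawn after the geometry
  vol <- with_seed(geom$case_seed, {
    # re-draw geometry quantities to advance the stream identically
    invisible(stats::runif(1)); invisible(stats::runif(3))
    invisible(stats::rnorm(3 * nrow(geom$lobe_axes)))
    invisible(stats::rnorm(3 * nrow(geom$spike_axes)))
    v <- array(config$lung_hu_mean, dim = shp)
    if (config$lung_hu_sd > 0)
      v <- v + config$lung_hu_sd * array(stats::rnorm(prod(shp)), dim = shp)
    n_in <- sum(mask)
    v[mask] <- config$nodule_hu_mean +
      if (config$nodule_hu_sd > 0) config$nodule_hu_sd * stats::rnorm(n_in) else 0
    v
  })

  structure(list(volume = vol,
                 spacing_mm = sp,
                 lesion_center_mm = geom$center_mm,
                 diameter_mm = geom$diameter_mm,
                 label = as.integer(label),
                 case_id = case_id %||% sprintf("case_%06d", case_seed),
                 case_seed = as.integer(case_seed)),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case %s> label=%d, diameter=%.1f mm, grid %s @ (%s) mm\n",
              x$case_id, x$label, x$diameter_mm,
              paste(dim(x$volume), collapse = "x"),
              paste(format(x$spacing_mm, digits = 3), collapse = ", ")))
  invisible(x)
}

#' Generate a reproducible phantom cohort
#'
#' Per-case seeds are derived deterministically from `config$seed`, so the
#' cohort (including its manifest) is a pure function of the arguments. The
#' first `floor(n_cases * class_fraction)` cases carry label 1.
#'
#' @param n_cases number of cases (>= 2)
#' @param class_fraction fraction of label-1 (malignant-like) cases, in (0,1)
#' @param config a [phantom_config()]
#' @param materialise if `FALSE`, volumes are not built; only the manifest
#'   (and per-case geometry) is computed. Volumes can be regenerated on
#'   demand from the recorded seeds with [generate_case()].
#' @return object of class `phantom_cohort`: list with `manifest`
#'   (data.frame: case_id, label, center_*_mm, diameter_mm, case_seed),
#'   `cases` (list of `phantom_case` or `NULL`), and `config`
#' @export
generate_cohort <- function(n_cases, class_fraction, config = phantom_config(),
                            materialise = TRUE) {
  if (n_cases < 2) stop("n_cases must be at least 2")
  if (class_fraction <= 0 || class_fraction >= 1)
    stop("class_fraction must lie strictly between 0 and 1")
  n1 <- floor(n_cases * class_fraction)
  labels <- c(rep(1L, n1), rep(0L, n_cases - n1))
  seeds <- vapply(seq_len(n_cases), function(i) derive_seed(config$seed, i),
                  integer(1))
  ids <- sprintf("case_%04d", seq_len(n_cases))
  rows <- vector("list", n_cases)
  cases <- if (materialise) vector("list", n_cases) else NULL
  for (i in seq_len(n_cases)) {
    geom <- nodule_geometry(config, labels[i], seeds[i])
    rows[[i]] <- data.frame(case_id = ids[i], label = labels[i],
                            center_z_mm = geom$center_mm[1],
                            center_y_mm = geom$center_mm[2],
                            center_x_mm = geom$center_mm[3],
                            diameter_mm = geom$diameter_mm,
                            case_seed = seeds[i],
                            stringsAsFactors = FALSE)
    if (materialise)
      cases[[i]] <- generate_case(config, labels[i], seeds[i], case_id = ids[i])
  }
  structure(list(manifest = do.call(rbind, rows), cases = cases,
                 config = config),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  n <- nrow(x$manifest)
  cat(sprintf("<phantom_cohort> %d cases (%d malignant-like, %d benign-like)%s\n",
              n, sum(x$manifest$label == 1), sum(x$manifest$label == 0),
              if (is.null(x$cases)) " [manifest only]" else ""))
  invisible(x)
}

#' Regenerate a cohort case from its manifest row
#' @param cohort a `phantom_cohort`
#' @param i case index
#' @export
cohort_case <- function(cohort, i) {
  if (!is.null(cohort$cases)) return(cohort$cases[[i]])
  row <- cohort$manifest[i, ]
  generate_case(cohort$config, row$label, row$case_seed, case_id = row$case_id)
}

#' Write a cohort to NIfTI volumes plus a CSV manifest
#'
#' Volumes are written in (x, y, z) order with voxel spacing recorded in the
#' NIfTI header; the manifest records case_id, label, lesion centre (mm) and
#' diameter.
#' @param cohort a `phantom_cohort` (materialised or not)
#' @param out_dir output directory (created if needed)
#' @return invisibly, the manifest with a `path` column
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  paths <- character(nrow(man))
  for (i in seq_len(nrow(man))) {
    case <- cohort_case(cohort, i)
    paths[i] <- file.path(out_dir, paste0(case$case_id, ".nii.gz"))
    arr <- aperm(case$volume, c(3, 2, 1)) # (z,y,x) -> (x,y,z) for NIfTI
    img <- RNifti::asNifti(arr)
    img <- RNifti::`pixdim<-`(img, rev(case$spacing_mm))
    RNifti::writeNifti(img, paths[i])
  }
  man$path <- paths
  utils::write.csv(man, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read a NIfTI volume as a `ct_volume`
#' @param path NIfTI file path
#' @return a [ct_volume()] in (z, y, x) axis order
#' @export
read_ct_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  ct_volume(aperm(as.array(img), c(3, 2, 1)), spacing_mm = rev(sp))
}
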