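# CT preprocessing: isotropic resampling, HU window normalisation,
# lesion-centred ROI slice stacks, 5x5 montage assembly and the fixed
# augmentation scheme (4 rotations x 2 flips x 5 anchor translations = 40
# variants per case).

#' Construct a CT volume container
#'
#' Axes are ordered (z, y, x) with z the slice (cranio-caudal) axis. Voxel
#' centres follow the half-voxel convention: the centre of voxel `i`
#' (1-based) on an axis with spacing `s` lies at `origin + (i - 0.5) * s`.
#'
#' @param voxels 3D numeric array (z, y, x) of HU (or normalised) values
#' @param spacing_mm per-axis voxel size, strictly positive
#' @param origin_mm physical offset of the volume corner
#' @export
ct_volume <- function(voxels, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be strictly positive on every axis")
  structure(list(voxels = voxels, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels @ (%s) mm, range [%.1f, %.1f]\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing_mm, digits = 3), collapse = ", "),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

as_ct_volume <- function(x) {
  if (inherits(x, "ct_volume")) return(x)
  if (inherits(x, "phantom_case"))
    return(ct_volume(x$volume, x$spacing_mm))
  stop("cannot interpret input as a CT volume")
}

# trilinear sampling of `arr` at fractional (0-based continuous) voxel-centre
# indices given per axis; border values are clamped (constant extrapolation),
# so interpolation never expands the value range. Trilinear interpolation on
# a separable grid factorises into three successive 1D linear interpolations.
trilinear_axes <- function(arr, fz, fy, fx) {
  d <- dim(arr)
  prep <- function(f, n) {
    f <- pmin(pmax(f, 0), n - 1)
    i0 <- pmin(floor(f), n - 1)
    list(i0 = i0 + 1, i1 = pmin(i0 + 1, n - 1) + 1, w = f - i0)
  }
  z <- prep(fz, d[1]); y <- prep(fy, d[2]); x <- prep(fx, d[3])
  nz <- length(fz); ny <- length(fy); nx <- length(fx)
  # x axis (weights recycle across the flattened leading dims)
  wx <- rep(x$w, each = d[1] * d[2])
  A <- arr[, , x$i0, drop = FALSE] * (1 - wx) +
       arr[, , x$i1, drop = FALSE] * wx
  # y axis
  wy <- rep(y$w, each = d[1])
  A <- A[, y$i0, , drop = FALSE] * (1 - wy) +
       A[, y$i1, , drop = FALSE] * wy
  # z axis
  A <- A[z$i0, , , drop = FALSE] * (1 - z$w) +
       A[z$i1, , , drop = FALSE] * z$w
  array(A, dim = c(nz, ny, nx))
}

#' Resample a CT volume to isotropic spacing
#'
#' Output size per axis is `round(n * spacing / target)`; values are obtained
#' by trilinear interpolation at the new voxel centres (half-voxel
#' convention, border-clamped). A volume already at the target spacing is
#' returned unchanged up to floating-point identity.
#'
#' @param volume a [ct_volume()] (or `phantom_case`)
#' @param target_mm target spacing in mm (scalar, applied to every axis)
#' @export
resample_isotropic <- function(volume, target_mm = 1.0) {
  volume <- as_ct_volume(volume)
  stopifnot_scalar_num(target_mm, "target_mm")
  if (target_mm <= 0) stop("target_mm must be positive")
  d <- dim(volume$voxels)
  if (any(d < 2)) stop("degenerate volume: need at least 2 voxels per axis")
  sp <- volume$spacing_mm
  nd <- pmax(2L, as.integer(round(d * sp / target_mm)))
  # fractional source indices (0-based voxel-centre coordinates)
  fidx <- function(n_out, s_in) (( seq_len(n_out) - 0.5) * target_mm) / s_in - 0.5
  out <- trilinear_axes(volume$voxels, fidx(nd[1], sp[1]),
                        fidx(nd[2], sp[2]), fidx(nd[3], sp[3]))
  ct_volume(out, spacing_mm = rep(target_mm, 3), origin_mm = volume$origin_mm)
}

#' Window-normalise HU values to [0, 1]
#'
#' Linear display mapping `v -> clip((v - (level - width/2)) / width, 0, 1)`.
#' The defaults (width 1400 HU, level -500 HU) span [-1200, 200] HU, the
#' standard lung window.
#'
#' @param volume a [ct_volume()], `phantom_case`, or plain numeric array
#' @param window_width window width in HU (> 0)
#' @param window_level window centre in HU
#' @export
window_normalize <- function(volume, window_width = 1400, window_level = -500) {
  if (window_width <= 0) stop("window_width must be positive")
  f <- function(v) pmin(pmax((v - (window_level - window_width / 2)) /
                               window_width, 0), 1)
  if (is.numeric(volume)) return(f(volume))
  volume <- as_ct_volume(volume)
  volume$voxels <- f(volume$voxels)
  volume
}

#' Normalised pad value for out-of-volume regions
#'
#' Air (-1000 HU) passed through the default lung window.
#' @param window_width,window_level as in [window_normalize()]
#' @export
pad_value_normalized <- function(window_width = 1400, window_level = -500) {
  window_normalize(-1000, window_width, window_level)
}

# extract a (possibly out-of-range) index slab, padding with `pad`
slab <- function(arr, zi, yi, xi, pad) {
  d <- dim(arr)
  out <- array(pad, dim = c(length(zi), length(yi), length(xi)))
  okz <- zi >= 1 & zi <= d[1]; oky <- yi >= 1 & yi <= d[2]
  okx <- xi >= 1 & xi <= d[3]
  if (any(okz) && any(oky) && any(okx))
    out[okz, oky, okx] <- arr[zi[okz], yi[oky], xi[okx], drop = FALSE]
  out
}

#' Extract a lesion-centred stack of ROI slices
#'
#' Takes `n_slices` consecutive slices along the plane normal, centred on the
#' anchor slice ((n-1)/2 on each side), each cropped to the square ROI of
#' side `side_mm` centred on the in-plane anchor. Regions outside the volume
#' are padded (never truncated). Coronal slices are re-oriented so the
#' cranio-caudal axis is vertical.
#'
#' @param volume a [ct_volume()] at isotropic spacing (1 mm by default, so
#'   that `side_mm` = 50 yields 50 px)
#' @param anchor_mm physical anchor point (z, y, x) in mm
#' @param plane `"axial"` or `"coronal"`
#' @param n_slices number of slices (default 25)
#' @param side_mm ROI side length in mm (default 50)
#' @param pad_value fill for out-of-volume regions; defaults to air through
#'   the lung window for normalised volumes
#' @return array of dim `c(n_slices, side_px, side_px)`
#' @export
extract_slice_stack <- function(volume, anchor_mm,
                                plane = c("axial", "coronal"),
                                n_slices = 25L, side_mm = 50,
                                pad_value = pad_value_normalized()) {
  volume <- as_ct_volume(volume)
  plane <- match.arg(plane)
  sp <- volume$spacing_mm
  if (max(abs(sp - sp[1])) > 1e-6)
    stop("volume must be resampled to isotropic spacing first")
  s <- sp[1]
  d <- dim(volume$voxels)
  rel <- (anchor_mm - volume$origin_mm)
  if (any(rel < 0) || any(rel > d * sp))
    stop("anchor lies outside the volume's physical extent")
  a <- pmin(pmax(round(rel / s + 0.5), 1), d) # nearest voxel index
  side_px <- as.integer(round(side_mm / s))
  half_lo <- floor((side_px - 1) / 2)          # 24 for side 50
  half_hi <- side_px - 1 - half_lo             # 25 for side 50
  ns_half <- (n_slices - 1) %/% 2
  sl <- function(c0, half = FALSE) if (half) (c0 - half_lo):(c0 + half_hi)
        else (c0 - ns_half):(c0 + n_slices - 1 - ns_half)
  if (plane == "axial") {
    st <- slab(volume$voxels, sl(a[1]), sl(a[2], TRUE), sl(a[3], TRUE),
               pad_value)
  } else {
    st <- slab(volume$voxels, sl(a[1], TRUE), sl(a[2]), sl(a[3], TRUE),
               pad_value)
    st <- aperm(st, c(2, 1, 3)) # (y-slice, z rows, x cols): cranio-caudal vertical
  }
  st
}

#' Assemble 25 ROI slices into a 5x5 montage
#'
#' Row-major placement: slice `s` (0-based) occupies rows
#' `[P*floor(s/5), P*floor(s/5)+P)` and columns `[P*(s mod 5), ...)`, where
#' `P` is the slice side. Inverse of [partition_patches()].
#'
#' @param slices array `c(25, P, P)` or list of 25 `P x P` matrices
#' @return a `5P x 5P` matrix (250 x 250 at the default ROI size)
#' @export
assemble_montage <- function(slices) {
  if (is.list(slices)) {
    p <- nrow(slices[[1]])
    arr <- array(0, dim = c(length(slices), p, p))
    for (i in seq_along(slices)) arr[i, , ] <- slices[[i]]
    slices <- arr
  }
  d <- dim(slices)
  if (length(d) != 3L || d[1] != 25L || d[2] != d[3])
    stop("expected 25 square slices")
  p <- d[2]
  m <- matrix(0, 5 * p, 5 * p)
  for (s in 0:24) {
    r <- p * (s %/% 5); c <- p * (s %% 5)
    m[(r + 1):(r + p), (c + 1):(c + p)] <- slices[s + 1, , ]
  }
  m
}

#' The fixed augmentation scheme
#'
#' Enumerates all combinations of in-plane rotation (0/90/180/270 degrees),
#' horizontal flip (none/flip) and anchor translation (centre, +/-x, +/-y by
#' `translation_mm`), giving 4 x 2 x 5 = 40 variants per case. Row order is
#' deterministic: translation varies slowest, then flip, then rotation.
#'
#' @param translation_mm in-plane anchor shift in mm (default 5)
#' @return data.frame with columns `rotation_k`, `flip`, `translation_index`,
#'   `dz_mm`, `dy_mm`, `dx_mm`
#' @export
augmentation_scheme <- function(translation_mm = 5) {
  g <- expand.grid(rotation_k = 0:3, flip = c(FALSE, TRUE),
                   translation_index = 0:4)
  shifts <- rbind(c(0, 0, 0),
                  c(0, 0, translation_mm), c(0, 0, -translation_mm),
                  c(0, translation_mm, 0), c(0, -translation_mm, 0))
  g$dz_mm <- shifts[g$translation_index + 1, 1]
  g$dy_mm <- shifts[g$translation_index + 1, 2]
  g$dx_mm <- shifts[g$translation_index + 1, 3]
  g
}

#' The identity (no-augmentation) scheme
#' @export
identity_scheme <- function() augmentation_scheme()[1, , drop = FALSE]

apply_rot_flip <- function(stack, rotation_k, flip) {
  if (rotation_k == 0 && !flip) return(stack)
  out <- stack
  for (i in seq_len(dim(stack)[1])) {
    m <- stack[i, , ]
    if (rotation_k > 0) m <- rot90_mat(m, rotation_k)
    if (flip) m <- flip_h_mat(m)
    out[i, , ] <- m
  }
  out
}

#' Build augmented axial/coronal montage pairs for one annotated case
#'
#' The raw HU volume is resampled to 1 mm isotropic spacing, window
#' normalised, and for each scheme row the (possibly translated) anchor is
#' used to extract 25-slice axial and coronal ROI stacks; rotation and flip
#' are applied identically to every slice of both planes before montage
#' assembly. Translated anchors falling near the volume face are padded,
#' never dropped.
#'
#' @param volume a raw HU [ct_volume()] or `phantom_case`
#' @param annotation list with `center_mm` (z, y, x), `label`, `case_id`
#'   (taken from the `phantom_case` if omitted)
#' @param scheme an [augmentation_scheme()] (or [identity_scheme()])
#' @param target_mm isotropic resampling target (default 1 mm)
#' @param window_width,window_level HU window (defaults 1400 / -500)
#' @param use_montage if `FALSE`, the 5x5 montage is replaced by the central
#'   ROI slice upsampled to the montage size (the "no multi-slice montage"
#'   ablation input)
#' @return list of `montage_pair` objects, one per scheme row, each with
#'   fields `axial`, `coronal` (250 x 250 in [0,1]), `label`, `case_id`,
#'   `tag`
#' @export
augment_case <- function(volume, annotation = NULL,
                         scheme = augmentation_scheme(),
                         target_mm = 1.0, window_width = 1400,
                         window_level = -500, use_montage = TRUE) {
  if (is.null(annotation)) {
    if (!inherits(volume, "phantom_case"))
      stop("annotation required unless volume is a phantom_case")
    annotation <- list(center_mm = volume$lesion_center_mm,
                       label = volume$label, case_id = volume$case_id)
  }
  vol <- resample_isotropic(as_ct_volume(volume), target_mm)
  vol <- window_normalize(vol, window_width, window_level)
  pad <- pad_value_normalized(window_width, window_level)

  # extraction depends only on the anchor; rotation/flip reuse the stacks
  anchors <- unique(scheme[, c("dz_mm", "dy_mm", "dx_mm")])
  stack_cache <- list()
  key <- function(dz, dy, dx) sprintf("%g_%g_%g", dz, dy, dx)
  for (i in seq_len(nrow(anchors))) {
    anc <- annotation$center_mm + as.numeric(anchors[i, ])
    anc <- pmin(pmax(anc, vol$origin_mm + 1e-9),
                vol$origin_mm + dim(vol$voxels) * vol$spacing_mm - 1e-9)
    stack_cache[[key(anchors$dz_mm[i], anchors$dy_mm[i], anchors$dx_mm[i])]] <-
      list(axial = extract_slice_stack(vol, anc, "axial", pad_value = pad),
           coronal = extract_slice_stack(vol, anc, "coronal", pad_value = pad))
  }

  to_image <- function(stack) {
    if (use_montage) return(assemble_montage(stack))
    centre <- stack[13, , ] # central ROI slice, upsampled x5 (nearest)
    centre[rep(seq_len(nrow(centre)), each = 5),
           rep(seq_len(ncol(centre)), each = 5)]
  }

  pairs <- vector("list", nrow(scheme))
  for (i in seq_len(nrow(scheme))) {
    st <- stack_cache[[key(scheme$dz_mm[i], scheme$dy_mm[i], scheme$dx_mm[i])]]
    ax <- apply_rot_flip(st$axial, scheme$rotation_k[i], scheme$flip[i])
    co <- apply_rot_flip(st$coronal, scheme$rotation_k[i], scheme$flip[i])
    pairs[[i]] <- structure(
      list(axial = to_image(ax), coronal = to_image(co),
           label = annotation$label, case_id = annotation$case_id,
           tag = list(rotation_k = scheme$rotation_k[i],
                      flip = scheme$flip[i],
                      translation_index = scheme$translation_index[i])),
      class = "montage_pair")
  }
  pairs
}

#' @export
print.montage_pair <- function(x, ...) {
  cat(sprintf("<montage_pair %s> label=%d, rot=%d flip=%s trans=%d, %dx%d\n",
              x$case_id, x$label, x$tag$rotation_k, x$tag$flip,
              x$tag$translation_index, nrow(x$axial), ncol(x$axial)))
  invisible(x)
}

#' Build the montage-pair dataset for a phantom cohort
#'
#' Applies the augmentation scheme to every case, producing a deterministic
#' dataset manifest (one row per montage pair) and optionally the montage
#' images themselves, either in memory or written as 16-bit PNG pairs.
#'
#' @param cohort a `phantom_cohort` (materialised or manifest-only)
#' @param scheme an [augmentation_scheme()]; use [identity_scheme()] for the
#'   unaugmented dataset used at fine-tuning
#' @param out_dir if non-NULL, write PNG images and `dataset_manifest.csv`
#'   there
#' @param materialise_images if `FALSE`, only the manifest is produced (the
#'   scheme is still enumerated per case); pairs are regenerable per case
#' @param use_montage see [augment_case()]
#' @return list with `manifest` (case_id, label, rotation_k, flip,
#'   translation_index, and paths when written) and `pairs` (list of
#'   `montage_pair`, or `NULL`)
#' @export
build_dataset <- function(cohort, scheme = augmentation_scheme(),
                          out_dir = NULL, materialise_images = TRUE,
                          use_montage = TRUE) {
  man <- cohort$manifest
  rows <- vector("list", nrow(man))
  all_pairs <- if (materialise_images) vector("list", nrow(man)) else NULL
  for (i in seq_len(nrow(man))) {
    tags <- scheme[, c("rotation_k", "flip", "translation_index")]
    rows[[i]] <- cbind(data.frame(case_id = man$case_id[i],
                                  label = man$label[i],
                                  stringsAsFactors = FALSE),
                       tags, row.names = NULL)
    if (materialise_images) {
      case <- cohort_case(cohort, i)
      all_pairs[[i]] <- augment_case(case, scheme = scheme,
                                     use_montage = use_montage)
    }
  }
  manifest <- do.call(rbind, rows)
  pairs <- if (materialise_images) do.call(c, all_pairs) else NULL
  if (!is.null(out_dir) && materialise_images) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("writing PNG montages requires the 'png' package")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ax_paths <- co_paths <- character(length(pairs))
    for (j in seq_along(pairs)) {
      p <- pairs[[j]]
      stem <- sprintf("%s_r%d_f%d_t%d", p$case_id, p$tag$rotation_k,
                      as.integer(p$tag$flip), p$tag$translation_index)
      ax_paths[j] <- file.path(out_dir, paste0(stem, "_axial.png"))
      co_paths[j] <- file.path(out_dir, paste0(stem, "_coronal.png"))
      png::writePNG(p$axial, ax_paths[j])
      png::writePNG(p$coronal, co_paths[j])
    }
    manifest$axial_path <- ax_paths
    manifest$coronal_path <- co_paths
    utils::write.csv(manifest, file.path(out_dir, "dataset_manifest.csv"),
                     row.names = FALSE)
  }
  list(manifest = manifest, pairs = pairs)
}
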