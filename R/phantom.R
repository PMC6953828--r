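#' @importFrom stats runif rnorm median mad fft pnorm sd quantile
#' @importFrom Matrix sparseMatrix Cholesky solve
NULL

# Coordinate convention (used everywhere in this package):
#   matrices are indexed [row, col]; row 1 is VENTRAL (sternum), the last row
#   is DORSAL (spine); the section is viewed from caudal, so the animal's
#   RIGHT side is on the image LEFT (low column indices).

#' Ellipse mask on a pixel grid
#'
#' @param n grid side length (pixels)
#' @param center numeric length-2, (row, col) of the ellipse center
#' @param semi numeric length-2, (row, col) semi-axes in pixels
#' @return logical n x n matrix
#' @keywords internal
ellipse_mask <- function(n, center, semi) {
  r <- matrix(seq_len(n), n, n)
  c <- matrix(seq_len(n), n, n, byrow = TRUE)
  ((r - center[1]) / semi[1])^2 + ((c - center[2]) / semi[2])^2 <= 1
}

#' Build a synthetic pig-thorax conductivity phantom
#'
#' Constructs a 2D cross-sectional phantom: an elliptic body outline with
#' right and left lung fields, the accessory (median) lobe found in pigs,
#' and a ventro-medial heart. Geometry is schematic, not an anatomical atlas.
#' With `geometry_jitter > 0`, lung/heart sizes and positions are perturbed
#' (seeded) to emulate between-animal variability.
#'
#' @param grid_shape side length of the square pixel grid (default 64)
#' @param pixel_size pixel edge length in cm (default 0.5)
#' @param ellipse_axes full axis lengths of the body ellipse in pixels,
#'   `c(lateral, ventrodorsal)`; the ventrodorsal axis times `pixel_size`
#'   is the sternovertebral distance
#' @param background_conductivity soft-tissue conductivity, S/m
#' @param lung_conductivity_expiration lung conductivity at end-expiration, S/m
#' @param heart_conductivity heart/blood conductivity, S/m
#' @param geometry_jitter fractional random perturbation of organ geometry
#'   (0 = fixed reference anatomy)
#' @param seed integer seed controlling the jitter
#' @return an object of class `thorax_phantom`: list with `grid_shape`,
#'   `pixel_size`, `body_mask`, `lung_masks` (right/left/accessory),
#'   `heart_mask`, `sternovertebral_distance` (cm) and the conductivities
#' @export
build_phantom <- function(grid_shape = 64L,
                          pixel_size = 0.5,
                          ellipse_axes = c(0.875, 0.6875) * grid_shape,
                          background_conductivity = 0.4,
                          lung_conductivity_expiration = 0.2,
                          heart_conductivity = 0.6,
                          geometry_jitter = 0,
                          seed = 1L) {
  if (grid_shape < 32) stop("grid_shape must be >= 32")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (any(ellipse_axes <= 0)) stop("ellipse_axes must be positive")
  if (background_conductivity <= 0 || lung_conductivity_expiration <= 0 ||
      heart_conductivity <= 0) stop("conductivities must be positive")

  n <- as.integer(grid_shape)
  ctr <- (n + 1) / 2
  ar <- ellipse_axes[2] / 2   # ventrodorsal semi-axis (rows)
  ac <- ellipse_axes[1] / 2   # lateral semi-axis (cols)

  jit <- local_rng(seed, function() {
    if (geometry_jitter > 0) {
      runif(8, 1 - geometry_jitter, 1 + geometry_jitter)
    } else rep(1, 8)
  })

  body <- ellipse_mask(n, c(ctr, ctr), c(ar, ac))

  # Lungs: two dorso-lateral ellipses; accessory lobe ventro-medial; heart
  # ventral, slightly toward the animal's left (image right).
  heart <- ellipse_mask(n, c(ctr - 0.35 * ar * jit[5], ctr + 0.05 * ac * jit[6]),
                        c(0.28 * ar * jit[7], 0.22 * ac * jit[8]))
  rl <- ellipse_mask(n, c(ctr + 0.08 * ar, ctr - 0.42 * ac * jit[3]),
                     c(0.60 * ar * jit[1], 0.34 * ac * jit[2]))
  ll <- ellipse_mask(n, c(ctr + 0.08 * ar, ctr + 0.42 * ac * jit[3]),
                     c(0.60 * ar * jit[1], 0.34 * ac * jit[4]))
  acc <- ellipse_mask(n, c(ctr - 0.52 * ar * jit[5], ctr - 0.10 * ac),
                      c(0.20 * ar * jit[7], 0.22 * ac * jit[2]))

  heart <- heart & body
  rl <- rl & body & !heart & !acc
  ll <- ll & body & !heart & !acc
  acc <- acc & body & !heart

  stopifnot(!any(rl & ll))
  ph <- structure(list(
    grid_shape = n,
    pixel_size = pixel_size,
    ellipse_axes = ellipse_axes,
    body_mask = body,
    lung_masks = list(right = rl, left = ll, accessory = acc),
    heart_mask = heart,
    sternovertebral_distance = ellipse_axes[2] * pixel_size,
    background_conductivity = background_conductivity,
    lung_conductivity_expiration = lung_conductivity_expiration,
    heart_conductivity = heart_conductivity,
    geometry_jitter = geometry_jitter,
    seed = as.integer(seed)
  ), class = "thorax_phantom")
  ph
}

#' @export
print.thorax_phantom <- function(x, ...) {
  cat(sprintf("thorax_phantom: %dx%d grid, %.2f cm/px, SV distance %.1f cm\n",
              x$grid_shape, x$grid_shape, x$pixel_size,
              x$sternovertebral_distance))
  cat(sprintf("  body %d px, lungs %d px, heart %d px\n",
              sum(x$body_mask),
              sum(x$lung_masks$right) + sum(x$lung_masks$left) +
                sum(x$lung_masks$accessory),
              sum(x$heart_mask)))
  invisible(x)
}

#' Anatomical segment labels for PTX localization
#'
#' Partitions the lung fields into ten segments used to report PTX location,
#' mirroring a porcine classification scheme in which the anterior segments
#' are 2, 3, 5 and 6, and segment 6 is the ventro-medial accessory lobe.
#' The layout is a schematic stand-in: right lung splits into ventral
#' lateral/medial (2, 3), mid-dorsal lateral/medial (1, 4) and far-dorsal (7);
#' left lung into ventral (5), mid-dorsal medial/lateral (8, 9) and
#' far-dorsal (10).
#'
#' @param phantom a `thorax_phantom`
#' @return integer matrix, 0 outside the lungs, 1-10 on lung pixels
#' @export
segment_map <- function(phantom) {
  stopifnot(inherits(phantom, "thorax_phantom"))
  n <- phantom$grid_shape
  ctr <- (n + 1) / 2
  ar <- phantom$ellipse_axes[2] / 2
  seg <- matrix(0L, n, n)
  row <- matrix(seq_len(n), n, n)
  col <- matrix(seq_len(n), n, n, byrow = TRUE)

  rl <- phantom$lung_masks$right
  ll <- phantom$lung_masks$left
  ventral <- row < ctr
  fardorsal <- row >= ctr + 0.35 * ar

  # right lung (image left): lateral = smaller col
  rc <- mean(col[rl])
  seg[rl & ventral & col < rc] <- 2L
  seg[rl & ventral & col >= rc] <- 3L
  seg[rl & !ventral & !fardorsal & col < rc] <- 1L
  seg[rl & !ventral & !fardorsal & col >= rc] <- 4L
  seg[rl & fardorsal] <- 7L

  lc <- mean(col[ll])
  seg[ll & ventral] <- 5L
  seg[ll & !ventral & !fardorsal & col >= lc] <- 9L
  seg[ll & !ventral & !fardorsal & col < lc] <- 8L
  seg[ll & fardorsal] <- 10L

  seg[phantom$lung_masks$accessory] <- 6L
  seg
}

#' Place a pneumothorax lesion against the pleural boundary of a segment
#'
#' The in-plane lesion is a disk of diameter `trans_frac` times the
#' sternovertebral distance, anchored against the outer (pleural) chest-wall
#' boundary adjacent to the requested segment -- free pleural air collects in
#' the nondependent periphery. The seed jitters the anchor angle slightly so
#' repeated cases differ; placement is deterministic for a fixed seed.
#'
#' @param phantom a `thorax_phantom`
#' @param segment_id target segment, 1-10
#' @param trans_frac transversal lesion diameter as a fraction of the
#'   sternovertebral distance (> 0)
#' @param cc_cm craniocaudal (out-of-plane) extent in cm (>= 0)
#' @param seed integer seed for anchor jitter
#' @param air_conductivity effective in-plane conductivity of the pleural
#'   air core, S/m. Deliberately above the true conductivity of air: in a
#'   2D forward model an insulating inclusion blocks in-plane current that
#'   in the real 3D thorax detours around the lesion cranio-caudally, so a
#'   physical air value grossly exaggerates current squeezing along the
#'   chest wall. The default (half the expiratory lung conductivity) keeps
#'   the static contrast secondary to the ventilation loss, which is the
#'   detection-relevant signal in time-difference imaging.
#' @return object of class `ptx_lesion`: `segment_id`, `center` (row, col),
#'   `transversal_diameter` (cm), `craniocaudal_extent` (cm),
#'   `in_plane_mask`, `conductivity` (S/m, air-like)
#' @export
place_lesion <- function(phantom, segment_id, trans_frac, cc_cm,
                         seed = 1L, air_conductivity = 0.1) {
  stopifnot(inherits(phantom, "thorax_phantom"))
  if (!(segment_id %in% 1:10)) stop("segment_id must be in 1..10")
  if (trans_frac <= 0) stop("trans_frac must be positive")
  if (cc_cm < 0) stop("cc_cm must be non-negative")

  seg <- segment_map(phantom)
  if (!any(seg == segment_id)) stop("segment not present in phantom")
  n <- phantom$grid_shape
  ctr <- (n + 1) / 2
  d_cm <- trans_frac * phantom$sternovertebral_distance
  d_px <- d_cm / phantom$pixel_size
  r_px <- d_px / 2

  # ray from body center through (jittered) segment centroid; the lesion
  # nestles just inside the pleural boundary, i.e. against the outermost
  # lung pixel of the segment along that ray, displacing peripheral lung
  idx <- which(seg == segment_id, arr.ind = TRUE)
  cen <- colMeans(idx)
  ang <- atan2(cen[2] - ctr, cen[1] - ctr)
  ang <- ang + local_rng(seed, function() runif(1, -0.15, 0.15))
  dirv <- c(cos(ang), sin(ang))

  ar <- phantom$ellipse_axes[2] / 2
  ac <- phantom$ellipse_axes[1] / 2
  proj <- (idx[, 1] - ctr) * dirv[1] + (idx[, 2] - ctr) * dirv[2]
  anchor <- idx[which.max(proj), ]

  # pull the disk inward from the pleural anchor until fully inside the body
  fits <- FALSE
  for (pull in seq(max(0, r_px - 1), 2.5 * r_px + 2, by = 0.5)) {
    cpt <- anchor - dirv * pull
    disk <- disk_mask(n, cpt, r_px)
    if (sum(disk) > 0 && all(phantom$body_mask[disk])) { fits <- TRUE; break }
  }
  if (!fits || 2 * r_px > 2 * min(ar, ac)) stop("lesion does not fit")

  structure(list(
    segment_id = as.integer(segment_id),
    center = cpt,
    transversal_diameter = d_cm,
    craniocaudal_extent = cc_cm,
    in_plane_mask = disk,
    conductivity = air_conductivity,
    trans_frac = trans_frac
  ), class = "ptx_lesion")
}

#' @keywords internal
disk_mask <- function(n, center, radius_px) {
  r <- matrix(seq_len(n), n, n)
  c <- matrix(seq_len(n), n, n, byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius_px^2
}

#' Clinical relevance classification of a PTX lesion
#'
#' A lesion is `trans20` when its maximum transversal diameter strictly
#' exceeds 20% of the sternovertebral distance, `cc3` when its craniocaudal
#' extent strictly exceeds 3 cm, `transcc` when both hold, and relevant when
#' either holds.
#'
#' @param lesion a `ptx_lesion` (or a list with `transversal_diameter` and
#'   `craniocaudal_extent` in cm)
#' @param sternovertebral_distance cm
#' @return list with logicals `is_trans20`, `is_cc3`, `is_transcc`,
#'   `is_relevant`
#' @export
classify_relevance <- function(lesion, sternovertebral_distance) {
  stopifnot(sternovertebral_distance > 0)
  t20 <- lesion$transversal_diameter > 0.20 * sternovertebral_distance
  cc3 <- lesion$craniocaudal_extent > 3.0
  list(is_trans20 = t20, is_cc3 = cc3,
       is_transcc = t20 && cc3, is_relevant = t20 || cc3)
}

#' Partial-volume attenuation weight of an out-of-plane lesion
#'
#' A lesion with small craniocaudal extent occupies only part of the
#' EIT-sensitive slab: surrounding conductive tissue counterbalances its
#' low conductivity, attenuating its in-plane contrast. Modelled as a linear
#' ramp saturating when the lesion spans the whole +/- `slab_halfwidth_cm`
#' analysis window.
#'
#' @param cc_cm craniocaudal lesion extent, cm (>= 0)
#' @param slab_halfwidth_cm half-width of the sensitive slab, cm (default 3)
#' @return weight in `[0, 1]`: `min(1, cc_cm / (2 * slab_halfwidth_cm))`
#' @export
partial_volume_weight <- function(cc_cm, slab_halfwidth_cm = 3) {
  if (any(cc_cm < 0)) stop("cc_cm must be non-negative")
  if (slab_halfwidth_cm <= 0) stop("slab_halfwidth_cm must be positive")
  pmin(1, cc_cm / (2 * slab_halfwidth_cm))
}

#' Ground-truth record for a simulated case
#'
#' @param phantom a `thorax_phantom`
#' @param lesions list of `ptx_lesion`
#' @return object of class `case_truth`: per-lesion relevance labels, the
#'   segment of the largest relevant lesion (or NA), affected quadrants and
#'   whether any lesion lies between the heart and the chest wall
#' @export
case_truth <- function(phantom, lesions = list()) {
  stopifnot(inherits(phantom, "thorax_phantom"))
  sv <- phantom$sternovertebral_distance
  labels <- lapply(lesions, classify_relevance, sternovertebral_distance = sv)

  largest <- NA_integer_
  rel <- vapply(labels, `[[`, logical(1), "is_relevant")
  if (any(rel)) {
    diams <- vapply(lesions, `[[`, numeric(1), "transversal_diameter")
    diams[!rel] <- -Inf
    largest <- lesions[[which.max(diams)]]$segment_id
  }

  n <- phantom$grid_shape
  ctr <- (n + 1) / 2
  quads <- character(0)
  hc <- FALSE
  if (length(lesions)) {
    hdil <- dilate_mask(phantom$heart_mask, 2L)
    for (les in lesions) {
      m <- les$in_plane_mask
      idx <- which(m, arr.ind = TRUE)
      v <- idx[, 1] < ctr
      r <- idx[, 2] < ctr
      quads <- union(quads, unique(paste0(ifelse(v, "ventral", "dorsal"), "-",
                                          ifelse(r, "right", "left"))))
      if (any(hdil & dilate_mask(m, 2L))) hc <- TRUE
    }
  }
  structure(list(lesions = lesions, labels = labels,
                 largest_relevant_segment = largest,
                 quadrant_labels = sort(quads),
                 heart_contact = hc), class = "case_truth")
}

#' @keywords internal
dilate_mask <- function(mask, k = 1L) {
  n1 <- nrow(mask); n2 <- ncol(mask)
  out <- mask
  for (i in seq_len(k)) {
    sh <- out
    sh[-1, ] <- sh[-1, ] | out[-n1, ]
    sh[-n1, ] <- sh[-n1, ] | out[-1, ]
    sh[, -1] <- sh[, -1] | out[, -n2]
    sh[, -n2] <- sh[, -n2] | out[, -1]
    out <- sh
  }
  out
}

# Run fn with a private RNG stream, restoring the caller's RNG state.
#' @keywords internal
local_rng <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}
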