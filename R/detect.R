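#' Pooled healthy reference from tidal images
#'
#' Each healthy tidal image is normalized to unit sum over the mask (making
#' the reference invariant to global signal amplitude), then pooled pixelwise
#' into a mean and SD image. The SD is floored at `sd_floor` to avoid
#' division blow-up where healthy subjects are identical.
#'
#' @param tidal_images list of `eit_image` (>= 2) from healthy cases
#' @param sd_floor lower bound for the pixelwise SD
#' @return object of class `healthy_reference`: `mean_image`, `sd_image`,
#'   `mask`, `n_subjects`, `normalization = "unit-sum"`
#' @export
build_reference <- function(tidal_images, sd_floor = 1e-6) {
  if (length(tidal_images) < 2) stop("need at least 2 healthy cases")
  mask <- tidal_images[[1]]$mask
  arr <- vapply(tidal_images, function(im) {
    tot <- sum(im$values[mask])
    if (!is.finite(tot) || tot <= 0)
      stop("tidal image with non-positive total cannot be normalized")
    v <- im$values / tot
    v[!mask] <- 0
    v
  }, matrix(0, nrow(mask), ncol(mask)))
  mu <- apply(arr, c(1, 2), mean)
  sdv <- apply(arr, c(1, 2), stats::sd)
  sdv[sdv < sd_floor] <- sd_floor
  sdv[!mask] <- sd_floor
  structure(list(mean_image = mu, sd_image = sdv, mask = mask,
                 n_subjects = length(tidal_images),
                 normalization = "unit-sum"),
            class = "healthy_reference")
}

#' Pixelwise deviation (z-score) map against the healthy reference
#'
#' `z = (mean_healthy - tidal_normalized) / sd_healthy`: positive where the
#' case ventilates less than healthy controls. Unit-sum normalization makes
#' the map invariant to global scaling of the raw tidal image.
#'
#' @param tidal an `eit_image` (raw tidal image, positive total)
#' @param reference a `healthy_reference`
#' @return 32 x 32 z-score matrix (0 outside the mask)
#' @export
deviation_map <- function(tidal, reference) {
  stopifnot(inherits(reference, "healthy_reference"))
  mask <- reference$mask
  tot <- sum(tidal$values[mask])
  if (!is.finite(tot) || tot <= 0) stop("tidal image total must be positive")
  nv <- tidal$values / tot
  z <- (reference$mean_image - nv) / reference$sd_image
  z[!mask] <- 0
  z
}

#' Semi-automatized PTX detection by pooled-reference deviation mapping
#'
#' Thresholds the deviation map at `z_threshold`, finds 8-connected
#' components inside the mask, discards components smaller than
#' `min_area_pixels`, and reports the largest remaining component as the
#' suspected PTX region (mirroring the convention of scoring the largest
#' PTX visible in the summary image).
#'
#' @param tidal an `eit_image`
#' @param reference a `healthy_reference`
#' @param z_threshold z-score threshold (default 2)
#' @param min_area_pixels minimum component area (default 8, about one
#'   resolvable feature on the 32x32 grid)
#' @param segment_image optional 32x32 segment label matrix from
#'   [segment_map_image()]; when given, the flagged region is localized
#' @return object of class `ptx_detection`: `is_positive`, `deviation_map`,
#'   `region_mask`, `segment_id` (NA when negative or no segment image),
#'   `score` (max z in the region), `area_pixels`
#' @export
detect_ptx <- function(tidal, reference, z_threshold = 2,
                       min_area_pixels = 8L, segment_image = NULL) {
  if (z_threshold <= 0 || min_area_pixels <= 0)
    stop("thresholds must be positive")
  z <- deviation_map(tidal, reference)
  hot <- z >= z_threshold & reference$mask
  lab <- label_components(hot, connectivity = 8L)
  region <- matrix(FALSE, nrow(z), ncol(z))
  score <- NA_real_; area <- 0L; segid <- NA_integer_
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_area_pixels)
    if (length(keep)) {
      best <- keep[which.max(sizes[keep])]
      region <- lab == best
      score <- max(z[region])
      area <- sum(region)
      if (!is.null(segment_image))
        segid <- localize_segment(region, segment_image)
    }
  }
  structure(list(is_positive = area > 0L, deviation_map = z,
                 region_mask = region, segment_id = segid,
                 score = score, area_pixels = as.integer(area)),
            class = "ptx_detection")
}

#' 8- or 4-connected component labelling of a binary mask
#'
#' @param mask logical matrix
#' @param connectivity 4 or 8
#' @return integer matrix of component labels (0 = background), labelled in
#'   column-major discovery order
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  n1 <- nrow(mask); n2 <- ncol(mask)
  lab <- matrix(0L, n1, n2)
  if (connectivity == 8L) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1)
    dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
  }
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      pr <- (p - 1L) %% n1 + 1L
      pc <- (p - 1L) %/% n1 + 1L
      nr <- pr + dr; nc <- pc + dc
      ok <- nr >= 1 & nr <= n1 & nc >= 1 & nc <= n2
      np <- (nc[ok] - 1L) * n1 + nr[ok]
      np <- np[mask[np] & lab[np] == 0L]
      if (length(np)) { lab[np] <- cur; queue <- c(queue, np) }
    }
  }
  lab
}

#' Localize a flagged region to an anatomical segment
#'
#' The segment with the largest pixel overlap wins; ties break toward the
#' lowest segment id. A region with no overlap with any lung segment maps to
#' the segment whose centroid is nearest the region centroid.
#'
#' @param region_mask logical matrix (non-empty)
#' @param segment_image integer matrix of segment labels (same shape)
#' @return integer segment id
#' @export
localize_segment <- function(region_mask, segment_image) {
  if (!any(region_mask)) stop("empty region")
  labs <- segment_image[region_mask]
  labs <- labs[labs > 0]
  if (length(labs)) {
    tab <- table(labs)
    return(as.integer(names(tab)[which.max(tab)]))  # ties: lowest id first
  }
  ridx <- which(region_mask, arr.ind = TRUE)
  rcen <- colMeans(ridx)
  ids <- sort(unique(segment_image[segment_image > 0]))
  d <- vapply(ids, function(s) {
    si <- which(segment_image == s, arr.ind = TRUE)
    sc <- colMeans(si)
    sum((sc - rcen)^2)
  }, numeric(1))
  as.integer(ids[which.min(d)])
}

#' Segment adjacency on a segment label image
#'
#' Two segments are adjacent when any of their pixels touch (8-connectivity,
#' after 1-pixel dilation to bridge background gaps between lung fields).
#'
#' @param segment_image integer matrix of segment labels
#' @return symmetric logical matrix indexed by segment id (diagonal TRUE)
#' @export
segments_adjacent <- function(segment_image) {
  ids <- sort(unique(segment_image[segment_image > 0]))
  k <- max(ids)
  adj <- matrix(FALSE, k, k)
  masks <- lapply(seq_len(k), function(s)
    if (s %in% ids) dilate_mask(segment_image == s, 1L) else NULL)
  for (a in ids) for (b in ids) {
    if (a >= b) next
    if (any(masks[[a]] & masks[[b]])) adj[a, b] <- adj[b, a] <- TRUE
  }
  diag(adj) <- TRUE
  adj
}
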