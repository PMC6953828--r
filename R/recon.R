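#' Sensitivity (Jacobian) matrix of the adjacent-drive frame
#'
#' Row `(d, m)` holds the derivative of measurement `(drive d, pair m)` with
#' respect to the conductivity of each body-mask pixel, computed by the
#' adjoint method: the product of the drive field and the measurement lead
#' field summed over the grid edges incident to the pixel. For the adjacent
#' protocol the 16 lead fields coincide with the 16 drive fields, so one
#' factorization yields the whole matrix.
#'
#' @param phantom a `thorax_phantom`
#' @param belt an `electrode_belt`
#' @param reference_field conductivity matrix to linearize around (default:
#'   homogeneous background conductivity on the body mask)
#' @return matrix (208 x n_mask_pixels) with attributes `body` (grid indices
#'   of the columns), `grid_shape`, and `mask`
#' @export
eit_jacobian <- function(phantom, belt = electrode_belt(phantom),
                         reference_field = NULL) {
  mask <- phantom$body_mask
  edges <- grid_edges(mask)
  if (is.null(reference_field)) {
    sig <- rep(phantom$background_conductivity, edges$n)
  } else {
    sig <- reference_field[mask]
  }
  if (any(!is.finite(sig)) || any(sig <= 0))
    stop("reference conductivity must be positive on the body mask")

  W <- belt_matrix(belt, edges)
  sol <- solve_all_drives(sig, belt, edges, W = W, keep_u = TRUE)
  U <- sol$U                                    # n_pix x 16 drive/lead fields
  Du <- U[edges$i, , drop = FALSE] - U[edges$j, , drop = FALSE]

  # d(edge conductance)/d(pixel conductivity), harmonic-mean discretization
  si <- sig[edges$i]; sj <- sig[edges$j]
  dgi <- 2 * sj^2 / (si + sj)^2
  dgj <- 2 * si^2 / (si + sj)^2
  nedge <- length(edges$i)
  Dmat <- sparseMatrix(i = c(seq_len(nedge), seq_len(nedge)),
                       j = c(edges$i, edges$j),
                       x = c(dgi, dgj), dims = c(nedge, edges$n))

  pr <- measurement_protocol(belt$n_electrodes)
  M <- Du[, pr$drive, drop = FALSE] * Du[, pr$measure, drop = FALSE]
  J <- -as.matrix(Matrix::crossprod(M, Dmat))
  attr(J, "body") <- edges$body
  attr(J, "grid_shape") <- phantom$grid_shape
  attr(J, "mask") <- mask
  J
}

#' Precompute the linear one-step Tikhonov reconstruction operator
#'
#' Solves `min ||J x - dv||^2 + lambda^2 * s * ||x||^2` where `s` is the mean
#' diagonal of `J'J` (making `lambda` a dimensionless, frame-scale-free
#' weight). The default `lambda` was frozen after an L-curve sweep on a
#' healthy simulated case.
#'
#' @param jacobian matrix from [eit_jacobian()]
#' @param lambda dimensionless regularization weight (> 0)
#' @return reconstruction matrix (n_mask_pixels x 208) carrying the same
#'   geometry attributes as the Jacobian
#' @export
recon_operator <- function(jacobian, lambda = 0.18) {
  if (lambda <= 0) stop("lambda must be positive")
  JtJ <- crossprod(jacobian)
  s <- mean(diag(JtJ))
  R <- solve(JtJ + lambda^2 * s * diag(nrow(JtJ)), t(jacobian))
  attr(R, "body") <- attr(jacobian, "body")
  attr(R, "grid_shape") <- attr(jacobian, "grid_shape")
  attr(R, "mask") <- attr(jacobian, "mask")
  attr(R, "lambda") <- lambda
  R
}

# Map a vector on forward-grid mask pixels to the 32x32 display grid with
# inscribed circular mask (the de-facto convention of 16-electrode systems).
#' @keywords internal
to_image_grid <- function(x_body, body, grid_shape, out = 32L) {
  full <- numeric(grid_shape * grid_shape)
  full[body] <- x_body
  m <- matrix(full, grid_shape, grid_shape)
  # block-average onto the out x out grid
  brk <- function(i) pmin(out, floor((i - 1) * out / grid_shape) + 1L)
  ri <- brk(seq_len(grid_shape))
  agg <- rowsum(m, ri)
  agg <- t(rowsum(t(agg), ri))
  cnt <- as.numeric(table(ri))
  img <- agg / outer(cnt, cnt)
  mask <- inscribed_circle_mask(out)
  img[!mask] <- 0
  structure(list(values = img, mask = mask), class = "eit_image")
}

#' @keywords internal
inscribed_circle_mask <- function(out = 32L) {
  ctr <- (out + 1) / 2
  r <- matrix(seq_len(out), out, out)
  c <- matrix(seq_len(out), out, out, byrow = TRUE)
  (r - ctr)^2 + (c - ctr)^2 <= (out / 2)^2
}

#' Linearized time-difference image reconstruction
#'
#' One-step Tikhonov solution of `J x = reference - frame`, mapped onto the
#' 32x32 circular display grid. Sign convention: a ventilation increase
#' (conductivity drop relative to the reference) is positive.
#'
#' @param frame numeric measurement vector (length 208) or `voltage_frame`
#' @param reference_frame same length reference measurements
#' @param jacobian matrix from [eit_jacobian()], or a precomputed operator
#'   from [recon_operator()] (then `lambda` is ignored)
#' @param lambda regularization weight, see [recon_operator()]
#' @return an `eit_image` (32x32 values, circular mask)
#' @export
reconstruct_difference <- function(frame, reference_frame, jacobian,
                                   lambda = 0.18) {
  v <- if (inherits(frame, "voltage_frame")) frame$measurements else frame
  r <- if (inherits(reference_frame, "voltage_frame"))
    reference_frame$measurements else reference_frame
  if (length(v) != length(r)) stop("frame and reference lengths differ")
  R <- if (!is.null(attr(jacobian, "lambda"))) jacobian
       else recon_operator(jacobian, lambda)
  if (ncol(R) != length(v)) stop("operator / frame size mismatch")
  x <- as.numeric(R %*% (r - v))
  to_image_grid(x, attr(R, "body"), attr(R, "grid_shape"))
}

#' Reconstruct a whole voltage series against a common reference
#'
#' The reference frame defaults to the end-expiration frame of the first
#' detected breath (found from a provisional global waveform referenced to
#' the first frame; the linearity of the reconstruction makes breath timing
#' independent of that provisional choice).
#'
#' @param vseries a `voltage_series`
#' @param operator reconstruction operator from [recon_operator()]
#' @param reference_index frame index to use as reference, or NULL to choose
#'   automatically as above
#' @return list: `images` (32 x 32 x T array), `mask`, `reference_index`,
#'   `frame_rate`, `breaths` (from [detect_breaths()] on the global waveform)
#' @export
reconstruct_series <- function(vseries, operator, reference_index = NULL) {
  stopifnot(inherits(vseries, "voltage_series"))
  fr <- vseries$frames
  nt <- nrow(fr)
  gvec <- colSums(operator)   # linear functional: global image sum
  if (is.null(reference_index)) {
    g0 <- as.numeric(gvec %*% (fr[1, ] - t(fr)))  # provisional, ref = frame 1
    br <- detect_breaths(roi_waveform(g0, vseries$frame_rate, "global"))
    reference_index <- if (nrow(br)) br$end_expiration_frame[1] else 1L
  }
  ref <- fr[reference_index, ]
  X <- operator %*% (ref - t(fr))               # n_pix x T
  imgs <- array(0, c(32, 32, nt))
  mask <- inscribed_circle_mask(32L)
  for (t in seq_len(nt)) {
    im <- to_image_grid(X[, t], attr(operator, "body"),
                        attr(operator, "grid_shape"))
    imgs[, , t] <- im$values
  }
  g <- apply(imgs, 3, sum)
  br <- detect_breaths(roi_waveform(g, vseries$frame_rate, "global"))
  list(images = imgs, mask = mask, reference_index = reference_index,
       frame_rate = vseries$frame_rate, breaths = br)
}

#' @keywords internal
roi_waveform <- function(samples, frame_rate, roi_name = "global") {
  structure(list(roi_name = roi_name, samples = as.numeric(samples),
                 frame_rate = frame_rate), class = "roi_waveform")
}

#' Detect breaths in a global impedance waveform
#'
#' Troughs mark end-expiration, the following peak end-inspiration. The
#' waveform is median-smoothed (0.4 s window) to suppress cardiac spikes;
#' candidate extrema are then pruned zigzag-fashion until every retained
#' breath has amplitude at least `min_prominence` times the median breath
#' amplitude. Equal-height troughs resolve to the earlier frame.
#'
#' @param global_waveform a waveform object (`samples`, `frame_rate`) or
#'   numeric vector (then `frame_rate` must be given)
#' @param min_prominence fraction of the median breath amplitude below which
#'   oscillations are discarded
#' @param frame_rate sampling rate in Hz when `global_waveform` is a vector
#' @return data.frame with columns `end_expiration_frame`,
#'   `end_inspiration_frame` (zero rows when no breaths are found)
#' @export
detect_breaths <- function(global_waveform, min_prominence = 0.5,
                           frame_rate = NULL) {
  if (inherits(global_waveform, "roi_waveform")) {
    x <- global_waveform$samples
    fs <- global_waveform$frame_rate
  } else {
    x <- as.numeric(global_waveform)
    if (is.null(frame_rate)) stop("frame_rate required for a bare vector")
    fs <- frame_rate
  }
  if (length(x) < 2 * fs) stop("need at least 2 s of signal")

  k <- max(3L, round(0.4 * fs))
  if (k %% 2 == 0) k <- k + 1L
  s <- stats::runmed(x, min(k, length(x) - (1 - length(x) %% 2)))

  ext <- find_extrema(s)
  if (nrow(ext) < 2) return(empty_breaths())

  # zigzag pruning: drop the weakest adjacent extremum pair until all
  # remaining swings clear the prominence threshold
  repeat {
    amp <- abs(diff(s[ext$idx]))
    if (!length(amp)) return(empty_breaths())
    thr <- min_prominence * stats::median(amp)
    w <- which.min(amp)
    if (amp[w] >= thr || nrow(ext) <= 2) break
    ext <- ext[-c(w, w + 1), , drop = FALSE]
  }

  tr <- which(ext$type == "min")
  br <- list(ee = integer(0), ei = integer(0))
  for (i in tr) {
    if (i + 1 <= nrow(ext) && ext$type[i + 1] == "max") {
      br$ee <- c(br$ee, ext$idx[i]); br$ei <- c(br$ei, ext$idx[i + 1])
    }
  }
  if (!length(br$ee)) return(empty_breaths())
  data.frame(end_expiration_frame = br$ee, end_inspiration_frame = br$ei)
}

#' @keywords internal
empty_breaths <- function() {
  data.frame(end_expiration_frame = integer(0),
             end_inspiration_frame = integer(0))
}

# Strict alternating local extrema; plateaus resolve to their first frame.
#' @keywords internal
find_extrema <- function(s) {
  d <- diff(s)
  nz <- which(d != 0)
  if (!length(nz)) return(data.frame(idx = integer(0), type = character(0)))
  idx <- integer(0); type <- character(0)
  prev_sign <- 0
  for (q in nz) {
    sg <- sign(d[q])
    if (prev_sign == 0) { prev_sign <- sg; next }
    if (sg != prev_sign) {
      # extremum at the first frame of the plateau ending at q
      run_start <- q
      while (run_start > 1 && d[run_start - 1] == 0) run_start <- run_start - 1
      idx <- c(idx, run_start)
      type <- c(type, if (sg > 0) "min" else "max")
      prev_sign <- sg
    }
  }
  data.frame(idx = idx, type = type, stringsAsFactors = FALSE)
}

#' Tidal image of one breath
#'
#' Pixelwise difference between the end-inspiration and end-expiration
#' reconstructed images of a breath.
#'
#' @param images 32 x 32 x T array of reconstructed images (or the list
#'   returned by [reconstruct_series()])
#' @param breath one row of a breath segmentation (list/row with
#'   `end_expiration_frame`, `end_inspiration_frame`)
#' @return an `eit_image` with `breath_index` attribute
#' @export
tidal_image <- function(images, breath) {
  if (is.list(images) && !is.null(images$images)) images <- images$images
  ee <- breath$end_expiration_frame[1]
  ei <- breath$end_inspiration_frame[1]
  nt <- dim(images)[3]
  if (is.na(ee) || is.na(ei) || ee < 1 || ei < 1 || ee > nt || ei > nt)
    stop("breath indices out of range")
  structure(list(values = images[, , ei] - images[, , ee],
                 mask = inscribed_circle_mask(dim(images)[1])),
            class = "eit_image", breath_index = c(ee, ei))
}

#' Breath-averaged tidal image
#'
#' @param images as in [tidal_image()]
#' @param breaths breath segmentation data.frame (>= 1 row)
#' @return an `eit_image`, the pixelwise mean of per-breath tidal images
#' @export
average_tidal_image <- function(images, breaths) {
  if (is.list(images) && !is.null(images$images)) images <- images$images
  if (!nrow(breaths)) stop("no breaths to average over")
  acc <- 0
  for (i in seq_len(nrow(breaths)))
    acc <- acc + tidal_image(images, breaths[i, ])$values
  structure(list(values = acc / nrow(breaths),
                 mask = inscribed_circle_mask(dim(images)[1])),
            class = "eit_image")
}

#' Global and quadrant ROI waveforms
#'
#' Per-frame sums of the reconstructed image over the whole mask and over the
#' four thoracic quadrants (ventral/dorsal x right/left; the animal's right
#' is on the image left). The quadrants partition the mask, so their sums add
#' to the global sum.
#'
#' @param images 32 x 32 x T array (or [reconstruct_series()] output)
#' @param frame_rate Hz (taken from the list input when available)
#' @return named list of waveforms: `global`, `ventral-right`,
#'   `ventral-left`, `dorsal-right`, `dorsal-left`
#' @export
quadrant_waveforms <- function(images, frame_rate = NULL) {
  if (is.list(images) && !is.null(images$images)) {
    if (is.null(frame_rate)) frame_rate <- images$frame_rate
    images <- images$images
  }
  if (is.null(frame_rate)) stop("frame_rate required")
  n <- dim(images)[1]
  if (!length(dim(images)) == 3 || dim(images)[3] < 1)
    stop("empty image sequence")
  mask <- inscribed_circle_mask(n)
  half <- n / 2
  qmask <- list(
    "ventral-right" = row(mask) <= half & col(mask) <= half,
    "ventral-left"  = row(mask) <= half & col(mask) > half,
    "dorsal-right"  = row(mask) > half & col(mask) <= half,
    "dorsal-left"   = row(mask) > half & col(mask) > half)
  flat <- matrix(images, n * n, dim(images)[3])
  out <- list(global = roi_waveform(colSums(flat[mask, , drop = FALSE]),
                                    frame_rate, "global"))
  for (nm in names(qmask)) {
    sel <- qmask[[nm]] & mask
    out[[nm]] <- roi_waveform(colSums(flat[sel, , drop = FALSE]),
                              frame_rate, nm)
  }
  out
}

#' Per-pixel ventilation phase map
#'
#' Phase of each pixel's time course at the respiratory frequency relative to
#' the global waveform, from the cross-spectrum at the dominant global
#' frequency bin. Positive values mean the pixel lags the global signal.
#' Pixels whose spectral amplitude at that bin is below `amp_frac` of the
#' maximum are flagged undefined (NA).
#'
#' @param images 32 x 32 x T array (or [reconstruct_series()] output)
#' @param global_waveform global waveform (defaults to the image sum)
#' @param amp_frac relative amplitude threshold for defined phase
#' @return 32 x 32 matrix of phase lags in radians (NA where undefined)
#' @export
phase_map <- function(images, global_waveform = NULL, amp_frac = 0.05) {
  if (is.list(images) && !is.null(images$images)) images <- images$images
  n <- dim(images)[1]; nt <- dim(images)[3]
  flat <- matrix(images, n * n, nt)
  g <- if (is.null(global_waveform)) colSums(flat)
       else if (inherits(global_waveform, "roi_waveform"))
         global_waveform$samples else as.numeric(global_waveform)
  if (length(g) != nt) stop("waveform length mismatch")
  G <- stats::fft(g - mean(g))
  half <- 2:(floor(nt / 2) + 1)
  kf <- half[which.max(Mod(G[half]))]
  if (Mod(G[kf]) == 0) stop("no respiratory peak found")

  Xf <- stats::mvfft(t(flat - rowMeans(flat)))[kf, ]
  amp <- Mod(Xf)
  ph <- Arg(G[kf] * Conj(Xf))
  ph[amp < amp_frac * max(amp)] <- NA_real_
  out <- matrix(ph, n, n)
  attr(out, "amplitude") <- matrix(amp, n, n)
  attr(out, "frequency_bin") <- kf
  out
}

#' Segment labels on the 32x32 display grid
#'
#' Majority-vote downsampling of the forward-grid [segment_map()] onto the
#' display grid (0 where no lung pixel falls in a display cell).
#'
#' @param phantom a `thorax_phantom`
#' @param out display grid side (32)
#' @return integer `out` x `out` matrix of segment labels
#' @export
segment_map_image <- function(phantom, out = 32L) {
  seg <- segment_map(phantom)
  n <- phantom$grid_shape
  brk <- function(i) pmin(out, floor((i - 1) * out / n) + 1L)
  ri <- brk(seq_len(n))
  res <- matrix(0L, out, out)
  idx <- which(seg > 0, arr.ind = TRUE)
  if (!nrow(idx)) return(res)
  cell <- cbind(ri[idx[, 1]], ri[idx[, 2]])
  lab <- seg[idx]
  key <- paste(cell[, 1], cell[, 2])
  for (k in unique(key)) {
    sel <- key == k
    tab <- table(lab[sel])
    best <- as.integer(names(tab)[which.max(tab)])  # ties: lowest label
    rc <- cell[which(sel)[1], ]
    res[rc[1], rc[2]] <- best
  }
  res
}
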