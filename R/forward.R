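#' 16-electrode belt on the body boundary
#'
#' Electrodes are placed at equal angles around the body ellipse, ordered
#' counterclockwise (as viewed from caudal) starting at the ventral midline.
#' Each electrode is a small extended contact patch just inside the chest
#' wall: its current injection (and, by reciprocity, its measurement pick-up)
#' is spread over the body pixels within `radius_cm` of the contact point
#' with a smooth Hann taper. A fixed physical patch size keeps the frame
#' rotationally symmetric on a homogeneous disk and makes electrode
#' potentials converge under grid refinement, neither of which holds for
#' pixel-snapped point electrodes on a Cartesian raster.
#'
#' @param phantom a `thorax_phantom` (or any list with `body_mask`,
#'   `ellipse_axes`, `grid_shape`, `pixel_size`)
#' @param n_electrodes number of electrodes (16)
#' @param pull_cm depth of the contact point inside the body outline, cm
#' @param radius_cm physical radius of the contact patch, cm
#' @return object of class `electrode_belt`: `n_electrodes`, `angles`
#'   (radians from ventral midline), `positions` (row, col contact points),
#'   `weights` (grid-pixel index / electrode / weight triplets; each
#'   electrode's weights sum to 1)
#' @export
electrode_belt <- function(phantom, n_electrodes = 16L, pull_cm = 0.75,
                           radius_cm = 1.5) {
  stopifnot(n_electrodes >= 4, pull_cm > 0, radius_cm > 0)
  n <- phantom$grid_shape
  px <- phantom$pixel_size
  ctr <- (n + 1) / 2
  ar <- phantom$ellipse_axes[2] / 2
  ac <- phantom$ellipse_axes[1] / 2
  angles <- (seq_len(n_electrodes) - 1) * 2 * pi / n_electrodes

  bi <- which(phantom$body_mask, arr.ind = TRUE)
  pos <- matrix(0, n_electrodes, 2)
  trip <- NULL
  for (k in seq_len(n_electrodes)) {
    th <- angles[k]
    # theta = 0 points ventral (row 1); increases toward the animal's left
    dirv <- c(-cos(th), sin(th))
    tmax <- 1 / sqrt((dirv[1] / ar)^2 + (dirv[2] / ac)^2)
    p <- c(ctr, ctr) + dirv * (tmax - pull_cm / px)
    pos[k, ] <- p
    d <- sqrt((bi[, 1] - p[1])^2 + (bi[, 2] - p[2])^2) * px
    sel <- which(d < radius_cm)
    if (length(sel) < 1)
      stop("electrode patch finds no body pixels; grid too coarse")
    w <- (1 + cos(pi * d[sel] / radius_cm)) / 2
    w <- w / sum(w)
    pix <- (bi[sel, 2] - 1) * n + bi[sel, 1]
    trip <- rbind(trip, cbind(pix = pix, electrode = k, w = w))
  }
  structure(list(n_electrodes = as.integer(n_electrodes), angles = angles,
                 positions = pos, weights = trip),
            class = "electrode_belt")
}

# Electrode injection/pick-up matrix restricted to mask pixels
# (n_mask x n_electrodes); columns sum to 1.
#' @keywords internal
belt_matrix <- function(belt, edges) {
  ridx <- match(belt$weights[, "pix"], edges$body)
  if (anyNA(ridx)) stop("electrode support outside body mask")
  W <- matrix(0, edges$n, belt$n_electrodes)
  W[cbind(ridx, belt$weights[, "electrode"])] <- belt$weights[, "w"]
  W
}

# Discrete conduction system on the body mask: 5-point finite differences
# with harmonic-mean edge conductances and natural (no-flux) boundaries.
#' @keywords internal
grid_edges <- function(mask) {
  n1 <- nrow(mask); n2 <- ncol(mask)
  idx <- matrix(NA_integer_, n1, n2)
  body <- which(mask)
  idx[body] <- seq_along(body)
  # vertical edges (row neighbours)
  v_ok <- mask[-n1, ] & mask[-1, ]
  vi <- which(v_ok)
  r <- ((vi - 1) %% (n1 - 1)) + 1
  c <- ((vi - 1) %/% (n1 - 1)) + 1
  e1 <- cbind(idx[cbind(r, c)], idx[cbind(r + 1, c)])
  # horizontal edges (col neighbours)
  h_ok <- mask[, -n2] & mask[, -1]
  hi <- which(h_ok)
  r <- ((hi - 1) %% n1) + 1
  c <- ((hi - 1) %/% n1) + 1
  e2 <- cbind(idx[cbind(r, c)], idx[cbind(r, c + 1)])
  edges <- rbind(e1, e2)
  # ground node: mask pixel closest to the mask centroid (interior, never an
  # electrode), fixing the potential gauge of the singular Neumann system
  bi <- arrayInd(body, c(n1, n2))
  cen <- colMeans(bi)
  ground <- which.min((bi[, 1] - cen[1])^2 + (bi[, 2] - cen[2])^2)
  list(i = edges[, 1], j = edges[, 2], n = length(body), body = body,
       ground = ground)
}

#' @keywords internal
edge_conductance <- function(edges, sig_body) {
  si <- sig_body[edges$i]; sj <- sig_body[edges$j]
  2 * si * sj / (si + sj)
}

# Stiffness matrix with the ground node clamped (row/col cleared, diag 1),
# which keeps the system symmetric positive definite.
#' @keywords internal
assemble_system <- function(edges, g) {
  n <- edges$n
  g0 <- edges$ground
  ii <- c(edges$i, edges$j, edges$i, edges$j)
  jj <- c(edges$i, edges$j, edges$j, edges$i)
  xx <- c(g, g, -g, -g)
  keep <- ii != g0 & jj != g0
  sparseMatrix(i = c(ii[keep], g0), j = c(jj[keep], g0),
               x = c(xx[keep], 1), dims = c(n, n))
}

#' Solve the forward conduction problem for one drive pair
#'
#' Solves the discrete conduction equation `div(sigma grad u) = 0` on the
#' body mask with unit current injected at the source electrode and withdrawn
#' at the sink (no-flux boundary elsewhere). Potentials are gauged to zero
#' mean over the electrodes.
#'
#' @param field conductivity matrix (positive on the body mask)
#' @param belt an `electrode_belt`
#' @param drive_pair integer length-2: source and sink electrode indices
#' @param phantom the `thorax_phantom` supplying the body mask
#' @return list: `electrode_potentials` (zero-mean over electrodes),
#'   `u` (potentials at all mask pixels), `residual` (relative)
#' @export
solve_forward <- function(field, belt, drive_pair, phantom) {
  stopifnot(length(drive_pair) == 2, drive_pair[1] != drive_pair[2])
  mask <- phantom$body_mask
  sig <- field[mask]
  if (any(!is.finite(sig)) || any(sig <= 0))
    stop("conductivity must be positive and finite on the body mask")
  edges <- grid_edges(mask)
  g <- edge_conductance(edges, sig)
  A <- assemble_system(edges, g)
  W <- belt_matrix(belt, edges)
  b <- W[, drive_pair[1]] - W[, drive_pair[2]]
  b[edges$ground] <- 0
  u <- as.numeric(Matrix::solve(A, b))
  res <- as.numeric(sqrt(sum((A %*% u - b)^2)) / sqrt(sum(b^2)))
  if (res > 1e-8)
    stop(sprintf("forward solve did not converge: residual %.2e", res))
  ep <- as.numeric(crossprod(W, u))
  ep <- ep - mean(ep)
  list(electrode_potentials = ep, u = u, residual = res)
}

# All adjacent-drive solutions at once (shared factorization). Returns
# electrode potentials (n_e x n_e drives) and, optionally, full potentials.
#' @keywords internal
solve_all_drives <- function(sig_body, belt, edges, W = belt_matrix(belt, edges),
                             keep_u = FALSE) {
  g <- edge_conductance(edges, sig_body)
  A <- assemble_system(edges, g)
  ne <- belt$n_electrodes
  B <- W - W[, c(2:ne, 1)]
  B[edges$ground, ] <- 0
  ch <- Matrix::Cholesky(methods::as(A, "symmetricMatrix"), LDL = FALSE)
  U <- as.matrix(Matrix::solve(ch, B))
  out <- list(EP = crossprod(W, U))
  if (keep_u) out$U <- U
  out
}

#' Acquire one 208-measurement voltage frame (adjacent drive protocol)
#'
#' For each of the 16 adjacent drive pairs `(k, k+1)`, differential voltages
#' are recorded on the 13 adjacent electrode pairs not involving a drive
#' electrode. Ordering is drive-major; within a drive, measurement pairs run
#' counterclockwise starting just past the drive pair. Drive current is unit
#' (the physical 5 mA at 50 kHz is metadata only).
#'
#' @param field conductivity matrix
#' @param belt an `electrode_belt`
#' @param phantom the `thorax_phantom` supplying the body mask
#' @return object of class `voltage_frame`: `measurements` (length 208 for 16
#'   electrodes), `drive_index`, `measure_index` (first electrode of each pair)
#' @export
acquire_frame <- function(field, belt, phantom) {
  mask <- phantom$body_mask
  sig <- field[mask]
  if (any(!is.finite(sig)) || any(sig <= 0))
    stop("conductivity must be positive and finite on the body mask")
  edges <- grid_edges(mask)
  sol <- solve_all_drives(sig, belt, edges)
  frame_from_potentials(sol$EP, belt)
}

#' @keywords internal
measurement_protocol <- function(ne = 16L) {
  drv <- integer(0); msr <- integer(0)
  for (k in seq_len(ne)) {
    prev <- (k - 2L) %% ne + 1L
    nxt <- k %% ne + 1L
    for (off in seq_len(ne)) {
      m <- (k - 1L + off) %% ne + 1L
      if (m %in% c(prev, k, nxt)) next
      drv <- c(drv, k); msr <- c(msr, m)
    }
  }
  list(drive = drv, measure = msr)
}

#' @keywords internal
frame_from_potentials <- function(EP, belt) {
  ne <- belt$n_electrodes
  pr <- measurement_protocol(ne)
  nxt <- pr$measure %% ne + 1L
  v <- EP[cbind(pr$measure, pr$drive)] - EP[cbind(nxt, pr$drive)]
  structure(list(measurements = as.numeric(v), drive_index = pr$drive,
                 measure_index = pr$measure), class = "voltage_frame")
}

#' Acquire a voltage frame series from a conductivity series
#'
#' One frame per conductivity field, order preserved; deterministic.
#'
#' @param series a `cond_series`
#' @param belt an `electrode_belt` (default: belt built on the series phantom)
#' @return object of class `voltage_series`: `frames` (n_frames x 208 matrix),
#'   `frame_rate`, `times`, plus truth metadata carried along
#' @export
acquire_series <- function(series, belt = electrode_belt(series$phantom)) {
  stopifnot(inherits(series, "cond_series"))
  nt <- ncol(series$sigma)
  if (nt == 0) stop("empty conductivity series")
  edges <- grid_edges(series$phantom$body_mask)
  W <- belt_matrix(belt, edges)
  nm <- belt$n_electrodes * (belt$n_electrodes - 3L)
  out <- matrix(0, nt, nm)
  for (t in seq_len(nt)) {
    sol <- solve_all_drives(series$sigma[, t], belt, edges, W = W)
    out[t, ] <- frame_from_potentials(sol$EP, belt)$measurements
  }
  structure(list(frames = out, frame_rate = series$dynamics$frame_rate,
                 times = series$times, truth = series$truth,
                 spike_frames = series$spike_frames,
                 phantom = series$phantom, belt = belt),
            class = "voltage_series")
}
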