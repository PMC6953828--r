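#' Run-length encode a matrix for compact JSON serialization
#'
#' @param m matrix (logical or integer)
#' @return list with `dim`, `values`, `lengths` (column-major runs)
#' @export
rle_encode <- function(m) {
  r <- rle(as.vector(m))
  list(dim = dim(m), values = r$values, lengths = r$lengths)
}

#' Decode a run-length-encoded matrix
#'
#' @param x list from [rle_encode()]
#' @return matrix
#' @export
rle_decode <- function(x) {
  matrix(inverse.rle(structure(list(values = x$values,
                                    lengths = x$lengths), class = "rle")),
         x$dim[1], x$dim[2])
}

#' Write phantom and case truth as JSON
#'
#' Scalars are stored directly; masks and the segment map are run-length
#' encoded.
#'
#' @param phantom a `thorax_phantom`
#' @param truth a `case_truth` (optional)
#' @param path output file
#' @export
write_case_json <- function(phantom, truth = NULL, path) {
  obj <- list(
    grid_shape = phantom$grid_shape,
    pixel_size = phantom$pixel_size,
    ellipse_axes = phantom$ellipse_axes,
    sternovertebral_distance = phantom$sternovertebral_distance,
    conductivities = list(
      background = phantom$background_conductivity,
      lung_expiration = phantom$lung_conductivity_expiration,
      heart = phantom$heart_conductivity),
    body_mask = rle_encode(phantom$body_mask),
    heart_mask = rle_encode(phantom$heart_mask),
    lung_masks = lapply(phantom$lung_masks, rle_encode),
    segment_map = rle_encode(segment_map(phantom)))
  if (!is.null(truth)) {
    obj$truth <- list(
      largest_relevant_segment = truth$largest_relevant_segment,
      quadrant_labels = truth$quadrant_labels,
      heart_contact = truth$heart_contact,
      lesions = lapply(seq_along(truth$lesions), function(i) {
        les <- truth$lesions[[i]]
        c(list(segment_id = les$segment_id,
               transversal_diameter = les$transversal_diameter,
               craniocaudal_extent = les$craniocaudal_extent,
               conductivity = les$conductivity,
               in_plane_mask = rle_encode(les$in_plane_mask)),
          truth$labels[[i]])
      }))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a voltage series as CSV plus a JSON metadata sidecar
#'
#' Plain-text stand-in for a hierarchical scientific container: the frame
#' matrix (one row per frame, 208 columns) goes to `<path>`, acquisition
#' attributes (frame rate, electrode layout) to `<path>.meta.json`.
#'
#' @param vseries a `voltage_series`
#' @param path CSV output file
#' @export
write_voltage_csv <- function(vseries, path) {
  utils::write.table(vseries$frames, path, sep = ",", row.names = FALSE,
                     col.names = paste0("m", seq_len(ncol(vseries$frames))))
  meta <- list(frame_rate = vseries$frame_rate,
               n_frames = nrow(vseries$frames),
               electrode_layout = "16 adjacent drive, 13 measurements/drive",
               spike_frames = vseries$spike_frames)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a voltage series written by [write_voltage_csv()]
#'
#' @param path CSV file
#' @return a `voltage_series` (frames + metadata; no truth attached)
#' @export
read_voltage_csv <- function(path) {
  fr <- as.matrix(utils::read.csv(path))
  dimnames(fr) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  structure(list(frames = fr, frame_rate = meta$frame_rate,
                 times = (seq_len(nrow(fr)) - 1) / meta$frame_rate,
                 truth = NULL, spike_frames = meta$spike_frames),
            class = "voltage_series")
}

#' Write ROI waveforms as CSV (frame, global, vr, vl, dr, dl)
#'
#' @param waveforms list from [quadrant_waveforms()]
#' @param path output file
#' @export
write_waveforms_csv <- function(waveforms, path) {
  df <- data.frame(frame = seq_along(waveforms$global$samples),
                   global = waveforms$global$samples,
                   vr = waveforms[["ventral-right"]]$samples,
                   vl = waveforms[["ventral-left"]]$samples,
                   dr = waveforms[["dorsal-right"]]$samples,
                   dl = waveforms[["dorsal-left"]]$samples)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an image as a plain-text portable graymap (PGM, P2)
#'
#' Values are linearly rescaled to 0..255 over the mask; optionally a region
#' overlay is marked at the maximum gray value plus channel convention noted
#' in the comment line (text format keeps artifacts inspectable anywhere).
#'
#' @param image an `eit_image` (or matrix)
#' @param path output file
#' @param overlay optional logical matrix; overlay pixels are forced to 255
#' @export
write_pgm <- function(image, path, overlay = NULL) {
  v <- if (inherits(image, "eit_image")) image$values else image
  rng <- range(v)
  g <- if (diff(rng) > 0) round(255 * (v - rng[1]) / diff(rng)) else v * 0
  if (!is.null(overlay)) g[overlay] <- 255
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", "# eitptx image; overlay pixels = 255",
               paste(ncol(g), nrow(g)), "255"), con)
  utils::write.table(g, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Serialize a detection result as JSON
#'
#' @param det a `ptx_detection`
#' @param path output file
#' @export
write_detection_json <- function(det, path) {
  obj <- list(is_positive = det$is_positive,
              segment_id = if (is.na(det$segment_id)) NULL else det$segment_id,
              score = if (is.na(det$score)) NULL else det$score,
              area_pixels = det$area_pixels,
              region_mask = rle_encode(det$region_mask))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Parse a key = value configuration file
#'
#' Lines of `key = value`; `#` starts a comment; values are parsed as
#' numbers, logicals (true/false) or strings.
#'
#' @param path config file
#' @return named list
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
      else val
  }
  out
}
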