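#' Shared simulation context for an end-to-end study
#'
#' Builds the reference anatomy, electrode belt, sensitivity matrix and
#' frozen reconstruction operator once; individual subjects share the body
#' outline (and therefore the belt and reconstruction model) but have
#' jittered organ geometry, mirroring a device that reconstructs every
#' subject with one generic thorax model.
#'
#' @param grid_shape forward grid side (default 64)
#' @param lambda regularization weight for the reconstruction operator
#' @param ... passed to [build_phantom()] for the reference anatomy
#' @return object of class `study_context`: `phantom`, `belt`, `jacobian`,
#'   `operator`, `segment_image`, `adjacency`
#' @export
study_context <- function(grid_shape = 64L, lambda = 0.18, ...) {
  ph <- build_phantom(grid_shape = grid_shape, geometry_jitter = 0, ...)
  belt <- electrode_belt(ph)
  J <- eit_jacobian(ph, belt)
  R <- recon_operator(J, lambda)
  seg <- segment_map_image(ph)
  structure(list(phantom = ph, belt = belt, jacobian = J, operator = R,
                 segment_image = seg, adjacency = segments_adjacent(seg)),
            class = "study_context")
}

#' Simulate one subject end-to-end
#'
#' Generates a jittered phantom, optional lesion, conductivity series,
#' voltage acquisition, difference reconstruction, breath detection and the
#' breath-averaged tidal image.
#'
#' @param ctx a `study_context`
#' @param seed integer seed for this subject (geometry jitter, lesion
#'   placement and noise)
#' @param lesion NULL for a healthy subject, or a list with `segment_id`,
#'   `trans_frac`, `cc_cm`
#' @param geometry_jitter between-subject anatomical variability (fraction)
#' @param dynamics a `dynamics_config`; the default is the desk-scale
#'   setting (10 Hz, 9 s, i.e. three breaths at 20/min) chosen to keep a
#'   full study tractable on one CPU; rates and noise keep their standard
#'   defaults
#' @return list: `tidal` (`eit_image`), `truth` (`case_truth`), `phantom`,
#'   `recon` (output of [reconstruct_series()]), `voltages`
#' @export
simulate_case <- function(ctx, seed, lesion = NULL, geometry_jitter = 0.05,
                          dynamics = dynamics_config(frame_rate = 10,
                                                     duration = 9,
                                                     seed = seed)) {
  stopifnot(inherits(ctx, "study_context"))
  ph <- build_phantom(grid_shape = ctx$phantom$grid_shape,
                      pixel_size = ctx$phantom$pixel_size,
                      ellipse_axes = ctx$phantom$ellipse_axes,
                      background_conductivity = ctx$phantom$background_conductivity,
                      lung_conductivity_expiration = ctx$phantom$lung_conductivity_expiration,
                      heart_conductivity = ctx$phantom$heart_conductivity,
                      geometry_jitter = geometry_jitter, seed = seed)
  lesions <- list()
  if (!is.null(lesion)) {
    lesions <- list(place_lesion(ph, lesion$segment_id, lesion$trans_frac,
                                 lesion$cc_cm, seed = seed))
  }
  cs <- conductivity_series(ph, lesions, dynamics)
  vs <- acquire_series(cs, ctx$belt)
  rec <- reconstruct_series(vs, ctx$operator)
  tid <- if (nrow(rec$breaths)) average_tidal_image(rec$images, rec$breaths)
         else stop("no breaths detected in simulated case (seed ", seed, ")")
  list(tidal = tid, truth = cs$truth, phantom = ph, recon = rec,
       voltages = vs)
}

#' Build the pooled healthy reference from simulated subjects
#'
#' @param ctx a `study_context`
#' @param n_subjects number of healthy pigs to pool (default 20)
#' @param seed base seed; subject i uses `seed * 1000 + i`
#' @param ... passed to [simulate_case()]
#' @return a `healthy_reference`
#' @export
simulate_reference <- function(ctx, n_subjects = 20L, seed = 1L, ...) {
  tids <- lapply(seq_len(n_subjects), function(i)
    simulate_case(ctx, seed = seed * 1000 + i, lesion = NULL, ...)$tidal)
  build_reference(tids)
}

#' Default lesion parameter ranges per relevance category
#'
#' Healthy draws no lesion. `trans20`: transversal diameter 22-30% of the
#' sternovertebral distance with craniocaudal extent 1-3 cm (relevant only
#' transversally); `cc3`: 10-18% with 3.5-8 cm; `transcc`: both large.
#' Segments are drawn from the anterior set (2, 3, 5, 6) where free pleural
#' air collects in supine animals.
#'
#' @param category one of "healthy", "trans20", "cc3", "transcc"
#' @param seed integer seed for the draw
#' @return NULL or a lesion spec list for [simulate_case()]
#' @export
draw_lesion <- function(category, seed) {
  if (category == "healthy") return(NULL)
  local_rng(seed, function() {
    seg <- sample(c(2L, 3L, 5L, 6L), 1)
    switch(category,
      trans20 = list(segment_id = seg, trans_frac = runif(1, 0.22, 0.30),
                     cc_cm = runif(1, 1, 3)),
      cc3 = list(segment_id = seg, trans_frac = runif(1, 0.10, 0.18),
                 cc_cm = runif(1, 3.5, 8)),
      transcc = list(segment_id = seg, trans_frac = runif(1, 0.22, 0.30),
                     cc_cm = runif(1, 3.5, 8)),
      stop("unknown category: ", category))
  })
}

#' Run a synthetic PTX detection study end-to-end
#'
#' Simulates a case mix (phantom, forward acquisition, reconstruction,
#' pooled-reference detection), compares the detector against ground truth
#' per relevance category and emits a summary table mirroring a
#' missed-by-size analysis, plus per-case records.
#'
#' @param config list with fields `n_healthy`, `n_trans20`, `n_cc3`,
#'   `n_transcc` (case counts), `seed`, and optional `z_threshold`,
#'   `min_area_pixels`, `n_reference`, `lambda`, `grid_shape`
#' @param ctx optional prebuilt `study_context` (built from config otherwise)
#' @param reference optional prebuilt `healthy_reference`
#' @return object of class `study_result`: `summary` (per-category
#'   data.frame), `cases` (per-case data.frame), `config`
#' @export
run_study <- function(config, ctx = NULL, reference = NULL) {
  cfg <- utils::modifyList(list(n_healthy = 0L, n_trans20 = 0L, n_cc3 = 0L,
                                n_transcc = 0L, seed = 1L, z_threshold = 2,
                                min_area_pixels = 8L, n_reference = 20L,
                                lambda = 0.18, grid_shape = 64L), config)
  if (is.null(ctx))
    ctx <- study_context(grid_shape = cfg$grid_shape, lambda = cfg$lambda)
  if (is.null(reference))
    reference <- simulate_reference(ctx, cfg$n_reference, seed = cfg$seed)

  cats <- c(rep("healthy", cfg$n_healthy), rep("trans20", cfg$n_trans20),
            rep("cc3", cfg$n_cc3), rep("transcc", cfg$n_transcc))
  rows <- vector("list", length(cats))
  for (i in seq_along(cats)) {
    cseed <- cfg$seed * 100000 + 537 * i
    les <- draw_lesion(cats[i], cseed)
    sim <- simulate_case(ctx, seed = cseed, lesion = les)
    det <- detect_ptx(sim$tidal, reference, cfg$z_threshold,
                      cfg$min_area_pixels, segment_image = ctx$segment_image)
    lab <- if (length(sim$truth$labels)) sim$truth$labels[[1]] else
      list(is_trans20 = FALSE, is_cc3 = FALSE, is_transcc = FALSE,
           is_relevant = FALSE)
    seg_true <- if (length(sim$truth$lesions))
      sim$truth$lesions[[1]]$segment_id else NA_integer_
    seg_ok <- if (!is.na(seg_true) && det$is_positive && !is.na(det$segment_id))
      isTRUE(ctx$adjacency[seg_true, det$segment_id]) else NA
    rows[[i]] <- data.frame(
      case_id = i, category = cats[i], seed = cseed,
      is_trans20 = lab$is_trans20, is_cc3 = lab$is_cc3,
      is_transcc = lab$is_transcc, is_relevant = lab$is_relevant,
      detected = det$is_positive, score = det$score,
      area_pixels = det$area_pixels,
      segment_truth = seg_true, segment_detected = det$segment_id,
      segment_correct_or_adjacent = seg_ok,
      stringsAsFactors = FALSE)
  }
  cases <- do.call(rbind, rows)

  cat_rows <- list(
    c("overall_relevant", "is_relevant"),
    c("PTX_cc3", "is_cc3"),
    c("PTX_trans20", "is_trans20"),
    c("PTX_transcc", "is_transcc"))
  summ <- do.call(rbind, lapply(cat_rows, function(cr) {
    sel <- cases[[cr[2]]]
    total <- sum(sel)
    missed <- sum(sel & !cases$detected)
    data.frame(category = cr[1], total = total, missed_count = missed,
               missed_percent = if (total > 0) percent_of(missed, total)
                                else NA_integer_,
               empty = total == 0, stringsAsFactors = FALSE)
  }))

  # Table-1 style: algorithm vs truth over all cases
  tp <- sum(cases$is_relevant & cases$detected)
  fp <- sum(!cases$is_relevant & cases$detected)
  fn <- sum(cases$is_relevant & !cases$detected)
  tn <- sum(!cases$is_relevant & !cases$detected)
  ntot <- nrow(cases)
  overall <- data.frame(
    correctly_classified_percent = percent_of(tp + tn, max(ntot, 1)),
    false_positive_percent = percent_of(fp, max(ntot, 1)),
    false_negative_percent = percent_of(fn, max(ntot, 1)))

  structure(list(summary = summ, cases = cases, algorithm_overall = overall,
                 config = cfg), class = "study_result")
}

#' Recompute the printed agreement statistics from printed marginals
#'
#' Two built-in 2x2 tables are reconstructed from published marginal counts
#' of a blinded two-observer EIT reading study (100 datasets; 55/14/10
#' positive calls for PTX, 51/13/11 for spike potentials) and Cohen's kappa
#' with its independence-null p-value is recomputed from scratch, together
#' with the expected printed values.
#'
#' @return data.frame with the computed and expected kappa / p-value per
#'   comparison and a `pass` flag at printed precision
#' @export
reproduce_stats <- function() {
  specs <- list(
    list(name = "PTX calls, observer 1 vs 2",
         marg = c(100, 55, 14, 10), kappa = 0.09, kdig = 2, p = 0.183),
    list(name = "spike potentials, observer 1 vs 2",
         marg = c(100, 51, 13, 11), kappa = 0.172, kdig = 3, p = 0.009))
  do.call(rbind, lapply(specs, function(s) {
    tb <- table_from_marginals(s$marg[1], s$marg[2], s$marg[3], s$marg[4])
    kr <- cohen_kappa(tb)
    data.frame(comparison = s$name,
               kappa = round(kr$kappa, s$kdig), kappa_expected = s$kappa,
               p_value = round(kr$p_value, 3), p_expected = s$p,
               band = kr$band,
               pass = round(kr$kappa, s$kdig) == s$kappa &&
                 round(kr$p_value, 3) == s$p,
               stringsAsFactors = FALSE)
  }))
}
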