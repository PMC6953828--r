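# Shared fixtures, built once per test run and cached in this environment.
# Everything is generated in code; no binary fixtures.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# default 64x64 phantom (reference anatomy)
fix_phantom <- function() fixture("phantom", function() build_phantom())

# homogeneous unit disk phantom + belt (for symmetry / closed-form checks)
fix_disk <- function() fixture("disk", function() {
  ph <- build_phantom(grid_shape = 64L, pixel_size = 0.5,
                      ellipse_axes = c(56, 56))
  fld <- matrix(NA_real_, 64, 64)
  fld[ph$body_mask] <- 1
  list(phantom = ph, belt = electrode_belt(ph), field = fld)
})

# full study context (phantom + belt + jacobian + frozen operator)
fix_ctx <- function() fixture("ctx", function() study_context())

# pooled healthy reference over 20 simulated pigs (the stated pool size)
fix_reference <- function() fixture("reference", function()
  simulate_reference(fix_ctx(), n_subjects = 20L, seed = 7L))

# one healthy and one matching transcc case on the shared context
fix_healthy_case <- function() fixture("healthy_case", function()
  simulate_case(fix_ctx(), seed = 301L))

fix_transcc_case <- function() fixture("transcc_case", function()
  simulate_case(fix_ctx(), seed = 302L,
                lesion = list(segment_id = 2L, trans_frac = 0.25, cc_cm = 6)))

# twin of the transcc case: same seed, no lesion
fix_twin_case <- function() fixture("twin_case", function()
  simulate_case(fix_ctx(), seed = 302L))
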