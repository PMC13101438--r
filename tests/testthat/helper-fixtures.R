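# Shared fixtures: tiny analytic geometries built in code.

# A placed single-fiber truth table.
single_fiber_truth <- function(d = 1.0, m = 0.25, q = 1.0, theta = 0,
                               row = 25.5, col = 25.5) {
  data.frame(fiber_id = 1L, center_row = row, center_col = col,
             inner_diameter_um = d, myelin_thickness_um = m,
             g_ratio = d / (d + 2 * m), axis_ratio = q,
             orientation_rad = theta)
}

small_render <- function(...) {
  args <- utils::modifyList(
    list(image_height = 50, image_width = 50, psf_sigma = 0,
         noise_sd = 0, artifact_rate = 0),
    list(...))
  do.call(render_params, args)
}

# Noise-free render of a list of fibers on a small canvas.
render_fibers <- function(truths, render = small_render()) {
  render_sample(truths, render, seed = 1)
}

# Semantic mask holding explicit myelin/axon pixel index sets.
mask_from_indices <- function(h, w, myelin_idx = integer(0),
                              axon_idx = integer(0), pixel_size = 0.166) {
  m <- matrix(0L, h, w)
  m[myelin_idx] <- 1L
  m[axon_idx] <- 2L
  semantic_mask(m, pixel_size)
}

# A rasterized ring (annulus) mask centered in an h x w canvas.
ring_mask <- function(h = 30, w = 30, r_in = 4, r_out = 8,
                      cr = (h + 1) / 2, cc = (w + 1) / 2,
                      pixel_size = 0.166) {
  d2 <- outer((seq_len(h) - cr)^2, (seq_len(w) - cc)^2, "+")
  m <- matrix(0L, h, w)
  m[d2 <= r_out^2] <- 1L
  m[d2 <= r_in^2] <- 2L
  semantic_mask(m, pixel_size)
}

# Minimal hand-built fiber record for QC tests.
fake_record <- function(d = 1, g = 0.5, e = 0.3, id = 1L) {
  outer <- d / g
  data.frame(fiber_id = id, axon_area_um2 = pi * (d / 2)^2,
             axon_diameter_um = d, outer_diameter_um = outer,
             myelin_thickness_um = (outer - d) / 2, g_ratio = g,
             eccentricity = e, centroid_row = 1, centroid_col = 1,
             touches_border = FALSE)
}
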