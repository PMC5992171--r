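# Scaled-down phantom specs used across unit tests: same morphology and
# geometry as the defaults, fewer frames for speed.
small_cylinder_spec <- function(n_frames = 6, r = 1.0, seed = 1, ...) {
  phantom_spec(n_frames = n_frames, lumen_radius_fn = radius_cylinder(r),
               seed = seed, ...)
}

# gradient image whose only bright pixels follow prescribed boundary rows
# (1-based), on an otherwise dark background
gradient_from_rows <- function(rows, n_depth, bright = 1, bg = 0) {
  G <- matrix(bg, n_depth, length(rows))
  G[cbind(rows, seq_along(rows))] <- bright
  G
}
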