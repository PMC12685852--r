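# Shared fixtures. Expensive phantoms are built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixture_env)) assign(name, make(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small, fast phantom for unit tests (still at 0.5 mm spacing)
tiny_spec <- function(...) {
  args <- list(annulus_radius_mm = 10, saddle_height_mm = 1.5,
               orifice_radius_min_mm = 2, orifice_radius_max_mm = 7,
               n_frames = 8, voxel_spacing_mm = 0.5, grid_shape = 56)
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

tiny_sequence <- function() fixture("tiny_sequence", function() {
  make_phantom_sequence(tiny_spec())
})

default_sequence <- function() fixture("default_sequence", function() {
  make_phantom_sequence(phantom_spec())
})

# a bare axis-aligned valve plane (normal = +z), for projection tests
axis_plane <- function() {
  structure(list(centroid = c(0, 0, 0), normal = c(0, 0, 1),
                 basis_u = c(1, 0, 0), basis_v = c(0, 1, 0)),
            class = "valve_plane")
}

# centered template volume
centered_template <- function(shape = 64L, spacing = 0.5) {
  A <- diag(c(rep(spacing, 3), 1))
  A[1:3, 4] <- -spacing * (shape - 1) / 2
  label_volume(array(0L, rep(shape, 3)), rep(spacing, 3), A)
}

# random probability map with per-pixel simplex normalization
random_prob_map <- function(H, W, C) {
  x <- array(stats::rgamma(H * W * C, shape = 1), c(H, W, C))
  s <- apply(x, c(1, 2), sum)
  x / array(rep(s, C), c(H, W, C))
}

random_one_hot <- function(H, W, C) {
  lab <- matrix(sample.int(C, H * W, replace = TRUE), H, W)
  one_hot(lab, seq_len(C))
}
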