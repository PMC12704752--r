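# Shared fixtures: built once per test run, in code.

# a small rendering scene (downscaled frame, identical geometry coverage)
small_scene <- function(frame_size = 128, jitter_sd = 0, nebd_time = NA,
                        seed = 11, ...) {
  geom <- follicle_geometry()
  follicle_scene(geom, frame_size = frame_size,
                 pixel_size = geom$follicle_diameter * 1.18 / frame_size,
                 jitter_sd = jitter_sd, nebd_time = nebd_time,
                 seed = seed, ...)
}

# cached wild-type simulation shared across test files
wt_traces <- local({
  cache <- NULL
  function(dt_out = 0.25) {
    if (is.null(cache))
      cache <<- simulate_follicle(t_end = 300, dt_out = dt_out)
    cache
  }
})

# fixed-step explicit Euler oracle for the same ODE system
euler_oracle <- function(params, geometry, perturb, t_start, t_end, dt) {
  ctx <- list(params = params, geom = geometry, perturb = perturb)
  y <- pre_lh_steady_state(params, geometry)
  times <- seq(t_start, t_end, by = dt)
  out <- matrix(NA_real_, length(times), 6)
  out[1, ] <- y
  for (i in seq_along(times)[-1]) {
    y <- y + dt * follisim:::follicle_rhs(times[i - 1], y, ctx)[[1]]
    out[i, ] <- y
  }
  colnames(out) <- names(pre_lh_steady_state(params, geometry))
  data.frame(t_min = times, out)
}
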