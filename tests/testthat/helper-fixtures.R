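# Shared fixtures. Everything is generated in code; expensive objects are
# built once per session and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# small geometry used by most unit tests
test_grid <- function(window = 40L) grid_spec(window = window)

# a mid-ladder anisotropic PSF on the small grid
test_psf <- function(grid = test_grid()) {
  fixture(paste0("psf_", grid$window), function()
    make_psf(450, 300, 0, "gaussian", grid))
}

# deterministic multi-bubble frames for solver tests
test_scene_frames <- function(n = 6, conc = 0.6, noise = 0.1,
                              grid = test_grid(), seed = 7) {
  fixture(sprintf("scene_%d_%g_%g_%d", n, conc, noise, seed), function() {
    set.seed(seed)
    psf <- test_psf(grid)
    lapply(seq_len(n), function(i) {
      b <- random_bubbles(conc, grid)
      list(truth = b,
           frame = synthesize_frame(b, psf,
                                    if (noise > 0) noise_spec(noise),
                                    grid)$frame)
    })
  })
}
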