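# Fixtures are built in code: nothing binary, everything seeded.

# tiny deterministic map: n_px x n_wn positive absorbances
tiny_map <- function(n_px = 5, n_wn = 8, seed = 1, lo = 1500, by = 10) {
  set.seed(seed)
  spectral_map(matrix(runif(n_px * n_wn, 0.1, 1), n_px, n_wn),
               seq(lo, by = by, length.out = n_wn))
}

# single-pixel map holding a sum of Gaussian bands on a given axis
band_map <- function(axis, centers, amplitudes, sigmas) {
  x <- rowSums(mapply(function(c, a, s) a * exp(-((axis - c)^2) / (2 * s^2)),
                      centers, amplitudes, sigmas))
  spectral_map(matrix(x, nrow = 1), axis)
}

# the standard synthetic scene shared across tests (cached per session)
default_scene_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      scene <- make_default_scene(32, 32, seed = 0)
      cache <<- list(scene = scene, map = render_scene(scene))
    }
    cache
  }
})

# three well-separated Gaussian blobs in score space with generative labels
blob_scores <- function(n_per = 60, d = 5, sep = 25, seed = 11) {
  set.seed(seed)
  centers <- diag(sep, 3, d)
  list(scores = do.call(rbind, lapply(1:3, function(i)
         matrix(rnorm(n_per * d), n_per, d) +
           matrix(centers[i, ], n_per, d, byrow = TRUE))),
       labels = rep(1:3, each = n_per))
}
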