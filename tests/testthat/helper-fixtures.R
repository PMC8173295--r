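# shared small fixtures: a coarse wide-field raster keeps aperture and pRF
# tests fast while preserving the full 45-deg geometry
coarse_raster <- function() vf_raster(45, 1.5)

coarse_apertures <- function(n_cycles = 1) {
  r <- coarse_raster()
  list(make_wedge_aperture(r, n_cycles = n_cycles),
       make_ring_aperture(r, n_cycles = n_cycles))
}

# perimetry map with a left hemianopia and given dB elsewhere, no noise
flat_perimetry <- function(db = 25, eye = "right") {
  grid <- make_302_grid(eye)
  v <- rep(db, nrow(grid))
  v[grid$blind_spot] <- 0
  perimetry_map(v, grid)
}

# deterministic per-location values on the 30-2 grid
grid_values <- function(values_at, default = 0, grid = make_302_grid()) {
  v <- rep(default, nrow(grid))
  for (i in seq_len(nrow(values_at))) {
    j <- which(grid$x_deg == values_at$x[i] & grid$y_deg == values_at$y[i])
    v[j] <- values_at$value[i]
  }
  v
}
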