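# small in-code fixtures shared across tests

# tiny even-x grid volume filled from a deterministic stream
tiny_volume <- function(dims = c(8, 6, 6), seed = 42, voxel_mm = c(2, 2, 2)) {
  withr::with_seed(seed, volume(array(runif(prod(dims)), dims), voxel_mm))
}

# small phantom spec so image tests stay fast
small_spec <- function(...) {
  phantom_spec(grid_shape = c(32L, 32L, 32L), roi_radius_vox = 4L,
               amyg_radius_vox = 2L, ...)
}

# concentric-shell tissue phantom for partial-volume tests:
# WM core (r<=10), GM shell (10,17], CSF rim (17,20], on a 48^3 lattice
pvc_phantom <- function(act_gm = 1.0, act_wm = 0.5, act_csf = 0) {
  d <- c(48, 48, 48)
  ii <- array(rep(1:48, 48 * 48), d)
  jj <- array(rep(rep(1:48, each = 48), 48), d)
  kk <- array(rep(1:48, each = 48 * 48), d)
  r <- sqrt((ii - 24.5)^2 + (jj - 24.5)^2 + (kk - 24.5)^2)
  gm <- array(0, d); wm <- array(0, d); csf <- array(0, d)
  wm[r <= 10] <- 1
  gm[r > 10 & r <= 17] <- 1
  csf[r > 17 & r <= 20] <- 1
  act <- act_gm * gm + act_wm * wm + act_csf * csf
  list(gm = volume(gm), wm = volume(wm), csf = volume(csf),
       act = volume(act), r = r)
}
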