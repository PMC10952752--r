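# shared fixtures, built in code at test time

geom_iso <- function(edge = 8L, spacing = 1, center = c(0, 0, 0)) {
  grid_geometry(rep(edge, 3L), spacing, center)
}

random_mask <- function(geometry, p = 0.3) {
  binary_mask(array(runif(prod(geometry$shape)) < p, geometry$shape), geometry)
}

# brute-force evaluation of the generalized Dice loss: explicit double loop
# over classes k and voxels n, independent of the vectorized implementation
gdl_brute <- function(probs, onehot) {
  M <- dim(probs)[4]
  pm <- matrix(probs, ncol = M)
  tm <- matrix(onehot, ncol = M)
  num <- 0
  den <- 0
  for (k in seq_len(M)) {
    tk <- 0
    for (n in seq_len(nrow(tm))) tk <- tk + tm[n, k]
    if (tk == 0) next
    w <- 1 / tk^2
    sn <- 0
    sd_ <- 0
    for (n in seq_len(nrow(pm))) {
      sn <- sn + pm[n, k] * tm[n, k]
      sd_ <- sd_ + pm[n, k] + tm[n, k]
    }
    num <- num + w * sn
    den <- den + w * sd_
  }
  if (den == 0) return(0)
  1 - 2 * num / den
}

# random (pred, target) pair on a small grid; both classes usually present
random_gdl_pair <- function(edge) {
  g <- geom_iso(edge)
  n <- prod(g$shape)
  p_fg <- runif(n)
  probs <- array(c(1 - p_fg, p_fg), dim = c(g$shape, 2L))
  t_fg <- runif(n) < runif(1, 0.1, 0.9)
  onehot <- array(c(as.numeric(!t_fg), as.numeric(t_fg)), dim = c(g$shape, 2L))
  list(probs = probs, onehot = onehot, geometry = g)
}

# sphere sized so that the default step displacements never clip at the
# 32-voxel (96 mm) FOV border
default_sphere_cfg <- function(n_repetitions = 12L,
                               events = list(motion_event(7, c(9, 0, 0))),
                               noise_sigma = 0, edge = 32L,
                               radius_mm = 30) {
  phantom_config(n_repetitions = n_repetitions, edge = edge,
                 events = events, noise_sigma = noise_sigma,
                 radius_mm = radius_mm)
}
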