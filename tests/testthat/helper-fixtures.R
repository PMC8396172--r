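# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# mid-size thorax phantom: fast to build, lungs large enough that each lobe
# clears the 200 mm^3 per-region floor
small_phantom <- function() {
  fixture("small_phantom", function() {
    generate_thorax(spacing_um = 180, shape = c(120, 120, 150),
                    lung_volume_mm3 = 520, noise_sd = 20, seed = 301)
  })
}

# compact phantom for projection work (fewer voxels, lungs below the
# segmentation volume floor -- only truth masks are used with it)
proj_phantom <- function(noise_sd = 0) {
  fixture(paste0("proj_phantom_", noise_sd), function() {
    generate_thorax(spacing_um = 200, shape = c(96, 96, 120),
                    lung_volume_mm3 = 360, noise_sd = noise_sd, seed = 302)
  })
}

small_bank <- function() {
  fixture("small_bank", function() {
    generate_tumor_bank(n_templates = 4, size_range_mm3 = c(0.2, 5),
                        spacing_um = 180, seed = 303)
  })
}

# analytic sphere in attenuation units, centered on an n^3 grid
sphere_volume <- function(n = 64, spacing_um = 150, r_mm = 3.2,
                          att = 0.02) {
  vox <- spacing_um / 1000
  xs <- (seq_len(n) - (n + 1) / 2) * vox
  X <- array(rep(xs, times = n * n), c(n, n, n))
  Y <- array(rep(rep(xs, each = n), times = n), c(n, n, n))
  Z <- array(rep(xs, each = n * n), c(n, n, n))
  inside <- X^2 + Y^2 + Z^2 <= r_mm^2
  list(hu = ct_volume(to_hounsfield(array(ifelse(inside, att, 0), c(n, n, n)),
                                    hu_calibration()), spacing_um),
       att = array(ifelse(inside, att, 0), c(n, n, n)),
       inside = inside, X = X, Y = Y, Z = Z, r_mm = r_mm, att_val = att)
}

# brute-force 26-connected flood fill, the oracle for component labeling
flood_fill_components <- function(vox) {
  d <- dim(vox)
  lab <- array(0L, d)
  nxt <- 0L
  idx_of <- function(i, j, k) i + (j - 1L) * d[1] + (k - 1L) * d[1] * d[2]
  for (start in which(vox == 1L)) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      ci <- arrayInd(cur, d)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        i <- ci[1] + dx; j <- ci[2] + dy; k <- ci[3] + dz
        if (i < 1 || j < 1 || k < 1 || i > d[1] || j > d[2] || k > d[3]) next
        l <- idx_of(i, j, k)
        if (vox[l] == 1L && lab[l] == 0L) {
          lab[l] <- nxt
          queue <- c(queue, l)
        }
      }
    }
  }
  lab
}
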