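# Independent oracles used by the tests.  These re-derive the optics from
# first principles (sequential thin-lens arithmetic and brute-force ray fans)
# without going through the package's matrix/trace code paths.

# Lens table for a preset, written out directly from the instrument geometry:
# data.frame(z, f) in mm from the mirror pivot, objective included as an
# equivalent lens EFL 8.25 mm at 95 + 50 mm past the tube lens.
oracle_lens_table <- function(preset, lens_distance_mm = 5,
                              etl_power_dpt = 0, standoff_mm = 50) {
  z_tl <- 56.6 + 250
  rows <- list(c(-200, if (etl_power_dpt != 0) 1000 / etl_power_dpt else Inf))
  rows <- c(rows, switch(preset,
    DL = list(c(56.6, 50), c(z_tl, 200)),
    nTC1 = list(c(z_tl - 190, 190), c(z_tl - lens_distance_mm, 175),
                c(z_tl, 200)),
    nTC2 = list(c(z_tl - lens_distance_mm, 200), c(z_tl, 200))))
  rows <- c(rows, list(c(z_tl + 95 + standoff_mm, 8.25)))
  data.frame(z = vapply(rows, `[`, numeric(1), 1),
             f = vapply(rows, `[`, numeric(1), 2))
}

# Trace one geometric ray (y, u) through the oracle lens table.
oracle_trace <- function(tab, y, u, start_z = -200.001) {
  z <- start_z
  for (i in seq_len(nrow(tab))) {
    if (tab$z[i] <= z) next
    y <- y + (tab$z[i] - z) * u
    z <- tab$z[i]
    if (is.finite(tab$f[i])) u <- u - y / tab$f[i]
  }
  c(y = y, u = u, z = z)
}

# Brute-force focus: trace a fan of n parallel rays spanning +/- w0 and find
# the axial distance (beyond the objective plane) that minimizes the spread
# of ray heights, then convert into the immersion medium.
oracle_ray_fan_focus <- function(preset, lens_distance_mm = 5,
                                 etl_power_dpt = 0, w0 = 1.39, n = 101,
                                 n_imm = 1.33) {
  tab <- oracle_lens_table(preset, lens_distance_mm, etl_power_dpt)
  h <- seq(-w0, w0, length.out = n)
  ys <- numeric(n); us <- numeric(n)
  for (i in seq_len(n)) {
    r <- oracle_trace(tab, h[i], 0)
    ys[i] <- r["y"]; us[i] <- r["u"]
  }
  # least-squares crossing: minimize sum (y + z u)^2 over z
  z_air <- -sum(ys * us) / sum(us^2)
  list(z_air = z_air, z_water = n_imm * z_air,
       spread = sqrt(mean((ys + z_air * us)^2)))
}

# Height of the fan edge ray at a plane (before refraction there).
oracle_ray_height_at <- function(preset, lens_distance_mm, plane_z,
                                 y0, etl_power_dpt = 0) {
  tab <- oracle_lens_table(preset, lens_distance_mm, etl_power_dpt)
  tab <- tab[tab$z < plane_z, , drop = FALSE]
  r <- oracle_trace(tab, y0, 0)
  unname(r["y"] + (plane_z - r["z"]) * r["u"])
}

# Thin-lens image distance, v = 1 / (1/f - 1/u) with u the object distance
# (negative for a virtual object beyond the lens).
oracle_thin_lens_image <- function(f, u) 1 / (1 / f - 1 / u)

# Default small bead phantom placed well inside a stack volume.
oracle_bead_positions <- function(n, half_xy, half_z, seed) {
  set.seed(seed)
  data.frame(x = runif(n, -half_xy, half_xy),
             y = runif(n, -half_xy, half_xy),
             z = runif(n, -half_z, half_z))
}
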