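# Small seeded seascapes shared across tests.

small_scape <- function(seed = 42, ...) {
  generate_seascape(seascape_config(
    extent_km = c(0, 0, 60, 40), res_km = 2, n_patches = 6,
    n_closures = 3, closure_halfwidth_km = c(4, 8), seed = seed, ...))
}

# flat, fully habitable seafloor with a uniform density field
flat_uniform_scape <- function(density = 0.002, seed = 1) {
  generate_seascape(seascape_config(
    extent_km = c(0, 0, 60, 40), res_km = 2,
    depth_shallow_m = 800, depth_deep_m = 800,
    uniform_density_kg_m2 = density, n_closures = 0, seed = seed))
}

# regular pings along a straight east-west line, one vessel
line_pings <- function(speeds, x0 = 0, y = 10, step_km = 5, interval_h = 1) {
  n <- length(speeds)
  data.frame(vessel_id = "V001",
             timestamp = as.POSIXct("2010-06-01", tz = "UTC") + (seq_len(n) - 1) * interval_h * 3600,
             x = x0 + (seq_len(n) - 1) * step_km, y = y, speed_kn = speeds)
}
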