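# Shared builders for geometry and material fixtures.

table1_materials <- function() material_set()

# Materials with the fish body acoustically identical to water, so that a
# bladder-only computation represents a bare gas scatterer in water.
water_body_materials <- function() {
  material_set(c_w = 1509, c_fb = 1509, c_sb = 345,
               rho_w = 1026, rho_fb = 1026, rho_sb = 1.24)
}

# Gas sphere of radius a_mm digitized finely enough for resampling.
gas_sphere_fish <- function(a_mm, du = 0.1) {
  spheroid_fish(c(a_mm, a_mm, a_mm), c(a_mm, a_mm, a_mm), du = du)
}

# A small gas-filled bladder shape ~19 mm long with the proportions of a
# small chub-mackerel bladder, reduced to its equivalent spheroid
# (semi-minor = sqrt(sbh * sbw) / 2).
small_bladder_fish <- function(du = 0.1) {
  sbl <- 19
  sbh <- sbl * 5 / 30
  sbw <- sbl * 7.1 / 30
  semi_minor <- sqrt(sbh * sbw) / 2
  spheroid_fish(c(sbl / 2, semi_minor, semi_minor),
                c(sbl / 2, semi_minor, semi_minor), du = du)
}

# The gas-filled prolate spheroid benchmark (semi-axes 15 mm / 2 mm).
benchmark_spheroid <- function(du = 0.25) {
  spheroid_fish(c(15, 2, 2), c(15, 2, 2), du = du)
}

krm_ts <- function(fish, mats, f, theta, du = 1, part = "whole") {
  L <- krm_scattering_length(fish, mats, f, theta, du = du, part = part)
  10 * log10(Mod(L)^2)
}
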