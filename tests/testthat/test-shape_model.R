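test_that("shape_profile enforces its geometric invariants", {
  expect_error(shape_profile(5, 1, 0, 1), "at least 2 stations")
  expect_error(shape_profile(c(0, 0), c(1, 1), c(0, 0), c(1, 1)),
               "strictly increasing")
  expect_error(shape_profile(c(0, 1), c(0, 0), c(1, 1), c(1, 1)),
               "z_upper")
  expect_error(shape_profile(c(0, 1), c(1, 1), c(0, 0), c(-1, 1)),
               "non-negative")
  p <- shape_profile(0:10, rep(2, 11), rep(-2, 11), rep(3, 11))
  expect_equal(attr(p, "du"), 1)
})

test_that("resampling is the identity on an already-uniform profile", {
  p <- shape_profile(0:20, sin(0:20 / 3) + 2, sin(0:20 / 3) - 2,
                     abs(cos(0:20 / 5)) + 1)
  q <- resample_profile(p, 1)
  expect_equal(q$u, p$u)
  expect_equal(q$z_upper, p$z_upper)
  expect_equal(q$w, p$w)
})

test_that("resampling is exact on linear data and idempotent", {
  p <- shape_profile(seq(0, 50, 10), seq(0, 50, 10), rep(-1, 6), rep(1, 6))
  q <- resample_profile(p, 1)
  expect_equal(max(abs(diff(q$u) - 1)), 0, tolerance = 1e-9)
  expect_equal(q$z_upper, q$u)  # linear taper preserved exactly
  # endpoints preserved
  expect_equal(range(q$u), range(p$u))
  q2 <- resample_profile(q, 1)
  expect_equal(q2, q)
})

test_that("resampling error against a closed-form circle behaves as chord sag", {
  # semicircular upper boundary, radius 10 mm; linear interpolation of a
  # 5 mm sampling has large sag in the interval adjacent to the pole and
  # small sag over the crown, and halving the input spacing quarters it
  circle <- function(u) sqrt(pmax(0, 100 - u^2))
  sampled <- function(step) {
    u <- seq(-10, 10, by = step)
    shape_profile(u, circle(u), rep(0, length(u)), circle(u))
  }
  err_on <- function(p, lo, hi) {
    q <- resample_profile(p, 0.5)
    keep <- q$u >= lo & q$u <= hi
    max(abs(q$z_upper[keep] - circle(q$u[keep])))
  }
  err5 <- err_on(sampled(5), -5, 5)
  expect_lt(err5, 0.36)     # crown sag of a 5 mm chord, computed 0.352 mm
  expect_gt(err_on(sampled(5), -10, 10), 1)  # pole-adjacent chord is poor
  err2.5 <- err_on(sampled(2.5), -5, 5)
  expect_lt(err2.5, err5 / 3.5)  # ~ O(step^2) convergence on the crown
})

test_that("morphometrics recover analytic spheroid dimensions", {
  sp <- spheroid_fish(c(40, 8, 6), c(15, 2.5, 3.55), du = 0.25)
  m <- measure_morphometrics(sp)
  expect_equal(m$sbl, 30)
  expect_equal(m$sbh, 5)
  expect_equal(m$sbw, 7.1)
  expect_equal(m$sb_theta, 0)
  expect_equal(m$volume, ellipsoid_volume(30, 5, 7.1))
})

test_that("bladder midline inclination is measured against the body centreline", {
  # straight-midline bladder sheared to 11 degrees inside a symmetric body
  tmpl <- trachurus_mediterraneus_template()
  fish <- krmfish:::build_template_fish(tmpl, 15.4, 50, 4, 4.8,
                                        sb_theta = 11, du = 0.5)
  m <- measure_morphometrics(fish)
  expect_equal(m$sb_theta, 11, tolerance = 1e-9)
})

test_that("dorsal area of an elliptical outline matches the ellipse formula", {
  # sbl = 50 mm, sbw = 4.8 mm -> pi/4 * 50 * 4.8
  u <- seq(-25, 25, by = 0.05)
  w <- 4.8 * sqrt(pmax(0, 1 - (u / 25)^2))
  p <- shape_profile(u, rep(1, length(u)), rep(-1, length(u)), w)
  body <- shape_profile(c(-30, 30), c(10, 10), c(-10, -10), c(5, 5))
  fish <- fish_model("ellipse", 15, body, p)
  m <- measure_morphometrics(fish)
  expect_equal(m$dorsal_area, pi / 4 * 50 * 4.8, tolerance = 1e-4)
})

test_that("area and volume are invariant under translation", {
  sp <- spheroid_fish(c(40, 8, 6), c(15, 2.5, 3.55), du = 0.5)
  shifted <- fish_model(sp$species, sp$TL_cm,
                        translate_profile(sp$body, 0, 4),
                        translate_profile(sp$bladder, 3, 4))
  m0 <- measure_morphometrics(sp)
  m1 <- measure_morphometrics(shifted)
  expect_equal(m1$dorsal_area, m0$dorsal_area)
  expect_equal(m1$volume, m0$volume)
  expect_equal(m1$sbh, m0$sbh)
})

test_that("morphometrics on spheroids are within 1% for du <= 0.5 mm", {
  sp <- spheroid_fish(c(40, 8, 6), c(15, 2.5, 3.55), du = 0.5)
  m <- measure_morphometrics(sp)
  truth <- c(sbl = 30, sbh = 5, sbw = 7.1,
             area = pi / 4 * 30 * 7.1,
             vol = ellipsoid_volume(30, 5, 7.1))
  expect_lt(abs(m$sbl - truth["sbl"]) / truth["sbl"], 0.01)
  expect_lt(abs(m$sbh - truth["sbh"]) / truth["sbh"], 0.01)
  expect_lt(abs(m$sbw - truth["sbw"]) / truth["sbw"], 0.01)
  expect_lt(abs(m$dorsal_area - truth["area"]) / truth["area"], 0.01)
})

test_that("ellipsoid volume follows the closed form and guards its domain", {
  expect_equal(ellipsoid_volume(2, 2, 2), 4 * pi / 3)
  expect_equal(ellipsoid_volume(0, 5, 5), 0)
  expect_equal(ellipsoid_volume(30, 5, 7.1), 557.6327, tolerance = 1e-6)
  expect_error(ellipsoid_volume(-1, 2, 2), "non-negative")
})

test_that("deflated specimens are rejected from measurement", {
  body <- shape_profile(c(0, 50, 100), c(10, 12, 10), c(-10, -12, -10),
                        c(8, 10, 8))
  fish <- fish_model("test", 10, body, bladder = NULL)
  expect_false(has_bladder(fish))
  expect_error(measure_morphometrics(fish), "deflated")
})

test_that("shape files round-trip through the tab dialect and accept commas", {
  p <- spheroid_fish(c(20, 5, 4), c(10, 2, 2), du = 1)$bladder
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_shape(p, tsv)
  q <- read_shape(tsv)
  expect_equal(q$u, p$u)
  expect_equal(q$w, p$w)
  csv <- withr::local_tempfile(fileext = ".csv")
  tab <- data.frame(u_mm = p$u, z_upper_mm = p$z_upper,
                    z_lower_mm = p$z_lower, w_mm = p$w)
  write.csv(tab, csv, row.names = FALSE)
  expect_equal(read_shape(csv)$z_upper, p$z_upper)
})

test_that("malformed shape files name the offending row", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("u_mm\tz_upper_mm\tz_lower_mm\tw_mm",
               "0\t1\t-1\t2", "1\toops\t-1\t2"), tsv)
  suppressWarnings(expect_error(read_shape(tsv), "row 2"))
})

test_that("fish round-trip through shape files plus metadata", {
  fish <- spheroid_fish(c(30, 6, 5), c(12, 2, 2.5), du = 1)
  stem <- file.path(withr::local_tempdir(), "fish1")
  write_fish(fish, stem)
  back <- read_fish(stem)
  expect_equal(back$TL_cm, fish$TL_cm)
  expect_equal(back$bladder$w, fish$bladder$w)
  expect_equal(measure_morphometrics(back), measure_morphometrics(fish))
})
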