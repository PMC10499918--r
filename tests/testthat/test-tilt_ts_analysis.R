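make_toy_grid <- function(f, theta, sigma) {
  # assemble a backscatter_grid by hand for averaging tests
  structure(list(f = f, theta = theta, L = sqrt(sigma) + 0i,
                 sigma_bs = sigma, ts = 10 * log10(sigma),
                 k_w = 2 * pi * f / 1509, k_fb = 2 * pi * f / 1570,
                 du = 1, part = "whole"),
            class = "backscatter_grid")
}

test_that("tilt weights are a renormalized truncated Gaussian", {
  d <- tilt_distribution(90, 10)
  expect_equal(sum(d$weights), 1)
  expect_true(all(d$weights >= 0))
  expect_equal(range(d$theta), c(65, 115))
  # symmetric about the mean when the mean is the support centre
  expect_equal(d$weights, rev(d$weights))
  d2 <- tilt_distribution(101, 12)
  expect_gt(d2$weights[d2$theta == 101], d2$weights[d2$theta == 90])
})

test_that("constant sigma is invariant under any tilt average", {
  th <- seq(65, 115, 1)
  g <- make_toy_grid(c(38e3, 70e3), th,
                     matrix(2e-5, nrow = 2, ncol = length(th)))
  for (d in list(tilt_distribution(90, 5), tilt_distribution(101, 12))) {
    avg <- tilt_averaged_sigma(g, d)
    expect_equal(avg$sigma_bs_m2, c(2e-5, 2e-5))
  }
})

test_that("a near-delta distribution picks out sigma at its mean", {
  th <- seq(65, 115, 1)
  sig <- matrix(seq_along(th) * 1e-6, nrow = 1)
  g <- make_toy_grid(38e3, th, sig)
  avg <- tilt_averaged_sigma(g, tilt_distribution(90, 0.001))
  expect_equal(avg$sigma_bs_m2, sig[1, th == 90])
})

test_that("tilt averaging equals explicit weighted summation", {
  th <- seq(65, 115, 1)
  set.seed(42)
  sig <- matrix(10^runif(length(th), -6, -4), nrow = 1)
  g <- make_toy_grid(38e3, th, sig)
  d <- tilt_distribution(88, 13)
  # brute-force oracle: renormalized Gaussian weights times sigma
  w <- dnorm(th, 88, 13)
  w <- w / sum(w)
  expect_equal(tilt_averaged_sigma(g, d)$sigma_bs_m2, sum(w * sig[1, ]))
  # two-point check with hand-computed truncated weights
  th2 <- c(90, 100)
  g2 <- make_toy_grid(38e3, th2, matrix(c(2e-5, 1e-5), nrow = 1))
  d2 <- tilt_distribution(90, 10, support = c(90, 100), step = 10)
  w2 <- dnorm(th2, 90, 10)
  w2 <- w2 / sum(w2)
  expect_equal(tilt_averaged_sigma(g2, d2)$sigma_bs_m2,
               w2[1] * 2e-5 + w2[2] * 1e-5)
})

test_that("tilt averaging is monotone and bounded by the sigma range", {
  th <- seq(65, 115, 1)
  set.seed(7)
  for (rep in 1:5) {
    sig_a <- matrix(10^runif(length(th), -6, -4), nrow = 1)
    sig_b <- sig_a * runif(length(th), 0.1, 1)  # sig_b <= sig_a pointwise
    d <- tilt_distribution(runif(1, 80, 100), runif(1, 2, 20))
    avg_a <- tilt_averaged_sigma(make_toy_grid(38e3, th, sig_a), d)$sigma_bs_m2
    avg_b <- tilt_averaged_sigma(make_toy_grid(38e3, th, sig_b), d)$sigma_bs_m2
    expect_gte(avg_a, avg_b)
    expect_gte(avg_a, min(sig_a))
    expect_lte(avg_a, max(sig_a))
  }
})

test_that("averaging requires the grid to cover the support", {
  g <- make_toy_grid(38e3, seq(80, 100, 1), matrix(1e-5, 1, 21))
  expect_error(tilt_averaged_sigma(g, tilt_distribution(90, 10)), "cover")
})

test_that("noiseless b20 data are fitted exactly by both models", {
  tl <- c(12, 14, 15, 18, 21)
  pairs <- data.frame(TL_cm = tl, ts_db = 20 * log10(tl) - 64.4)
  fit <- suppressWarnings(fit_ts_length(pairs))  # perfect-fit lm warning
  expect_equal(fit$m, 20)
  expect_equal(fit$b, -64.4)
  expect_equal(fit$b20, -64.4)
  expect_equal(fit$r2, 1)
  expect_equal(fit$r2_fixed, 1)
  expect_equal(predict(fit, 15), 20 * log10(15) - 64.4)
  expect_equal(predict(fit, 15), -40.88, tolerance = 0.005)
  expect_equal(predict(fit, 15, model = "fixed"), predict(fit, 15))
})

test_that("degenerate flat TS data give zero slope and r2", {
  pairs <- data.frame(TL_cm = c(10, 15, 20, 25), ts_db = rep(-50, 4))
  fit <- suppressWarnings(fit_ts_length(pairs))
  expect_equal(fit$m, 0)
  expect_equal(fit$r2, 0)
})

test_that("TS-length fit guards its preconditions", {
  expect_error(fit_ts_length(data.frame(TL_cm = c(10, 12), ts_db = c(-50, -49))),
               "insufficient")
  expect_error(fit_ts_length(data.frame(TL_cm = c(-1, 10, 12),
                                        ts_db = c(-50, -49, -48))),
               "positive")
})

test_that("b20 is recovered within 2 s.e. in >= 90% of seeded replicates", {
  b20_true <- -66
  hits <- 0
  set.seed(20260930)
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    tl <- runif(30, 11, 23)
    ts <- 20 * log10(tl) + b20_true + rnorm(30, 0, 0.5)
    fit <- fit_ts_length(data.frame(TL_cm = tl, ts_db = ts))
    if (abs(fit$b20 - b20_true) <= 2 * fit$se_b20) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("relative frequency response normalizes to the 38 kHz reference", {
  sig <- matrix(c(2e-5, 7e-6, 4e-6, 4e-6), nrow = 1)
  r <- relative_frequency_response(sig)
  expect_equal(unname(r$per_fish[1, ]), c(1, 0.35, 0.2, 0.2))
  # flat spectrum
  r2 <- relative_frequency_response(matrix(3e-6, 2, 4))
  expect_true(all(r2$per_fish == 1))
  # r(38) is exactly 1 for every fish, whatever the spectra
  set.seed(3)
  sig3 <- matrix(10^runif(20, -6, -4), nrow = 5)
  r3 <- relative_frequency_response(sig3)
  expect_identical(unname(r3$per_fish[, 1]), rep(1, 5))
  expect_true(all(r3$per_fish >= 0))
  expect_error(relative_frequency_response(matrix(c(0, 1, 1, 1), nrow = 1)),
               "positive")
})

test_that("RFI confidence band is mean +/- 1.96 se across fish", {
  set.seed(11)
  sig <- matrix(10^runif(12, -6, -5), nrow = 3)
  r <- relative_frequency_response(sig)
  ratios <- sig / sig[, 1]
  se <- apply(ratios, 2, sd) / sqrt(3)
  expect_equal(r$summary$mean_r, unname(colMeans(ratios)))
  expect_equal(r$summary$ci_hi - r$summary$ci_lo, unname(2 * 1.96 * se))
})

test_that("allometry test recovers exact power-law slopes", {
  tl <- seq(11, 30, length.out = 12)
  iso <- suppressWarnings(allometry_test(3 * tl^2, tl))
  expect_equal(iso$slope, 2)
  expect_equal(iso$p_value, 1)
  allo <- suppressWarnings(allometry_test(0.8 * tl^2.69, tl))
  expect_equal(allo$slope, 2.69)
  expect_lt(allo$p_value, 1e-6)
  expect_error(allometry_test(c(1, 2), c(10, 20)), "insufficient")
  expect_error(allometry_test(c(-1, 2, 3), c(10, 20, 30)), "positive")
})

test_that("species comparison is null on identical cohorts and detects shifts", {
  tmpl <- trachurus_mediterraneus_template()
  cohort <- do.call(rbind, lapply(generate_cohort(tmpl, 10, seed = 5),
                                  measure_morphometrics))
  cmp <- compare_species_morphometrics(cohort, cohort)
  expect_equal(cmp$t, rep(0, 5))
  expect_equal(cmp$p_value, rep(1, 5))
  # forced separation: shift one cohort's measures by 10 pooled sd
  shifted <- cohort
  for (m in c("sbl", "sbh", "sbw", "dorsal_area", "volume")) {
    shifted[[m]] <- shifted[[m]] + 10 * sd(cohort[[m]])
  }
  cmp2 <- compare_species_morphometrics(cohort, shifted)
  expect_true(all(cmp2$p_value < 0.001))
})

test_that("template cohorts reproduce the species contrast in sign", {
  co_t <- do.call(rbind, lapply(
    generate_cohort(trachurus_mediterraneus_template(), 57, seed = 101),
    measure_morphometrics))
  co_s <- do.call(rbind, lapply(
    generate_cohort(scomber_colias_template(), 25,
                    tl_range_cm = c(11.1, 23.1), seed = 102),
    measure_morphometrics))
  cmp <- compare_species_morphometrics(co_t, co_s)
  diff <- cmp$mean_resid_a - cmp$mean_resid_b
  names(diff) <- cmp$measure
  # horse mackerel: longer bladder; chub mackerel: wider and higher
  expect_gt(diff["sbl"], 0)
  expect_lt(diff["sbw"], 0)
  expect_lt(diff["sbh"], 0)
})
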