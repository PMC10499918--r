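#' TS-length regression (free slope and slope fixed to 20)
#'
#' Fits the standard model \eqn{TS = m \log_{10} L + b} by ordinary least
#' squares and, alongside it, the fixed-slope conversion model
#' \eqn{TS = 20 \log_{10} L + b_{20}}, whose intercept is the mean offset
#' \eqn{b_{20} = \overline{TS_i - 20\log_{10} L_i}}. \eqn{L} is the fish
#' total length in cm and TS is in dB re 1 m^2. `b20` is the conversion
#' constant used to turn survey backscatter into biomass.
#'
#' @param pairs Data frame with columns `TL_cm` (> 0) and `ts_db`, one row
#'   per fish.
#' @param fixed_slope Slope of the fixed-slope model (default 20); set to
#'   `NULL` to skip it.
#' @return An object of class `ts_length_fit`: a list with `n`, free-slope
#'   coefficients `m`, `b` and their standard errors `se_m`, `se_b`,
#'   coefficient of determination `r2`, residual standard error
#'   `sigma_resid`, and (when `fixed_slope` is given) `fixed_slope`, `b20`,
#'   `se_b20`, `r2_fixed`, `sigma_resid_fixed`.
#' @examples
#' tl <- c(12, 15, 18, 21)
#' fit <- fit_ts_length(data.frame(TL_cm = tl, ts_db = 20 * log10(tl) - 64.4))
#' fit$m; fit$b20
#' @export
fit_ts_length <- function(pairs, fixed_slope = 20) {
  if (!all(c("TL_cm", "ts_db") %in% names(pairs))) {
    stop("pairs must have columns TL_cm and ts_db", call. = FALSE)
  }
  if (any(pairs$TL_cm <= 0)) stop("total lengths must be positive", call. = FALSE)
  n <- nrow(pairs)
  if (n < 3) stop("insufficient data: the free-slope fit needs n >= 3", call. = FALSE)
  logL <- log10(pairs$TL_cm)
  ts <- pairs$ts_db
  fit <- stats::lm(ts ~ logL)
  cf <- summary(fit)$coefficients
  ss_tot <- sum((ts - mean(ts))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  out <- list(n = n,
              m = unname(cf["logL", "Estimate"]),
              b = unname(cf["(Intercept)", "Estimate"]),
              se_m = unname(cf["logL", "Std. Error"]),
              se_b = unname(cf["(Intercept)", "Std. Error"]),
              r2 = r2,
              sigma_resid = summary(fit)$sigma)
  if (!is.null(fixed_slope)) {
    off <- ts - fixed_slope * logL
    b20 <- mean(off)
    res_f <- off - b20
    ss_res_f <- sum(res_f^2)
    out$fixed_slope <- fixed_slope
    out$b20 <- b20
    out$se_b20 <- stats::sd(off) / sqrt(n)
    out$r2_fixed <- if (ss_tot > 0) max(0, 1 - ss_res_f / ss_tot) else
      as.numeric(ss_res_f <= 1e-12)
    out$sigma_resid_fixed <- sqrt(ss_res_f / (n - 1))
  }
  class(out) <- "ts_length_fit"
  out
}

#' @export
print.ts_length_fit <- function(x, ...) {
  cat(sprintf("<ts_length_fit> n = %d\n", x$n))
  cat(sprintf("  TS = %.2f log10(L) + %.2f   (se %.2f / %.2f, r2 = %.2f)\n",
              x$m, x$b, x$se_m, x$se_b, x$r2))
  if (!is.null(x$b20)) {
    cat(sprintf("  TS = %g log10(L) + %.2f      (se %.2f, r2 = %.2f)\n",
                x$fixed_slope, x$b20, x$se_b20, x$r2_fixed))
  }
  invisible(x)
}

#' Predict TS from a fitted TS-length relation
#'
#' @param object A [fit_ts_length()] result.
#' @param TL_cm Total lengths in cm.
#' @param model `"free"` for the fitted slope, `"fixed"` for the
#'   fixed-slope (b20) model.
#' @param ... Unused.
#' @return Predicted TS in dB re 1 m^2.
#' @export
predict.ts_length_fit <- function(object, TL_cm, model = c("free", "fixed"), ...) {
  model <- match.arg(model)
  if (model == "free") object$m * log10(TL_cm) + object$b
  else {
    if (is.null(object$b20)) stop("fit has no fixed-slope model", call. = FALSE)
    object$fixed_slope * log10(TL_cm) + object$b20
  }
}

#' Relative frequency response across survey frequencies
#'
#' The multi-frequency fingerprint \eqn{r_i(f) = \sigma_i(f)/\sigma_i(38)}:
#' each fish's (tilt-averaged or broadside) backscattering cross-section
#' at the discrete survey frequencies is divided by its value at the
#' reference frequency (38 kHz). The cohort curve is the mean ratio across
#' fish with a parametric confidence band (mean +/- 1.96 standard errors).
#'
#' @param sigma Numeric matrix of backscattering cross-sections, one row
#'   per fish, one column per frequency.
#' @param f_khz Frequencies (kHz) labelling the columns, default
#'   `c(38, 70, 120, 200)`.
#' @param ref_khz Reference frequency, default 38 kHz (must be one of
#'   `f_khz`).
#' @return An object of class `rfi_curve`: `per_fish` (matrix of ratios)
#'   and `summary` (data frame `f_khz`, `mean_r`, `ci_lo`, `ci_hi`).
#' @export
relative_frequency_response <- function(sigma, f_khz = c(38, 70, 120, 200),
                                        ref_khz = 38) {
  sigma <- as.matrix(sigma)
  if (ncol(sigma) != length(f_khz)) {
    stop("sigma must have one column per frequency in f_khz", call. = FALSE)
  }
  ref <- which(abs(f_khz - ref_khz) < 1e-9)
  if (length(ref) != 1) stop("ref_khz must appear in f_khz", call. = FALSE)
  if (any(sigma[, ref] <= 0)) {
    stop("sigma at the reference frequency must be positive for every fish",
         call. = FALSE)
  }
  ratios <- sigma / sigma[, ref]
  colnames(ratios) <- paste0("r_", f_khz)
  n <- nrow(ratios)
  mean_r <- colMeans(ratios)
  se <- if (n > 1) apply(ratios, 2, stats::sd) / sqrt(n) else rep(NA_real_, ncol(ratios))
  structure(list(per_fish = ratios,
                 summary = data.frame(f_khz = f_khz, mean_r = unname(mean_r),
                                      ci_lo = unname(mean_r - 1.96 * se),
                                      ci_hi = unname(mean_r + 1.96 * se)),
                 ref_khz = ref_khz, n = n),
            class = "rfi_curve")
}

#' @export
print.rfi_curve <- function(x, ...) {
  cat(sprintf("<rfi_curve> %d fish, reference %g kHz\n", x$n, x$ref_khz))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Allometric growth test of the dorsal cross-sectional area
#'
#' Regresses \eqn{\log_{10}(area)} on \eqn{\log_{10}(TL)} and tests the
#' slope against 2, the isometric expectation for an area, with a
#' two-sided t-test. A slope significantly above 2 indicates allometric
#' growth of the swimbladder's dorsal area with fish length.
#'
#' @param areas Dorsal areas (mm^2, > 0).
#' @param TLs Total lengths (cm, > 0).
#' @return A list with `slope`, `se`, `t`, `df`, `p_value`, `n`.
#' @export
allometry_test <- function(areas, TLs) {
  if (length(areas) != length(TLs)) stop("areas and TLs must match", call. = FALSE)
  if (any(areas <= 0) || any(TLs <= 0)) {
    stop("areas and lengths must be positive", call. = FALSE)
  }
  n <- length(areas)
  if (n < 3) stop("insufficient data: allometry test needs n >= 3", call. = FALSE)
  fit <- stats::lm(log10(areas) ~ log10(TLs))
  cf <- summary(fit)$coefficients
  slope <- unname(cf[2, "Estimate"])
  se <- unname(cf[2, "Std. Error"])
  df <- n - 2
  if (se < 1e-12) {  # noiseless power-law data
    t <- if (abs(slope - 2) < 1e-9) 0 else sign(slope - 2) * Inf
    p <- if (abs(slope - 2) < 1e-9) 1 else 0
  } else {
    t <- (slope - 2) / se
    p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  }
  list(slope = slope, se = se, t = t, df = df, p_value = p, n = n)
}

#' Compare swimbladder morphometrics between two species
#'
#' Removes the fish-length effect by regressing each swimbladder measure
#' (`sbl`, `sbh`, `sbw`, `dorsal_area`, `volume`) linearly on total length
#' over the pooled cohorts, keeps the residuals as relative (dimensionless
#' of length) swimbladder sizes, and compares the two species' residuals
#' with a Welch two-sample t-test per measure. The pooled fit is what
#' makes the species contrast visible: residuals of a within-species fit
#' are centred on zero by construction.
#'
#' @param cohort_a,cohort_b Data frames of per-fish morphometrics as
#'   returned by [measure_morphometrics()] (rows bound together), each
#'   with n >= 3.
#' @return A data frame with one row per measure: `measure`, `t`, `df`,
#'   `p_value`, `mean_resid_a`, `mean_resid_b`.
#' @export
compare_species_morphometrics <- function(cohort_a, cohort_b) {
  measures <- c("sbl", "sbh", "sbw", "dorsal_area", "volume")
  need <- c("TL_cm", measures)
  for (co in list(cohort_a, cohort_b)) {
    if (!all(need %in% names(co))) {
      stop("cohorts must contain columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (nrow(co) < 3) stop("insufficient data: each cohort needs n >= 3", call. = FALSE)
  }
  na <- nrow(cohort_a)
  pooled <- rbind(cohort_a[need], cohort_b[need])
  out <- lapply(measures, function(m) {
    fit <- stats::lm(pooled[[m]] ~ pooled$TL_cm)
    res <- stats::residuals(fit)
    ra <- res[seq_len(na)]
    rb <- res[-seq_len(na)]
    if (stats::var(ra) + stats::var(rb) < 1e-24) {
      # degenerate: identical residual sets
      data.frame(measure = m, t = 0, df = NA_real_, p_value = 1,
                 mean_resid_a = mean(ra), mean_resid_b = mean(rb))
    } else {
      tt <- stats::t.test(ra, rb)
      data.frame(measure = m, t = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 mean_resid_a = mean(ra), mean_resid_b = mean(rb))
    }
  })
  do.call(rbind, out)
}
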