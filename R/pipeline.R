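#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end workflow. The defaults
#' reproduce the study configuration: Table-1 materials, 1 mm slices,
#' discrete survey frequencies 38/70/120/200 kHz, tilt grid 65-115 degrees
#' at 1 degree steps, and the five orientation models 90 +/- 5, 90 +/- 10,
#' 90 +/- 20, 101 +/- 12 and 88 +/- 13 degrees. The 88 +/- 13 interval
#' (normal swimming behaviour) is the one used for the reported RFI
#' curves.
#'
#' @param materials A [material_set()].
#' @param du_mm Slice thickness (mm).
#' @param freqs_hz Discrete survey frequencies (Hz).
#' @param theta_deg Tilt-angle grid (degrees, within \[65, 115\]).
#' @param tilt_models Data frame with columns `mean` and `sd` (degrees),
#'   one row per orientation model.
#' @param rfi_tilt Length-2 numeric `c(mean, sd)` selecting the
#'   orientation model used for the tilt-averaged RFI.
#' @param seed Integer seed for any synthetic generation.
#' @return An object of class `run_config`.
#' @export
run_config <- function(materials = material_set(),
                       du_mm = 1,
                       freqs_hz = c(38, 70, 120, 200) * 1e3,
                       theta_deg = seq(65, 115, by = 1),
                       tilt_models = data.frame(
                         mean = c(90, 90, 90, 101, 88),
                         sd = c(5, 10, 20, 12, 13)),
                       rfi_tilt = c(88, 13),
                       seed = 1) {
  stopifnot(inherits(materials, "material_set"),
            all(c("mean", "sd") %in% names(tilt_models)))
  structure(list(materials = materials, du_mm = du_mm, freqs_hz = freqs_hz,
                 theta_deg = theta_deg, tilt_models = tilt_models,
                 rfi_tilt = rfi_tilt, seed = as.integer(seed)),
            class = "run_config")
}

#' Serialize and restore a pipeline configuration
#'
#' JSON round-trip of a [run_config()].
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return `read_config()` returns a `run_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- list(materials = unclass(config$materials), du_mm = config$du_mm,
            freqs_hz = config$freqs_hz, theta_deg = config$theta_deg,
            tilt_models = config$tilt_models, rfi_tilt = config$rfi_tilt,
            seed = config$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(materials = do.call(material_set, as.list(x$materials)),
             du_mm = x$du_mm, freqs_hz = x$freqs_hz, theta_deg = x$theta_deg,
             tilt_models = as.data.frame(x$tilt_models),
             rfi_tilt = x$rfi_tilt, seed = x$seed)
}

config_fingerprint <- function(config) {
  js <- jsonlite::toJSON(list(unclass(config$materials), config$du_mm,
                              config$freqs_hz, config$theta_deg,
                              config$tilt_models, config$rfi_tilt,
                              config$seed),
                         auto_unbox = TRUE, digits = NA)
  sprintf("%08x", sum(as.integer(charToRaw(as.character(js))) *
                        (seq_along(charToRaw(as.character(js))) %% 97 + 1)) %%
            .Machine$integer.max)
}

#' Run the full backscatter-analysis pipeline
#'
#' Chains the stages end to end: morphometrics of every inflated specimen,
#' per-fish KRM grids over the discrete survey frequencies and the tilt
#' grid, tilt-averaged TS per orientation model, per-species TS-length
#' regression tables (free slope and slope fixed to 20, evaluated at 38
#' kHz), and tilt-averaged plus broadside relative frequency response
#' curves. Deflated specimens are excluded and logged with a reason.
#'
#' @param config A [run_config()].
#' @param fish One of: a list of [fish_model()] objects; a directory path
#'   containing fish written by [write_fish()]; or a synthetic
#'   specification `list(template =, n =)` handed to [generate_cohort()]
#'   with the config seed.
#' @return An object of class `krm_results`: a list with `morphometrics`,
#'   `tilt_ts` (per fish x orientation model x frequency), `regressions`
#'   (per species x orientation model), `rfi` (per species, tilt-averaged
#'   and broadside), `excluded`, `log` and `config`.
#' @export
run_pipeline <- function(config, fish) {
  stopifnot(inherits(config, "run_config"))
  log <- c(sprintf("krmfish %s | config %s | seed %d",
                   as.character(utils::packageVersion("krmfish")),
                   config_fingerprint(config), config$seed))

  if (is.character(fish) && length(fish) == 1 && dir.exists(fish)) {
    stems <- sub("_meta\\.json$", "",
                 list.files(fish, pattern = "_meta\\.json$", full.names = TRUE))
    fish <- lapply(stems, read_fish)
    log <- c(log, sprintf("read %d fish from %s", length(fish), stems[1]))
  } else if (is.list(fish) && !is.null(fish$template)) {
    fish <- generate_cohort(fish$template, fish$n, seed = config$seed)
    log <- c(log, sprintf("generated %d synthetic fish (seed %d)",
                          length(fish), config$seed))
  }
  if (!length(fish) || !all(vapply(fish, inherits, logical(1), "fish_model"))) {
    stop("fish must be a list of fish_model objects, a directory, or a ",
         "synthetic spec", call. = FALSE)
  }

  inflated <- vapply(fish, has_bladder, logical(1))
  excluded <- data.frame(fish_id = which(!inflated),
                         species = vapply(fish[!inflated], function(f) f$species,
                                          character(1)),
                         reason = rep("deflated swimbladder",
                                      sum(!inflated)))
  for (i in which(!inflated)) {
    log <- c(log, sprintf("excluded fish %d (%s): deflated swimbladder",
                          i, fish[[i]]$species))
  }
  fish <- fish[inflated]
  if (!length(fish)) stop("empty cohort: all specimens are deflated", call. = FALSE)

  morpho <- do.call(rbind, lapply(fish, measure_morphometrics))
  morpho <- cbind(fish_id = seq_along(fish), morpho)

  grids <- lapply(fish, function(f) {
    krm_grid(f, config$materials, config$freqs_hz, config$theta_deg,
             du = config$du_mm)
  })

  # tilt-averaged TS per fish x orientation model x frequency; the
  # quadrature nodes are the grid's own tilt nodes
  theta_step <- config$theta_deg[2] - config$theta_deg[1]
  tilt_ts <- do.call(rbind, lapply(seq_len(nrow(config$tilt_models)), function(d) {
    dist <- tilt_distribution(config$tilt_models$mean[d],
                              config$tilt_models$sd[d],
                              support = range(config$theta_deg),
                              step = theta_step)
    do.call(rbind, lapply(seq_along(fish), function(i) {
      avg <- tilt_averaged_sigma(grids[[i]], dist)
      data.frame(fish_id = i, species = fish[[i]]$species,
                 TL_cm = fish[[i]]$TL_cm,
                 tilt_mean = dist$mean, tilt_sd = dist$sd,
                 f_hz = avg$f_hz, sigma_bs_m2 = avg$sigma_bs_m2,
                 ts_db = avg$ts_db)
    }))
  }))

  # TS-length regressions at 38 kHz, per species x orientation model
  f38 <- config$freqs_hz[which.min(abs(config$freqs_hz - 38e3))]
  reg_rows <- list()
  for (sp in unique(morpho$species)) {
    for (d in seq_len(nrow(config$tilt_models))) {
      sub <- tilt_ts[tilt_ts$species == sp &
                       tilt_ts$tilt_mean == config$tilt_models$mean[d] &
                       tilt_ts$tilt_sd == config$tilt_models$sd[d] &
                       tilt_ts$f_hz == f38, ]
      if (nrow(sub) < 3) next
      fit <- fit_ts_length(data.frame(TL_cm = sub$TL_cm, ts_db = sub$ts_db))
      reg_rows[[length(reg_rows) + 1]] <-
        data.frame(species = sp, tilt_mean = config$tilt_models$mean[d],
                   tilt_sd = config$tilt_models$sd[d], n = fit$n,
                   m = fit$m, b = fit$b, se_b = fit$se_b, r2 = fit$r2,
                   b20 = fit$b20, se_b20 = fit$se_b20,
                   r2_fixed = fit$r2_fixed)
    }
  }
  regressions <- if (length(reg_rows)) do.call(rbind, reg_rows) else NULL

  # RFI: tilt-averaged (rfi_tilt model) and broadside, per species
  rfi <- list()
  dist_rfi <- tilt_distribution(config$rfi_tilt[1], config$rfi_tilt[2],
                                support = range(config$theta_deg),
                                step = theta_step)
  i90 <- match_angle(90, config$theta_deg)
  for (sp in unique(morpho$species)) {
    idx <- which(vapply(fish, function(f) f$species == sp, logical(1)))
    sig_avg <- t(vapply(idx, function(i) {
      tilt_averaged_sigma(grids[[i]], dist_rfi)$sigma_bs_m2
    }, numeric(length(config$freqs_hz))))
    sig_bro <- t(vapply(idx, function(i) grids[[i]]$sigma_bs[, i90],
                        numeric(length(config$freqs_hz))))
    rfi[[sp]] <- list(
      tilt_averaged = relative_frequency_response(sig_avg,
                                                  f_khz = config$freqs_hz / 1e3),
      broadside = relative_frequency_response(sig_bro,
                                              f_khz = config$freqs_hz / 1e3))
  }
  log <- c(log, sprintf("processed %d inflated specimens (%s)",
                        length(fish),
                        paste(unique(morpho$species), collapse = ", ")))

  structure(list(morphometrics = morpho, tilt_ts = tilt_ts,
                 regressions = regressions, rfi = rfi, grids = grids,
                 excluded = excluded, log = log, config = config),
            class = "krm_results")
}

#' @export
print.krm_results <- function(x, ...) {
  cat("<krm_results>\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

#' Write the pipeline result tables
#'
#' Emits tab-separated tables (`morphometrics.tsv`, `tilt_ts.tsv`,
#' `ts_length_regressions.tsv`, `rfi.tsv`) and a JSON run manifest
#' (`manifest.json`, with config, fingerprint and exclusions) into a
#' directory. All dB values are rounded to 2 decimals in the tables.
#'
#' @param results A [run_pipeline()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "krm_results"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(x, name) {
    utils::write.table(x, file.path(dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  round_db <- function(x) round(x, 2)
  m <- results$morphometrics
  wt(m, "morphometrics.tsv")
  tt <- results$tilt_ts
  tt$ts_db <- round_db(tt$ts_db)
  wt(tt, "tilt_ts.tsv")
  if (!is.null(results$regressions)) {
    rg <- results$regressions
    for (col in c("m", "b", "se_b", "b20", "se_b20")) rg[[col]] <- round_db(rg[[col]])
    for (col in c("r2", "r2_fixed")) rg[[col]] <- round(rg[[col]], 2)
    wt(rg, "ts_length_regressions.tsv")
  }
  rfi_tab <- do.call(rbind, lapply(names(results$rfi), function(sp) {
    do.call(rbind, lapply(c("tilt_averaged", "broadside"), function(case) {
      s <- results$rfi[[sp]][[case]]$summary
      cbind(species = sp, case = case, round(s, 4))
    }))
  }))
  if (!is.null(rfi_tab)) wt(rfi_tab, "rfi.tsv")
  manifest <- list(config = jsonlite::fromJSON(jsonlite::toJSON(
    list(materials = unclass(results$config$materials),
         du_mm = results$config$du_mm, freqs_hz = results$config$freqs_hz,
         tilt_models = results$config$tilt_models,
         rfi_tilt = results$config$rfi_tilt, seed = results$config$seed),
    auto_unbox = TRUE, digits = NA)),
    fingerprint = config_fingerprint(results$config),
    excluded = results$excluded, log = results$log)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
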