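#' Sensitivity of the KRM spectrum to slice thickness
#'
#' Recomputes the TS(f) spectrum of a fish (or of its swimbladder or body
#' alone) for several slice thicknesses and reports the pairwise band-max
#' absolute TS differences. Thicknesses are given in mm, or as the string
#' `"lambda/10"` which is resolved as one tenth of the water wavelength at
#' `lambda_ref_hz` (default 200 kHz, the refinement reference).
#'
#' @inheritParams krm_scattering_length
#' @param thicknesses Vector (length >= 2) of slice thicknesses: numbers in
#'   mm and/or the string `"lambda/10"`.
#' @param f Frequencies in Hz.
#' @param theta Tilt angle in degrees (default 90, broadside).
#' @param lambda_ref_hz Frequency at which `"lambda/10"` is evaluated.
#' @return A list of class `slice_sensitivity` with elements `ts` (long
#'   data frame `thickness`, `du_mm`, `f_hz`, `ts_db`) and `pairwise`
#'   (data frame `thickness_a`, `thickness_b`, `max_abs_dts_db`).
#' @export
slice_sensitivity <- function(fish, mats, thicknesses, f, theta = 90,
                              part = c("whole", "bladder", "body"),
                              lambda_ref_hz = 200000) {
  part <- match.arg(part)
  if (length(thicknesses) < 2) {
    stop("need at least two slice thicknesses to compare", call. = FALSE)
  }
  labels <- vapply(thicknesses, function(t) {
    if (is.character(t)) t else paste0(format(t), " mm")
  }, character(1))
  du_mm <- vapply(thicknesses, function(t) {
    if (is.character(t)) {
      if (!identical(t, "lambda/10")) {
        stop("unknown thickness specifier: ", t, call. = FALSE)
      }
      mats$c_w / lambda_ref_hz / 10 * 1000
    } else as.numeric(t)
  }, numeric(1))

  curves <- lapply(du_mm, function(du) {
    L <- krm_scattering_length(fish, mats, f, theta, du = du, part = part)
    10 * log10(Mod(L)^2)
  })
  ts <- do.call(rbind, lapply(seq_along(curves), function(i) {
    data.frame(thickness = labels[i], du_mm = du_mm[i], f_hz = f,
               ts_db = curves[[i]])
  }))
  pairs <- utils::combn(seq_along(curves), 2)
  pairwise <- data.frame(
    thickness_a = labels[pairs[1, ]],
    thickness_b = labels[pairs[2, ]],
    max_abs_dts_db = apply(pairs, 2, function(ij) {
      max(abs(curves[[ij[1]]] - curves[[ij[2]]]))
    })
  )
  structure(list(ts = ts, pairwise = pairwise, part = part, theta = theta),
            class = "slice_sensitivity")
}

#' @export
print.slice_sensitivity <- function(x, ...) {
  cat(sprintf("<slice_sensitivity> part = %s, theta = %g deg\n", x$part, x$theta))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Band-restricted maximum TS difference between two spectra
#'
#' Compares two TS(f) spectra over a frequency band, interpolating the
#' coarser spectrum onto the finer grid linearly in TS. Used to benchmark
#' KRM spectra against externally computed full-wave (e.g. finite-element)
#' solutions imported through [read_spectrum()].
#'
#' @param spec_a,spec_b Data frames with columns `f_hz` and `ts_db`.
#' @param band Numeric length-2 vector, the frequency band in Hz.
#' @return A list of class `spectrum_diff`: `band` (Hz), `max_abs_dts_db`,
#'   and `table` (per-frequency `f_hz`, `dts_db`).
#' @export
spectrum_max_diff <- function(spec_a, spec_b, band) {
  check_spectrum <- function(s, name) {
    if (!all(c("f_hz", "ts_db") %in% names(s))) {
      stop(name, " must have columns f_hz and ts_db", call. = FALSE)
    }
    s[order(s$f_hz), , drop = FALSE]
  }
  spec_a <- check_spectrum(spec_a, "spec_a")
  spec_b <- check_spectrum(spec_b, "spec_b")
  if (length(band) != 2 || band[1] >= band[2]) {
    stop("band must be (lo, hi) with lo < hi", call. = FALSE)
  }
  tol <- 1e-6
  if (min(spec_a$f_hz) > band[1] + tol || max(spec_a$f_hz) < band[2] - tol ||
      min(spec_b$f_hz) > band[1] + tol || max(spec_b$f_hz) < band[2] - tol) {
    stop("both spectra must cover the requested band", call. = FALSE)
  }
  in_band <- function(s) s$f_hz >= band[1] - tol & s$f_hz <= band[2] + tol
  na <- sum(in_band(spec_a))
  nb <- sum(in_band(spec_b))
  if (na >= nb) {
    f_ref <- spec_a$f_hz[in_band(spec_a)]
    ts_ref <- spec_a$ts_db[in_band(spec_a)]
    ts_other <- stats::approx(spec_b$f_hz, spec_b$ts_db, xout = f_ref)$y
  } else {
    f_ref <- spec_b$f_hz[in_band(spec_b)]
    ts_ref <- stats::approx(spec_a$f_hz, spec_a$ts_db, xout = f_ref)$y
    ts_other <- spec_b$ts_db[in_band(spec_b)]
  }
  tab <- data.frame(f_hz = f_ref, dts_db = ts_ref - ts_other)
  structure(list(band = band, max_abs_dts_db = max(abs(tab$dts_db)),
                 table = tab),
            class = "spectrum_diff")
}

#' @export
print.spectrum_diff <- function(x, ...) {
  cat(sprintf("<spectrum_diff> band %g-%g kHz: max |dTS| = %.3f dB (%d frequencies)\n",
              x$band[1] / 1e3, x$band[2] / 1e3, x$max_abs_dts_db, nrow(x$table)))
  invisible(x)
}

#' Read and write TS spectrum files
#'
#' Two-column delimited text (`f_hz`, `ts_db`); the writer emits tabs, the
#' reader accepts commas or tabs. This is both the export format for KRM
#' spectra and the import interface for external full-wave oracle spectra.
#'
#' @param path File path.
#' @param spectrum Data frame with columns `f_hz`, `ts_db` (for the writer).
#' @return `read_spectrum()` returns a data frame `f_hz`, `ts_db`;
#'   `write_spectrum()` returns `path` invisibly.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("spectrum file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("f_hz", "ts_db") %in% names(tab))) {
    stop("malformed spectrum file ", path, ": expected columns f_hz, ts_db",
         call. = FALSE)
  }
  tab[order(tab$f_hz), c("f_hz", "ts_db")]
}

#' @rdname read_spectrum
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(all(c("f_hz", "ts_db") %in% names(spectrum)))
  utils::write.table(spectrum[c("f_hz", "ts_db")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
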